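write_bed12 <- function(path, rows) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
}

test_that("BED12 junction records convert with 0-based half-open arithmetic", {
  path <- withr::local_tempfile(fileext = ".bed")
  # chromStart 100, blockSizes 50,50, blockStarts 0,150
  write_bed12(path, list(c("chr7", 100, 300, "JUNC1", 12, "+",
                           100, 300, "255,0,0", 2, "50,50", "0,150")))
  jt <- read_junction_bed(path, sample_id = "s1", class = "tumor")
  # hand conversion: block 1 covers 1-based [101,150] so pos1 = 150;
  # block 2 starts at 0-based 250 so pos2 = 251
  expect_equal(jt$pos1, 150L)
  expect_equal(jt$pos2, 251L)
  expect_equal(jt$strand, "+")
  expect_equal(jt$count, 12L)

  # malformed block count
  bad <- withr::local_tempfile(fileext = ".bed")
  write_bed12(bad, list(c("chr7", 100, 300, "J", 5, "+", 100, 300, "0", 3,
                          "50,50,50", "0,100,150")))
  err <- expect_error(read_junction_bed(bad, "s1"), class = "racescreen_format_error")
  expect_match(conditionMessage(err), "line 1")
})

test_that("BED12 conversion agrees with rtracklayer block parsing", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".bed")
  set.seed(99)
  rows <- lapply(1:8, function(i) {
    start <- sample(1000:100000, 1)
    s1 <- sample(30:120, 1); s2 <- sample(30:120, 1)
    gap <- sample(200:5000, 1)
    c(paste0("chr", sample(1:5, 1)), start, start + s1 + gap + s2,
      paste0("J", i), sample(1:500, 1), sample(c("+", "-"), 1),
      start, start + s1 + gap + s2, "255,0,0", 2,
      paste0(s1, ",", s2), paste0(0, ",", s1 + gap))
  })
  write_bed12(path, rows)
  jt <- read_junction_bed(path, "s1")
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- rtracklayer::blocks(gr)
  expect_equal(jt$pos1,
               vapply(seq_along(blocks), function(i) BiocGenerics::end(blocks[[i]])[1], 0L))
  expect_equal(jt$pos2,
               vapply(seq_along(blocks), function(i) BiocGenerics::start(blocks[[i]])[2], 0L))
})

test_that("plain TSV junction tables pass through and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos1\tpos2\tstrand\tcount",
               "chr19\t51485170\t51504353\t+\t12"), path)
  jt <- read_junction_bed(path, "s1", "cell_line")
  expect_equal(jt$pos1, 51485170L)
  expect_equal(jt$count, 12L)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_junction_tsv(jt, out)
  back <- read_junction_bed(out, "s1", "cell_line")
  expect_identical(back, jt)
})

test_that("junction tables validate coordinates, counts and strand", {
  base <- tibble::tibble(chrom = "chr1", pos1 = 100L, pos2 = 200L,
                         strand = "+", count = 5L)
  expect_s3_class(junction_table("s", "tumor", base), "tbl_df")
  expect_error(junction_table("s", "tumor", dplyr::mutate(base, pos2 = 100L)),
               class = "racescreen_validation_error")
  expect_error(junction_table("s", "tumor", dplyr::mutate(base, count = 0L)),
               class = "racescreen_validation_error")
  expect_error(junction_table("s", "tumor", dplyr::mutate(base, strand = "x")),
               class = "racescreen_validation_error")
})

mk_jt <- function(sample, class, ...) {
  junction_table(sample, class, tibble::tribble(~chrom, ~pos1, ~pos2, ~strand, ~count, ...))
}

test_that("cohort merge unions junctions and rejects duplicate samples", {
  t1 <- mk_jt("s1", "tumor", "chr1", 10L, 50L, "+", 5L, "chr2", 5L, 25L, "-", 7L)
  t2 <- mk_jt("s2", "tumor", "chr1", 10L, 50L, "+", 9L)
  merged <- merge_cohort(list(t1, t2))
  expect_equal(nrow(merged), 3L)
  expect_setequal(merged$count[merged$chrom == "chr1"], c(5L, 9L))
  expect_error(merge_cohort(list(t1, t1)), class = "racescreen_validation_error")
  expect_equal(nrow(merge_cohort(list())), 0L)
})

test_that("annotation, normal-presence and support filters behave and commute", {
  cohort <- merge_cohort(list(
    mk_jt("s1", "tumor",
          "chr1", 10L, 50L, "+", 150L,    # novel, high support
          "chr1", 99L, 200L, "+", 120L,   # annotated
          "chr2", 5L, 25L, "-", 130L,     # seen in a normal
          "chr3", 7L, 77L, "+", 99L),     # novel, low support
    mk_jt("s2", "tumor", "chr3", 7L, 77L, "+", 5L)
  ))
  known <- tibble::tibble(chrom = "chr1", pos1 = 99L, pos2 = 200L, strand = "+")
  normals <- list(mk_jt("n1", "normal", "chr2", 5L, 25L, "-", 1L))

  fa <- filter_annotated(cohort, known)
  expect_equal(attr(fa, "n_removed"), 1L)
  fn <- filter_in_normals(cohort, normals)
  expect_false(any(fn$chrom == "chr2"))
  fs <- filter_min_support(cohort, 100L)
  expect_false(any(fs$chrom == "chr3"))   # max support 99 < 100

  # boundary: exactly 100 in one sample is kept, 99 is not
  b <- merge_cohort(list(mk_jt("s1", "tumor", "chr9", 1L, 9L, "+", 99L),
                         mk_jt("s2", "tumor", "chr9", 1L, 9L, "+", 100L)))
  expect_equal(nrow(filter_min_support(b, 100L)), 2L)  # kept via s2, counts preserved
  expect_equal(nrow(filter_min_support(b[b$sample_id == "s1", ], 100L)), 0L)

  # order invariance of the cascade
  o1 <- filter_min_support(filter_annotated(filter_in_normals(cohort, normals), known), 100L)
  o2 <- filter_in_normals(filter_annotated(filter_min_support(cohort, 100L), known), normals)
  key <- function(x) sort(paste(x$chrom, x$pos1, x$pos2, x$sample_id))
  expect_identical(key(o1), key(o2))

  # identity cases
  expect_equal(nrow(filter_annotated(cohort, known[0, ])), nrow(cohort))
  expect_equal(nrow(filter_in_normals(cohort, list())), nrow(cohort))
  expect_equal(nrow(filter_annotated(cohort, dplyr::select(cohort, chrom:strand))), 0L)
})

test_that("unknown strand matches either strand in set operations", {
  cohort <- merge_cohort(list(mk_jt("s1", "tumor", "chr1", 10L, 50L, "*", 150L)))
  known_plus <- tibble::tibble(chrom = "chr1", pos1 = 10L, pos2 = 50L, strand = "+")
  expect_equal(nrow(filter_annotated(cohort, known_plus)), 0L)
  cohort2 <- merge_cohort(list(mk_jt("s1", "tumor", "chr1", 10L, 50L, "-", 150L)))
  expect_equal(nrow(filter_annotated(cohort2, known_plus)), 1L)
})

test_that("surviving junctions keep their per-sample counts unchanged", {
  sim <- simulate_junction_cohorts(seed = 6L)
  cohort <- merge_cohort(sim$tumor_tables)
  out <- filter_cascade(cohort, sim$known, sim$normal_tables, 100L)
  joined <- dplyr::inner_join(out, cohort,
                              by = c("sample_id", "chrom", "pos1", "pos2", "strand"))
  expect_identical(joined$count.x, joined$count.y)
  # brute-force recount oracle for the support filter
  keys <- unique(paste(cohort$chrom, cohort$pos1, cohort$pos2))
  keep <- vapply(keys, function(k) {
    max(cohort$count[paste(cohort$chrom, cohort$pos1, cohort$pos2) == k]) >= 100L
  }, TRUE)
  fs <- filter_min_support(cohort, 100L)
  expect_setequal(unique(paste(fs$chrom, fs$pos1, fs$pos2)), keys[keep])
})

test_that("threshold strings parse and validation respects strict boundaries", {
  thr <- parse_threshold(c(">10", ">=2", ">= 1"))
  expect_equal(thr$min_reads, c(10L, 2L, 1L))
  expect_equal(thr$strict, c(TRUE, FALSE, FALSE))
  expect_error(parse_threshold("10+"), class = "racescreen_configuration_error")

  j <- list(chrom = "chrX", pos1 = 100L, pos2 = 500L, strand = "+")
  ds <- list(
    raceseq = list(mk_jt("a", "tumor", "chrX", 100L, 500L, "+", 11L),
                   mk_jt("b", "tumor", "chrX", 100L, 500L, "+", 10L),
                   mk_jt("c", "tumor", "chr1", 5L, 10L, "+", 99L)),
    tcga = list(mk_jt("d", "tumor", "chrX", 100L, 500L, "+", 1L),
                mk_jt("e", "tumor", "chr2", 7L, 20L, "+", 2L),
                mk_jt("f", "tumor", "chrX", 100L, 500L, "+", 2L))
  )
  vs <- validate_junction(j, ds, c(raceseq = ">10", tcga = ">=1"))
  # count 11 > 10 positive, count 10 is not; counts 1 and 2 both >= 1
  expect_equal(vs$n_positive[vs$dataset == "raceseq"], 1L)
  expect_equal(vs$n_total[vs$dataset == "raceseq"], 3L)
  expect_equal(vs$n_positive[vs$dataset == "tcga"], 2L)
  expect_equal(vs$fraction[vs$dataset == "tcga"], 2 / 3)

  expect_error(validate_junction(j, ds, c(raceseq = ">10")),
               class = "racescreen_configuration_error")

  # n_positive is non-increasing as a threshold tightens
  ns <- vapply(c(">=1", ">=2", ">2", ">10", ">11"), function(t) {
    validate_junction(j, ds["raceseq"], c(raceseq = t))$n_positive
  }, 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("validation fraction estimates a planted prevalence", {
  set.seed(12)
  prev <- 0.6; n <- 50L
  carriers <- which(runif(n) < prev)
  tables <- lapply(seq_len(n), function(i) {
    if (i %in% carriers) {
      mk_jt(paste0("s", i), "tumor", "chr5", 50L, 900L, "+", 3L)
    } else {
      mk_jt(paste0("s", i), "tumor", "chr1", 1L, 10L, "+", 2L)
    }
  })
  j <- list(chrom = "chr5", pos1 = 50L, pos2 = 900L, strand = "+")
  vs <- validate_junction(j, list(cohort = tables), c(cohort = ">=1"))
  # binomial 99% interval around 0.6 at n = 50
  expect_gt(vs$fraction, qbinom(0.005, n, prev) / n - 1e-9)
  expect_lt(vs$fraction, qbinom(0.995, n, prev) / n + 1e-9)
})

test_that("junction spans reproduce simple coordinate differences", {
  expect_equal(junction_span(list(pos1 = 51485170L, pos2 = 51504353L)), 19183L)
  expect_equal(junction_span(list(pos1 = 153536357L, pos2 = 153537981L)), 1624L)
  expect_equal(junction_span(list(pos1 = 10L, pos2 = 11L)), 1L)
  tbl <- tibble::tibble(pos1 = c(1L, 10L), pos2 = c(100L, 20L))
  expect_equal(junction_span(tbl), c(99L, 10L))
})
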