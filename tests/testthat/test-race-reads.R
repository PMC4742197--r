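test_that("adapter trimming removes exactly the aligned adapter suffix", {
  adapter <- default_adapter()
  insert <- random_dna(60, seed = 101)

  # full adapter prefix
  p1 <- make_pairs(paste0(adapter, insert))
  t1 <- trim_adapter(p1, adapter)
  expect_identical(t1$seq1, insert)
  expect_identical(nchar(t1$qual1), nchar(t1$seq1))

  # no adapter: untouched
  p2 <- make_pairs(insert)
  expect_identical(trim_adapter(p2, adapter)$seq1, insert)

  # last 10 bases of the adapter, min_overlap 5: those 10 bases removed;
  # oracle enumerates every adapter-suffix alignment
  tail10 <- substr(adapter, nchar(adapter) - 9L, nchar(adapter))
  read <- paste0(tail10, insert)
  oracle <- function(read, adapter, min_overlap) {
    na <- nchar(adapter)
    best <- 0L
    for (L in min_overlap:min(na, nchar(read))) {
      if (substr(adapter, na - L + 1L, na) == substr(read, 1L, L)) best <- max(best, L)
    }
    best
  }
  expect_equal(oracle(read, adapter, 5L), 10L)
  t3 <- trim_adapter(make_pairs(read), adapter, min_overlap = 5L,
                     max_mismatch_rate = 0)
  expect_identical(t3$seq1, insert)
  expect_equal(t3$trimmed1, 10L)
})

test_that("trimming never lengthens a read and is idempotent at zero mismatch rate", {
  adapter <- default_adapter()
  set.seed(55)
  seqs <- c(
    paste0(adapter, random_dna(40)),
    paste0(substr(adapter, 20, 30), random_dna(40)),
    random_dna(50),
    substr(adapter, 1, 12)
  )
  p <- make_pairs(seqs)
  t1 <- trim_adapter(p, adapter, max_mismatch_rate = 0)
  expect_true(all(nchar(t1$seq1) <= nchar(p$seq1)))
  t2 <- trim_adapter(t1, adapter, max_mismatch_rate = 0)
  expect_identical(t2$seq1, t1$seq1)
})

test_that("mismatch budget admits slightly divergent adapter prefixes", {
  adapter <- default_adapter()
  mutated <- adapter
  substr(mutated, 5, 5) <- if (substr(adapter, 5, 5) == "A") "C" else "A"
  read <- paste0(mutated, random_dna(30, seed = 9))
  expect_equal(trim_adapter(make_pairs(read), adapter,
                            max_mismatch_rate = 0)$trimmed1, 0L)
  expect_equal(trim_adapter(make_pairs(read), adapter,
                            max_mismatch_rate = 0.1)$trimmed1, nchar(adapter))
})

test_that("primer-anchored retrieval finds exactly the planted reads", {
  set.seed(77)
  ngsp <- random_dna(20)
  n <- 2000L
  backgrounds <- vapply(rep(120L, n), random_dna, "")
  planted_idx <- sort(sample(n, 12L))
  seqs <- backgrounds
  frag <- substr(ngsp, 6L, 20L)  # 15-base NGSP suffix fragment
  for (i in planted_idx) {
    s <- seqs[i]
    seqs[i] <- paste0(substr(s, 1, 40), frag, substr(s, 56, 120))
  }
  reads <- tibble::tibble(read_id = sprintf("r%04d", 1:n), seq = seqs)
  hits <- find_primer_reads(reads, ngsp, min_match_len = 15L)
  # a 120-mer random read collides with a specific 15-mer with prob ~ 1e-7,
  # so the retrieved set equals the planted set
  expect_setequal(hits$read_id, reads$read_id[planted_idx])
  expect_true(all(hits$match_len >= 15L))

  # full NGSP embedded: full-length match reported with its position
  r_full <- tibble::tibble(read_id = "full", seq = paste0(random_dna(10), ngsp, random_dna(10)))
  h_full <- find_primer_reads(r_full, ngsp, min_match_len = 15L)
  expect_equal(h_full$match_len, 20L)
  expect_equal(h_full$position, 11L)
  expect_equal(h_full$orientation, "forward")

  # reverse-complement occurrences are found and labelled
  r_rc <- tibble::tibble(read_id = "rc",
                         seq = paste0(random_dna(15), racescreen:::revcomp(ngsp)))
  h_rc <- find_primer_reads(r_rc, ngsp, min_match_len = 15L)
  expect_equal(h_rc$orientation, "reverse")

  expect_error(find_primer_reads(reads, ngsp, min_match_len = 21L),
               class = "racescreen_parameter_error")
})

test_that("raising min_match_len only shrinks the retrieved set", {
  fx <- fusion_fixture(n_pairs = 120L)
  tr <- trim_adapter(fx$pairs, default_adapter())
  ids <- lapply(c(12L, 18L, 24L),
                function(m) unique(find_primer_reads(tr, fx$ngsp, m)$read_id))
  expect_true(all(ids[[2]] %in% ids[[1]]))
  expect_true(all(ids[[3]] %in% ids[[2]]))
})

test_that("split mapping covers chimeric reads with segments from both genes", {
  ref <- simulate_reference(seed = 3)
  a <- ref$transcripts[["TX_GENE01"]]
  b <- ref$transcripts[["TX_GENE02"]]
  read <- paste0(substr(a, 101, 160), substr(b, 301, 360))
  sm <- split_map(read, ref, seed_len = 20L)
  expect_true(sm$chimeric)
  expect_setequal(sm$genes, c("GENE01", "GENE02"))
  expect_equal(nrow(sm$segments), 2L)
  expect_equal(sm$segments$read_start, c(1L, 61L))
  expect_equal(sm$segments$read_end, c(60L, 120L))
  expect_equal(sm$segments$t_start, c(101L, 301L))

  # single-transcript read: one segment, not chimeric
  sm1 <- split_map(substr(a, 51, 170), ref)
  expect_false(sm1$chimeric)
  expect_equal(nrow(sm1$segments), 1L)

  # absent sequence: empty result
  sm0 <- split_map(random_dna(80, seed = 1234), ref)
  expect_equal(nrow(sm0$segments), 0L)
  expect_false(sm0$chimeric)

  # reverse-complement reads map with segments reported on the read's axis
  smr <- split_map(racescreen:::revcomp(read), ref)
  expect_true(smr$chimeric)
  expect_setequal(smr$genes, c("GENE01", "GENE02"))

  expect_error(split_map(read, ref, seed_len = 10L),
               class = "racescreen_parameter_error")
})

test_that("scaffold construction honours exon boundaries and clips flanks", {
  ref <- simulate_reference(seed = 3)
  fus <- plant_fusion(ref, "GENE01", 3L, "GENE02", 4L)
  sc <- build_scaffold(ref, "GENE01", fus$break_a, "GENE02", fus$break_b, flank = 100L)
  expect_equal(nchar(sc$seq), 200L)
  expect_equal(sc$junction_offset, 100L)
  # scaffold sequence is the fusion transcript around the junction
  expect_identical(sc$seq, substr(fus$seq, fus$junction_pos - 99L, fus$junction_pos + 100L))

  # upstream transcript shorter than the flank: junction_offset clipped
  sc2 <- build_scaffold(ref, "GENE01", fus$break_a, "GENE02", fus$break_b, flank = 500L)
  expect_equal(sc2$junction_offset, 360L)   # 3 exons x 120 bp
  expect_equal(nchar(sc2$seq), 360L + 360L) # downstream side also 3 exons

  # mid-exon coordinate: not an intact splice boundary
  expect_error(build_scaffold(ref, "GENE01", fus$break_a - 5L, "GENE02", fus$break_b),
               class = "racescreen_breakpoint_error")
})

test_that("split/spanning counting matches simulator truth and boundary rules", {
  fx <- fusion_fixture(n_pairs = 300L)
  tr <- trim_adapter(fx$pairs, default_adapter())
  sc <- build_scaffold(fx$ref, "GENE01", fx$fus$break_a, "GENE02", fx$fus$break_b,
                       flank = 120L)
  cnt <- count_junction_reads(tr, sc, min_overhang = 10L)
  expected <- sum(fx$truth$overhang1 >= 10L | fx$truth$overhang2 >= 10L)
  expect_equal(cnt$split_reads, expected)

  # no reads
  empty <- fx$pairs[0, ]
  cnt0 <- count_junction_reads(empty, sc)
  expect_equal(c(cnt0$split_reads, cnt0$spanning_pairs), c(0L, 0L))

  # a read ending exactly at the junction has zero overhang: never split
  up_end <- substr(sc$seq, sc$junction_offset - 49L, sc$junction_offset)
  down_start <- substr(sc$seq, sc$junction_offset + 1L, sc$junction_offset + 50L)
  p <- make_pairs(up_end, down_start)
  cnt1 <- count_junction_reads(p, sc, min_overhang = 1L)
  expect_equal(cnt1$split_reads, 0L)
  # ...but that pair has one mate entirely on each side: spanning
  expect_equal(cnt1$spanning_pairs, 1L)
})

test_that("wild-type-only reads produce zero split reads", {
  fx <- fusion_fixture(n_pairs = 200L, abundances = c(0, 1))
  tr <- trim_adapter(fx$pairs, default_adapter())
  sc <- build_scaffold(fx$ref, "GENE01", fx$fus$break_a, "GENE02", fx$fus$break_b,
                       flank = 120L)
  # oracle scan: the junction 2*min_overhang-mer is absent from both wild types
  jmer <- substr(sc$seq, sc$junction_offset - 9L, sc$junction_offset + 10L)
  expect_false(grepl(jmer, fx$ref$transcripts[["TX_GENE01"]], fixed = TRUE))
  expect_false(grepl(jmer, fx$ref$transcripts[["TX_GENE02"]], fixed = TRUE))
  expect_equal(count_junction_reads(tr, sc, min_overhang = 10L)$split_reads, 0L)
})

test_that("junction k-mer counts are nested and exact on constructed reads", {
  fx <- fusion_fixture(n_pairs = 150L)
  sc <- build_scaffold(fx$ref, "GENE01", fx$fus$break_a, "GENE02", fx$fus$break_b,
                       flank = 60L)
  counts <- scaffold_kmer_search(fx$pairs, sc)
  expect_equal(counts$half_length, c(8, 10, 15, 20, 24))
  expect_true(all(diff(counts$n_reads) <= 0))

  # a read containing the full 48-mer is counted at every half-length
  k48 <- substr(sc$seq, sc$junction_offset - 23L, sc$junction_offset + 24L)
  c48 <- scaffold_kmer_search(make_pairs(paste0("ACGT", k48, "TTAA")), sc)
  expect_equal(c48$n_reads, rep(1L, 5))

  # 5 reads carrying only the 20-mer (h=10): counted at h in {8,10}, not 15
  k20 <- substr(sc$seq, sc$junction_offset - 9L, sc$junction_offset + 10L)
  p5 <- make_pairs(vapply(1:5, function(i) paste0(random_dna(20), k20, random_dna(20)), ""))
  c20 <- scaffold_kmer_search(p5, sc, half_lengths = c(8L, 10L, 15L))
  expect_equal(c20$n_reads, c(5L, 5L, 0L))

  expect_error(scaffold_kmer_search(fx$pairs, sc, half_lengths = 100L),
               class = "racescreen_parameter_error")
})

test_that("exon coverage computes RPK and per-gene counts from leftmost segments", {
  ref <- simulate_reference(seed = 3)
  # 10 synthetic single-segment reads inside exon 2 of GENE01 (t 121..240)
  segs <- tibble::tibble(
    read_id = sprintf("r%02d", 1:10), mate = 1L,
    read_start = 1L, read_end = 50L,
    transcript_id = "TX_GENE01", gene_id = "GENE01",
    t_start = 140L, t_end = 189L, strand = "+"
  )
  cov <- exon_coverage(segs, ref$gene_models)
  e2 <- cov$exons[cov$exons$gene_id == "GENE01" & cov$exons$exon_number == 2L, ]
  expect_equal(e2$count, 10L)
  expect_equal(e2$rpk, 10 / (120 / 1000))
  g <- cov$genes[cov$genes$gene_id == "GENE01", ]
  expect_equal(g$count, 10L)
  # exons without coverage are present at zero
  expect_equal(sum(cov$exons$count), 10L)
  expect_equal(nrow(cov$exons), nrow(ref$gene_models))
})

test_that("median-of-ratios size factors match the hand oracle and DESeq2", {
  counts <- matrix(c(10, 20, 30,
                     20, 40, 60), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  sf <- size_factors(counts)
  # hand oracle: geometric means (sqrt(200), sqrt(800), sqrt(1800));
  # ratios s1 = 1/sqrt(2) for every gene, s2 = sqrt(2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # proportional samples: factors in the same ratio, normalized counts equal
  expect_equal(unname(counts[, 2] / sf[["s2"]]), unname(counts[, 1] / sf[["s1"]]))

  set.seed(8)
  cnt <- matrix(rpois(30, 50) + 1L, nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  expect_equal(unname(size_factors(cnt)),
               unname(DESeq2::estimateSizeFactorsForMatrix(cnt)),
               tolerance = 1e-8)

  # genes with any zero are excluded from the median
  cnt0 <- rbind(cnt, g11 = c(0L, 100L, 100L))
  expect_equal(unname(size_factors(cnt0)[1]),
               unname(DESeq2::estimateSizeFactorsForMatrix(cnt0)[1]),
               tolerance = 1e-8)
})
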