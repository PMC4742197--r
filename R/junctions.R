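#' Splice-junction tables
#'
#' A junction is identified by chromosome, the 1-based coordinate of the
#' last base of the upstream exon (`pos1`), the 1-based coordinate of the
#' first base of the downstream exon (`pos2`) and strand. A junction table
#' holds one sample's junctions with their split-read support.
#'
#' @param sample_id sample identifier.
#' @param class one of `"tumor"`, `"normal"`, `"cell_line"`, `"body_map"`.
#' @param junctions tibble with columns `chrom`, `pos1`, `pos2`, `strand`
#'   (`"+"`, `"-"` or `"*"` for unknown) and `count` (positive integers).
#' @return tibble with columns `sample_id`, `class`, `chrom`, `pos1`,
#'   `pos2`, `strand`, `count`.
#' @export
junction_table <- function(sample_id, class, junctions) {
  junctions <- as_tibble(junctions)
  stopifnot(all(c("chrom", "pos1", "pos2", "strand", "count") %in% names(junctions)))
  if (any(junctions$pos2 <= junctions$pos1)) {
    abort("junction pos2 must exceed pos1", class = "racescreen_validation_error")
  }
  if (any(junctions$count < 1L)) {
    abort("junction counts must be positive", class = "racescreen_validation_error")
  }
  if (!all(junctions$strand %in% c("+", "-", "*"))) {
    abort("strand must be '+', '-' or '*'", class = "racescreen_validation_error")
  }
  tibble(sample_id = sample_id, class = class,
         chrom = as.character(junctions$chrom),
         pos1 = as.integer(junctions$pos1),
         pos2 = as.integer(junctions$pos2),
         strand = junctions$strand,
         count = as.integer(junctions$count))
}

#' Read a junction table from a BED12 or TSV file
#'
#' Accepts the aligner `junctions.bed` dialect -- BED12 records whose two
#' blocks flank one junction, with split-read support in the score column --
#' or a plain TSV (`chrom`, `pos1`, `pos2`, `strand`, `count`, with or
#' without a header). BED coordinates are 0-based half-open; the junction
#' donor base is the last base of block 1 and the acceptor base the first
#' base of block 2, both converted to 1-based.
#'
#' @param path input file.
#' @param sample_id,class sample metadata for the resulting table.
#' @return a [junction_table()].
#' @export
read_junction_bed <- function(path, sample_id, class = "tumor") {
  first <- readLines(path, n = 1L)
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (nfield >= 12L) {
    juncs <- parse_bed12_junctions(path)
  } else {
    header <- grepl("^chrom", first)
    juncs <- readr::read_tsv(path, col_names = if (header) TRUE else
      c("chrom", "pos1", "pos2", "strand", "count"),
      col_types = readr::cols(chrom = readr::col_character(),
                              strand = readr::col_character(),
                              .default = readr::col_integer()),
      progress = FALSE)
  }
  junction_table(sample_id, class, juncs)
}

# BED is 0-based half-open: block 1 covers [chromStart, chromStart + size1),
# so its last base is chromStart + size1 in 1-based coordinates; block 2
# starts at chromStart + blockStart2, i.e. chromStart + blockStart2 + 1
# in 1-based coordinates
parse_bed12_junctions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  map_dfr(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 12L) {
      abort(sprintf("line %d: expected 12 BED fields, got %d", i, length(f)),
            class = "racescreen_format_error")
    }
    n_blocks <- as.integer(f[10])
    if (n_blocks != 2L) {
      abort(sprintf("line %d: junction record has %d blocks (expected 2)", i, n_blocks),
            class = "racescreen_format_error")
    }
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    starts <- as.integer(strsplit(f[12], ",")[[1]])
    chrom_start <- as.integer(f[2])
    tibble(chrom = f[1],
           pos1 = chrom_start + sizes[1],
           pos2 = chrom_start + starts[2] + 1L,
           strand = if (f[6] %in% c("+", "-")) f[6] else "*",
           count = as.integer(f[5]))
  })
}

#' Write a junction table as plain TSV
#'
#' @param tbl a [junction_table()].
#' @param path output path.
#' @export
write_junction_tsv <- function(tbl, path) {
  atomic_write(function(p) {
    readr::write_tsv(select(tbl, "chrom", "pos1", "pos2", "strand", "count"), p)
  }, path)
  invisible(tbl)
}

junction_keys <- function(x) {
  paste(x$chrom, x$pos1, x$pos2, sep = ":")
}

# key match honouring unknown strand: equal coordinates, and strands equal
# or either unknown
keys_match <- function(x, ref) {
  kx <- junction_keys(x)
  kr <- junction_keys(ref)
  hit <- kx %in% kr
  if (!any(hit)) return(hit)
  # strand compatibility per coordinate key
  strands <- split(ref$strand, kr)
  vapply(seq_along(kx), function(i) {
    if (!hit[i]) return(FALSE)
    rs <- strands[[kx[i]]]
    any(rs == "*" | x$strand[i] == "*" | rs == x$strand[i])
  }, logical(1))
}

#' Merge per-sample junction tables into a cohort
#'
#' @param tables list of [junction_table()] tibbles with distinct sample
#'   ids.
#' @return long cohort tibble (union of junction keys, per-sample counts
#'   preserved).
#' @export
merge_cohort <- function(tables) {
  if (length(tables) == 0L) {
    return(tibble(sample_id = character(), class = character(),
                  chrom = character(), pos1 = integer(), pos2 = integer(),
                  strand = character(), count = integer()))
  }
  ids <- map_chr(tables, ~ unique(.x$sample_id)[1])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sample id across tables: %s", ids[duplicated(ids)][1]),
          class = "racescreen_validation_error")
  }
  bind_rows(tables)
}

#' Remove junctions annotated in a reference set
#'
#' @param cohort cohort tibble from [merge_cohort()].
#' @param known tibble of known junction keys (`chrom`, `pos1`, `pos2`,
#'   `strand`).
#' @return filtered cohort; attribute `n_removed` gives the number of
#'   distinct junctions removed.
#' @export
filter_annotated <- function(cohort, known) {
  if (nrow(cohort) == 0L || nrow(known) == 0L) {
    attr(cohort, "n_removed") <- 0L
    return(cohort)
  }
  drop <- keys_match(cohort, known)
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "n_removed") <- length(unique(junction_keys(cohort[drop, ])))
  out
}

#' Remove junctions detected in normal or body-map samples
#'
#' A junction present with any support (count >= 1) in any normal or
#' body-map table is not cancer-specific and is removed.
#'
#' @param cohort cohort tibble.
#' @param normal_tables list of junction tables from normal / body-map
#'   samples.
#' @return filtered cohort; attribute `n_removed` as in
#'   [filter_annotated()].
#' @export
filter_in_normals <- function(cohort, normal_tables) {
  if (length(normal_tables) == 0L || nrow(cohort) == 0L) {
    attr(cohort, "n_removed") <- 0L
    return(cohort)
  }
  normals <- bind_rows(normal_tables)
  drop <- keys_match(cohort, normals)
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "n_removed") <- length(unique(junction_keys(cohort[drop, ])))
  out
}

#' Keep junctions with high split-read support in at least one sample
#'
#' @param cohort cohort tibble.
#' @param min_reads minimum split-read count required in at least one
#'   sample (default 100).
#' @return filtered cohort (per-sample counts of survivors unchanged).
#' @export
filter_min_support <- function(cohort, min_reads = 100L) {
  stopifnot(min_reads >= 1L)
  if (nrow(cohort) == 0L) return(cohort)
  keep_keys <- cohort |>
    mutate(key = junction_keys(cohort)) |>
    group_by(.data$key) |>
    summarise(mx = max(.data$count), .groups = "drop") |>
    filter(.data$mx >= min_reads) |>
    pull("key")
  cohort[junction_keys(cohort) %in% keep_keys, , drop = FALSE]
}

#' Full novel-junction filter cascade
#'
#' Applies [filter_min_support()], [filter_annotated()] and
#' [filter_in_normals()] in sequence -- keep well-supported junctions,
#' discard annotated ones, discard anything seen in normal tissue.
#'
#' @inheritParams filter_annotated
#' @inheritParams filter_in_normals
#' @inheritParams filter_min_support
#' @return filtered cohort tibble.
#' @export
filter_cascade <- function(cohort, known, normal_tables, min_reads = 100L) {
  cohort |>
    filter_min_support(min_reads) |>
    filter_annotated(known) |>
    filter_in_normals(normal_tables)
}

#' Parse a threshold string such as ">10" or ">=2"
#'
#' @param x threshold strings.
#' @return tibble `min_reads`, `strict` (TRUE for `>`, FALSE for `>=`).
#' @export
parse_threshold <- function(x) {
  m <- stringr::str_match(x, "^\\s*(>=|>)\\s*(\\d+)\\s*$")
  if (anyNA(m[, 1])) {
    abort(sprintf("cannot parse threshold: '%s'", x[is.na(m[, 1])][1]),
          class = "racescreen_configuration_error")
  }
  tibble(min_reads = as.integer(m[, 3]), strict = m[, 2] == ">")
}

#' Validate one junction across cohorts
#'
#' For each named dataset, counts how many samples support the junction at
#' that dataset's threshold (`>` or `>=` a read count), as when probing a
#' candidate junction in external tumor/normal cohorts.
#'
#' @param j one junction: list or one-row tibble with `chrom`, `pos1`,
#'   `pos2`, `strand`.
#' @param datasets named list; each element is a list of
#'   [junction_table()]s or a single long cohort tibble.
#' @param thresholds named character vector or list of threshold strings
#'   (e.g. `c(raceseq = ">10", ccle = ">=2", tcga_tumor = ">=1")`); every
#'   dataset must have one.
#' @return a `validation_summary` tibble: `dataset`, `n_positive`,
#'   `n_total`, `fraction`; attribute `detail` has per-sample counts.
#' @export
validate_junction <- function(j, datasets, thresholds) {
  j <- as_tibble(as.list(j)[c("chrom", "pos1", "pos2", "strand")])
  missing_thr <- setdiff(names(datasets), names(thresholds))
  if (length(missing_thr)) {
    abort(sprintf("no threshold defined for dataset: %s", missing_thr[1]),
          class = "racescreen_configuration_error")
  }
  detail <- imap(datasets, function(ds, name) {
    tbl <- if (is.data.frame(ds)) ds else bind_rows(ds)
    all_samples <- unique(tbl$sample_id)
    hits <- tbl[keys_match(tbl, j), , drop = FALSE]
    tibble(dataset = name, sample_id = all_samples,
           count = coalesce(hits$count[match(all_samples, hits$sample_id)], 0L))
  }) |> bind_rows()
  out <- map_dfr(names(datasets), function(name) {
    thr <- parse_threshold(thresholds[[name]])
    d <- filter(detail, .data$dataset == name)
    pos <- if (thr$strict) d$count > thr$min_reads else d$count >= thr$min_reads
    tibble(dataset = name, n_positive = sum(pos), n_total = nrow(d),
           fraction = if (nrow(d)) sum(pos) / nrow(d) else NA_real_)
  })
  attr(out, "detail") <- detail
  class(out) <- c("validation_summary", class(out))
  out
}

#' Genomic span of a junction
#'
#' The distance `pos2 - pos1` between donor and acceptor base: small for
#' intragenic splices, tens of kilobases for read-through fusions between
#' adjacent genes.
#'
#' @param j a junction (list/one-row tibble) or a junction tibble.
#' @return integer vector of spans in bp.
#' @export
junction_span <- function(j) {
  as.integer(j$pos2) - as.integer(j$pos1)
}
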