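#' Exon-level expression matrix
#'
#' Container for a probe-set by sample matrix of log2 intensities, with
#' probe-set annotation (gene, genomic position, strand, transcriptional
#' order) and sample class labels. The matrix is stored samples-in-rows so
#' that row `i`, column `j` is the log2 signal of sample `i` at probe set
#' `j`.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   probe sets in columns (colnames = probe-set ids). All values must be
#'   finite; missing values are rejected.
#' @param samples tibble with columns `sample_id` and `class` (one of
#'   `"tumor"`, `"normal"`, `"cell_line"`).
#' @param probesets tibble with columns `probeset_id`, `gene_id`, `chrom`,
#'   `strand` (+1/-1), `start`, `end` (1-based inclusive) and optionally
#'   `order_index` (1..k per gene, transcriptional 5'->3'). When
#'   `order_index` is absent it is computed from genomic position and
#'   strand.
#' @return an `expr_matrix` object.
#' @export
expression_matrix <- function(values, samples, probesets) {
  samples <- as_tibble(samples)
  probesets <- as_tibble(probesets)
  if (anyDuplicated(samples$sample_id)) {
    abort(sprintf("duplicate sample id: %s",
                  samples$sample_id[duplicated(samples$sample_id)][1]),
          class = "racescreen_validation_error")
  }
  bad_class <- setdiff(unique(samples$class), c("tumor", "normal", "cell_line"))
  if (length(bad_class)) {
    abort(sprintf("unknown sample class: %s", bad_class[1]),
          class = "racescreen_validation_error")
  }
  if (!"order_index" %in% names(probesets)) {
    probesets <- infer_order_index(probesets)
  }
  probesets$order_index <- as.integer(probesets$order_index)
  probesets$strand <- as.integer(probesets$strand)
  validate_probeset_annotation(probesets)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("values must be a numeric matrix", class = "racescreen_validation_error")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    abort("expression values must all be finite (missing values are not supported)",
          class = "racescreen_validation_error")
  }
  if (!setequal(rownames(values), samples$sample_id) ||
      nrow(values) != nrow(samples)) {
    abort("matrix rows do not match sample table", class = "racescreen_validation_error")
  }
  if (!setequal(colnames(values), probesets$probeset_id) ||
      ncol(values) != nrow(probesets)) {
    abort("matrix columns do not match probe-set annotation",
          class = "racescreen_validation_error")
  }
  probesets <- arrange(probesets, .data$gene_id, .data$order_index)
  values <- values[samples$sample_id, probesets$probeset_id, drop = FALSE]
  structure(
    list(values = values, samples = samples, probesets = probesets),
    class = "expr_matrix"
  )
}

# order_index from genomic coordinates: ascending start on the + strand,
# descending on the - strand (transcriptional 5'->3')
infer_order_index <- function(probesets) {
  probesets |>
    group_by(.data$gene_id) |>
    mutate(order_index = if (first(.data$strand) == 1L) {
      rank(.data$start, ties.method = "first")
    } else {
      rank(-.data$start, ties.method = "first")
    }) |>
    ungroup() |>
    mutate(order_index = as.integer(.data$order_index))
}

validate_probeset_annotation <- function(probesets) {
  need <- c("probeset_id", "gene_id", "chrom", "strand", "start", "end", "order_index")
  miss <- setdiff(need, names(probesets))
  if (length(miss)) {
    abort(sprintf("annotation is missing columns: %s", paste(miss, collapse = ", ")),
          class = "racescreen_validation_error")
  }
  if (anyDuplicated(probesets$probeset_id)) {
    abort("duplicate probeset_id in annotation", class = "racescreen_validation_error")
  }
  if (!all(probesets$strand %in% c(1L, -1L))) {
    abort("strand must be +1 or -1", class = "racescreen_validation_error")
  }
  if (any(probesets$start > probesets$end)) {
    abort("genomic start > end in annotation", class = "racescreen_validation_error")
  }
  chk <- probesets |>
    group_by(.data$gene_id) |>
    summarise(
      ok_seq = identical(sort(.data$order_index), seq_len(n())),
      ok_strand = {
        o <- order(.data$order_index)
        if (first(.data$strand) == 1L) !is.unsorted(.data$start[o])
        else !is.unsorted(rev(.data$start[o]))
      },
      .groups = "drop"
    )
  bad <- chk$gene_id[!chk$ok_seq]
  if (length(bad)) {
    abort(sprintf("gene %s: order_index is not exactly 1..k", bad[1]),
          class = "racescreen_validation_error")
  }
  bad <- chk$gene_id[!chk$ok_strand]
  if (length(bad)) {
    abort(sprintf("gene %s: order_index disagrees with strand and genomic position", bad[1]),
          class = "racescreen_validation_error")
  }
  invisible(probesets)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d probe sets, %d genes\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$probesets$gene_id))))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$samples$class)),
                                  table(x$samples$class)), collapse = " "), "\n")
  invisible(x)
}

#' Read an exon-level expression matrix from TSV files
#'
#' The matrix file has a header row of sample ids and a first column
#' `probeset_id`; the annotation file has columns `probeset_id`, `gene_id`,
#' `chrom`, `strand`, `start`, `end` and optionally `order_index`; the
#' sample file has `sample_id` and `class`.
#'
#' @param matrix_path,annotation_path,samples_path paths to TSV files.
#' @return an [expression_matrix()] object.
#' @export
read_expression_matrix <- function(matrix_path, annotation_path, samples_path) {
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (names(raw)[1] != "probeset_id") {
    abort("matrix file must have first column 'probeset_id'",
          class = "racescreen_parse_error")
  }
  ids <- raw$probeset_id
  num <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L)
  for (jj in seq(2L, ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[jj]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      abort(sprintf("non-numeric value '%s' at row %d, column '%s'",
                    raw[[jj]][row], row, names(raw)[jj]),
            class = "racescreen_parse_error")
    }
    num[, jj - 1L] <- v
  }
  values <- t(num)
  rownames(values) <- names(raw)[-1]
  colnames(values) <- ids

  probesets <- readr::read_tsv(annotation_path, progress = FALSE,
                               col_types = readr::cols())
  probesets$strand <- as.integer(probesets$strand)
  unknown <- setdiff(ids, probesets$probeset_id)
  if (length(unknown)) {
    abort(sprintf("probeset id not present in annotation: %s", unknown[1]),
          class = "racescreen_annotation_error")
  }
  probesets <- filter(probesets, .data$probeset_id %in% ids)

  samples <- readr::read_tsv(samples_path, progress = FALSE, col_types = readr::cols())
  expression_matrix(values, samples, probesets)
}

#' Write an expression matrix to TSV files
#'
#' Inverse of [read_expression_matrix()]; round-trips values exactly (full
#' double precision).
#'
#' @param m an `expr_matrix`.
#' @param matrix_path,annotation_path,samples_path output paths.
#' @export
write_expression_matrix <- function(m, matrix_path, annotation_path, samples_path) {
  df <- as.data.frame(t(m$values))
  df <- cbind(probeset_id = colnames(m$values), df)
  atomic_write(function(p) {
    readr::write_tsv(tibble::as_tibble(df), p)
  }, matrix_path)
  atomic_write(function(p) readr::write_tsv(m$probesets, p), annotation_path)
  atomic_write(function(p) readr::write_tsv(m$samples, p), samples_path)
  invisible(m)
}

#' Per-probe-set normalization
#'
#' Centers each probe set at its cohort median and scales by its standard
#' deviation: `s[i,j] = (p[i,j] - median_j) / sd_j`, where the SD is the
#' usual n-1 sample standard deviation about the mean. On the normalized
#' scale a sample's value says how far, in cohort SDs, it deviates from the
#' cohort-typical signal at that probe set. Probe sets with `sd <=
#' sigma_floor` carry no usable signal and are excluded.
#'
#' @param m an `expr_matrix`.
#' @param sigma_floor probe sets with SD at or below this are excluded
#'   (default `1e-8`, i.e. effectively constant columns).
#' @return a `norm_matrix` object: list with `values` (samples x retained
#'   probe sets), `mu`, `sigma` (named per probe set), `excluded_probesets`,
#'   plus the sample and (retained) probe-set tables.
#' @export
normalize_probesets <- function(m, sigma_floor = 1e-8) {
  stopifnot(inherits(m, "expr_matrix"))
  if (nrow(m$values) < 2L) {
    abort("normalization needs at least 2 samples",
          class = "racescreen_insufficient_data_error")
  }
  mu <- apply(m$values, 2L, stats::median)
  sigma <- apply(m$values, 2L, stats::sd)
  excluded <- colnames(m$values)[sigma <= sigma_floor]
  keep <- setdiff(colnames(m$values), excluded)
  s <- sweep(m$values[, keep, drop = FALSE], 2L, mu[keep], `-`)
  s <- sweep(s, 2L, sigma[keep], `/`)
  structure(
    list(values = s,
         mu = mu[keep], sigma = sigma[keep],
         excluded_probesets = excluded,
         samples = m$samples,
         probesets = filter(m$probesets, .data$probeset_id %in% keep)),
    class = "norm_matrix"
  )
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d samples x %d probe sets (%d excluded, sigma floor)\n",
              nrow(x$values), ncol(x$values), length(x$excluded_probesets)))
  invisible(x)
}

#' Ordered normalized profile of one gene in one sample
#'
#' Returns the normalized values of a gene's retained probe sets for one
#' sample, ordered 5' to 3' along the transcript (`order_index` order, which
#' for minus-strand genes is descending genomic position).
#'
#' @param nm a `norm_matrix`.
#' @param gene_id,sample_id identifiers to look up.
#' @return named numeric vector (names = probeset ids) in 5'->3' order.
#' @export
gene_profile <- function(nm, gene_id, sample_id) {
  stopifnot(inherits(nm, "norm_matrix"))
  if (!sample_id %in% nm$samples$sample_id) {
    abort(sprintf("unknown sample: %s", sample_id), class = "racescreen_lookup_error")
  }
  ann <- filter(nm$probesets, .data$gene_id == !!gene_id)
  if (nrow(ann) == 0L) {
    abort(sprintf("gene %s has no retained probe sets (unknown gene, or every probe set excluded)",
                  gene_id),
          class = "racescreen_lookup_error")
  }
  ann <- arrange(ann, .data$order_index)
  stats::setNames(nm$values[sample_id, ann$probeset_id], ann$probeset_id)
}
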