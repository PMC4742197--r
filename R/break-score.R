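#' Expression break score of a single profile
#'
#' The expression break score (EBS) is a change-point statistic on a gene's
#' ordered (5'->3') normalized exon profile `s[1..k]`: the maximum over all
#' intragenic breakpoints `j in 1..k-1` of the absolute difference between
#' the mean of the 3' probe sets and the mean of the 5' probe sets,
#'
#'   `EBS = max_j | mean(s[(j+1)..k]) - mean(s[1..j]) |`.
#'
#' A large EBS flags a sample whose expression steps up (or down) partway
#' along the gene, the signature of a 3' fusion partner driven by a foreign
#' promoter. Ties in `|difference|` are broken toward the smallest `j`.
#'
#' @param s numeric vector, the normalized profile in 5'->3' order (length
#'   k >= 2).
#' @return one-row tibble: `ebs`, `breakpoint_index` (break falls between
#'   order positions j and j+1), `d_signed` (mean 3' minus mean 5' at the
#'   argmax), `direction` (`three_prime_up`, `five_prime_up` or `none`),
#'   `n5` = j, `n3` = k - j.
#' @export
ebs_profile <- function(s) {
  k <- length(s)
  if (k < 2L) {
    abort("EBS needs at least 2 probe sets", class = "racescreen_insufficient_probes_error")
  }
  s <- unname(s)
  cs <- cumsum(s)
  tot <- cs[k]
  j <- seq_len(k - 1L)
  mean5 <- cs[j] / j
  mean3 <- (tot - cs[j]) / (k - j)
  d <- mean3 - mean5
  # snap accumulated rounding to an exact zero so constant profiles report
  # direction "none" and ties break deterministically
  d[abs(d) <= 1e-10 * max(1, max(abs(s)))] <- 0
  jmax <- which.max(abs(d)) # which.max returns the first (smallest j) on ties
  ebs <- abs(d[jmax])
  direction <- if (ebs == 0) "none" else if (d[jmax] > 0) "three_prime_up" else "five_prime_up"
  tibble(
    ebs = ebs,
    breakpoint_index = as.integer(jmax),
    d_signed = d[jmax],
    direction = direction,
    n5 = as.integer(jmax),
    n3 = as.integer(k - jmax)
  )
}

#' EBS for every gene x sample combination
#'
#' Applies [ebs_profile()] to every gene's ordered profile in every sample.
#' Genes with fewer than 2 retained probe sets cannot host a breakpoint and
#' are reported in the skip log instead.
#'
#' @param nm a `norm_matrix` from [normalize_probesets()].
#' @return an `ebs_screen`: a tibble with columns `gene_id`, `sample_id`,
#'   `ebs`, `breakpoint_index`, `d_signed`, `direction`, `n5`, `n3`, and an
#'   attribute `skipped` (tibble of genes with < 2 retained probe sets).
#' @export
ebs_all <- function(nm) {
  stopifnot(inherits(nm, "norm_matrix"))
  ann <- arrange(nm$probesets, .data$gene_id, .data$order_index)
  by_gene <- split(ann$probeset_id, ann$gene_id)
  skipped <- tibble(
    gene_id = names(by_gene)[lengths(by_gene) < 2L],
    n_retained = lengths(by_gene)[lengths(by_gene) < 2L] |> as.integer()
  )
  by_gene <- by_gene[lengths(by_gene) >= 2L]
  samples <- rownames(nm$values)
  # vectorized over samples within each gene: all k-1 breakpoint contrasts
  # at once (ebs_profile is the scalar reference implementation)
  res <- imap(by_gene, function(ps, g) {
    s <- nm$values[, ps, drop = FALSE]
    k <- ncol(s)
    cs <- t(apply(s, 1L, cumsum))
    j <- seq_len(k - 1L)
    mean5 <- sweep(cs[, j, drop = FALSE], 2L, j, `/`)
    mean3 <- sweep(cs[, k] - cs[, j, drop = FALSE], 2L, k - j, `/`)
    d <- mean3 - mean5
    d[abs(d) <= 1e-10 * max(1, max(abs(s)))] <- 0
    jmax <- max.col(abs(d), ties.method = "first")
    d_at <- d[cbind(seq_len(nrow(d)), jmax)]
    tibble(
      gene_id = g, sample_id = samples,
      ebs = abs(d_at),
      breakpoint_index = as.integer(jmax),
      d_signed = d_at,
      direction = ifelse(d_at == 0, "none",
                         ifelse(d_at > 0, "three_prime_up", "five_prime_up")),
      n5 = as.integer(jmax), n3 = as.integer(k - jmax)
    )
  }) |> bind_rows()
  res <- select(res, "gene_id", "sample_id", "ebs", "breakpoint_index",
                "d_signed", "direction", "n5", "n3")
  res <- new_ebs_screen(res, skipped = skipped, samples = nm$samples)
  res
}

new_ebs_screen <- function(tbl, skipped, samples) {
  structure(tbl, skipped = skipped, sample_info = samples,
            class = c("ebs_screen", class(tbl)))
}

#' @export
print.ebs_screen <- function(x, ...) {
  cat(sprintf("<ebs_screen> %d gene x sample scores (%d genes skipped: < 2 probe sets)\n",
              nrow(x), nrow(attr(x, "skipped"))))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ebs_all
#' @param x an `ebs_screen`.
#' @param ... unused.
#' @method tidy ebs_screen
#' @export
tidy.ebs_screen <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname ebs_all
#' @method glance ebs_screen
#' @export
glance.ebs_screen <- function(x, ...) {
  tibble(
    n_genes = length(unique(x$gene_id)),
    n_samples = length(unique(x$sample_id)),
    n_skipped_genes = nrow(attr(x, "skipped")),
    max_ebs = max(x$ebs),
    frac_three_prime_up = mean(x$direction == "three_prime_up")
  )
}

#' Nomination parameters
#'
#' Tuning knobs for [nominate_candidates()]. `normal_ebs_max` implements the
#' rule that a gene showing an elevated break score in any normal sample is
#' not cancer-specific and is discarded; `min_probes_5`/`min_probes_3`
#' implement the robustness rule that more than one probe set must sit on
#' each side of the breakpoint, with `probe_count_overrides` letting named
#' very-high-scoring genes through on a single flanking probe set.
#'
#' @param top_n number of ranked candidates to keep.
#' @param min_probes_5,min_probes_3 minimum probe sets 5'/3' of the break.
#' @param probe_count_overrides gene ids exempt from the probe-count filter.
#' @param normal_ebs_max a gene is discarded when any normal sample reaches
#'   this EBS. The default 4 is calibrated against the null: for cohorts of
#'   ~100 samples and ~8 probe sets per gene, the no-break EBS of a single
#'   profile exceeds 2 about 10% of the time (the edge contrasts pit one
#'   probe set against the mean of the rest, SD ~ 1.07), so a cutoff of 2
#'   would flag most genes through normal-sample noise alone; 4 sits above
#'   the practical null range and fires on genuinely elevated normals.
#' @param excluded_genes user-supplied exclusion list (e.g. genes whose
#'   profiles are explained by paralogous probe cross-hybridisation or
#'   annotated alternative transcripts).
#' @export
nomination_params <- function(top_n = 25L, min_probes_5 = 2L, min_probes_3 = 2L,
                              probe_count_overrides = character(),
                              normal_ebs_max = 4,
                              excluded_genes = character()) {
  stopifnot(top_n >= 1L, min_probes_5 >= 1L, min_probes_3 >= 1L)
  structure(list(top_n = as.integer(top_n),
                 min_probes_5 = as.integer(min_probes_5),
                 min_probes_3 = as.integer(min_probes_3),
                 probe_count_overrides = probe_count_overrides,
                 normal_ebs_max = normal_ebs_max,
                 excluded_genes = excluded_genes),
            class = "nomination_params")
}

#' Nominate candidate 3' fusion partner genes
#'
#' From per-gene, per-sample break scores, selects genes whose 3' part is
#' overexpressed in an individual tumor or cell-line sample. For each gene
#' the deviating sample is the tumor/cell-line sample with the highest EBS
#' among profiles whose 3' side is up; the gene survives when (a) no normal
#' sample reaches `normal_ebs_max`, (b) at least `min_probes_5`/`min_probes_3`
#' probe sets flank the deviating breakpoint (unless overridden), and (c) it
#' is not on the exclusion list. Survivors are ranked by EBS and truncated
#' to `top_n`.
#'
#' @param results an `ebs_screen` (or plain tibble with its columns).
#' @param samples tibble `sample_id`, `class`; defaults to the sample info
#'   carried by the screen.
#' @param params a [nomination_params()] object.
#' @return tibble of candidates: `gene_id`, `deviating_sample_id`, `ebs`,
#'   `breakpoint_index`, `n5`, `n3`, `rank`, and `filter_log` (list column
#'   of per-filter pass records). The attribute `dropped` records every
#'   gene that failed and the first filter it failed.
#' @export
nominate_candidates <- function(results, samples = attr(results, "sample_info"),
                                params = nomination_params()) {
  if (nrow(results) == 0L) {
    return(tibble(gene_id = character(), deviating_sample_id = character(),
                  ebs = numeric(), breakpoint_index = integer(),
                  n5 = integer(), n3 = integer(), rank = integer(),
                  filter_log = list()))
  }
  res <- as_tibble(results) |>
    left_join(select(as_tibble(samples), "sample_id", "class"), by = "sample_id")
  if (anyNA(res$class)) {
    abort("sample(s) in results missing from sample table",
          class = "racescreen_validation_error")
  }

  normal_max <- res |>
    filter(.data$class == "normal") |>
    group_by(.data$gene_id) |>
    summarise(normal_ebs = max(.data$ebs, -Inf), .groups = "drop")

  dev <- res |>
    filter(.data$class %in% c("tumor", "cell_line"),
           .data$direction == "three_prime_up") |>
    group_by(.data$gene_id) |>
    slice_max(.data$ebs, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    left_join(normal_max, by = "gene_id") |>
    mutate(normal_ebs = coalesce(.data$normal_ebs, -Inf))

  dev <- dev |>
    mutate(
      pass_normal = .data$normal_ebs < params$normal_ebs_max,
      pass_probes = (.data$n5 >= params$min_probes_5 &
                       .data$n3 >= params$min_probes_3) |
        .data$gene_id %in% params$probe_count_overrides,
      pass_excluded = !.data$gene_id %in% params$excluded_genes
    )

  dropped <- dev |>
    filter(!(.data$pass_normal & .data$pass_probes & .data$pass_excluded)) |>
    mutate(reason = case_when(
      !.data$pass_normal ~ "elevated_in_normal",
      !.data$pass_probes ~ "too_few_flanking_probes",
      TRUE ~ "excluded_gene"
    )) |>
    select("gene_id", "sample_id", "ebs", "reason")

  out <- dev |>
    filter(.data$pass_normal, .data$pass_probes, .data$pass_excluded) |>
    arrange(desc(.data$ebs)) |>
    slice_head(n = params$top_n) |>
    mutate(rank = row_number(),
           filter_log = pmap(list(.data$pass_normal, .data$pass_probes, .data$pass_excluded),
                             function(a, b, c) {
                               tibble(filter = c("no_elevated_normal",
                                                 "flanking_probe_count",
                                                 "not_excluded"),
                                      pass = c(a, b, c))
                             })) |>
    select(gene_id = "gene_id", deviating_sample_id = "sample_id",
           "ebs", "breakpoint_index", "n5", "n3", "rank", "filter_log")
  attr(out, "dropped") <- dropped
  out
}

#' Write an EBS results table or candidate list to TSV
#'
#' @param x an `ebs_screen` tibble or a candidate tibble from
#'   [nominate_candidates()] (its `filter_log` list column is serialized as
#'   a JSON string).
#' @param path output path.
#' @export
write_results_tsv <- function(x, path) {
  x <- as_tibble(x)
  if ("filter_log" %in% names(x)) {
    x$filter_log <- map_chr(x$filter_log, function(fl) {
      jsonlite::toJSON(fl, auto_unbox = FALSE) |> as.character()
    })
  }
  # no quoting: the JSON column contains quote characters but never tabs,
  # and quoted TSV does not round-trip through readr
  atomic_write(function(p) readr::write_tsv(x, p, quote = "none", escape = "none"), path)
  invisible(x)
}
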