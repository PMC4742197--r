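#' Plan nested 5' RACE assays
#'
#' Bookkeeping for a RACE-seq experiment: one nested RACE assay per
#' candidate gene and per positive-control gene, run separately in every
#' sample, so the number of first-round PCR reactions is
#' `(n_candidates + n_controls) x n_samples`.
#'
#' @param candidates candidate gene ids (character vector, or a tibble with
#'   a `gene_id` column such as the output of [nominate_candidates()]).
#' @param control_genes positive-control gene ids; must be disjoint from
#'   the candidates.
#' @param samples sample ids (character vector, or tibble with `sample_id`).
#' @return an `assay_plan`: list with `assays` (tibble `gene_id`, `role`),
#'   `samples`, and `n_first_round_reactions`.
#' @export
plan_assays <- function(candidates, control_genes, samples) {
  cand <- if (is.data.frame(candidates)) candidates$gene_id else candidates
  samp <- if (is.data.frame(samples)) samples$sample_id else samples
  overlap <- intersect(cand, control_genes)
  if (length(overlap)) {
    abort(sprintf("gene(s) listed as both candidate and control: %s",
                  paste(overlap, collapse = ", ")),
          class = "racescreen_validation_error")
  }
  assays <- bind_rows(
    tibble(gene_id = cand, role = "candidate"),
    tibble(gene_id = control_genes, role = "control")
  )
  structure(
    list(assays = assays,
         samples = samp,
         n_first_round_reactions = nrow(assays) * length(samp)),
    class = "assay_plan"
  )
}

#' @export
print.assay_plan <- function(x, ...) {
  cat(sprintf("<assay_plan> %d assays (%d candidates + %d controls) x %d samples = %d first-round reactions\n",
              nrow(x$assays), sum(x$assays$role == "candidate"),
              sum(x$assays$role == "control"), length(x$samples),
              x$n_first_round_reactions))
  invisible(x)
}

#' Place primer design windows around an expression breakpoint
#'
#' For 5' RACE the gene-specific primer (GSP) and the nested primer (NGSP)
#' are reverse primers placed downstream (3') of the suspected breakpoint --
#' NGSP nearest the break, GSP further 3' -- while a forward internal
#' control primer (ICP) sits upstream (5') of the break. Windows are placed
#' in transcript coordinates and projected onto the genome through the exon
#' model (so a window may split across exons, and minus-strand windows run
#' in descending genomic coordinates).
#'
#' @param gene_model tibble of one transcript's exons: `exon_number` (1..n,
#'   transcriptional order), `chrom`, `start`, `end` (1-based genomic,
#'   inclusive), `strand` (+1/-1).
#' @param breakpoint_index the break falls between exon `breakpoint_index`
#'   and `breakpoint_index + 1`.
#' @param window_len window length in bp (default 300); windows are clipped
#'   at the transcript ends.
#' @param margin extra distance in bp between the break and the NGSP
#'   window, for assays placed deliberately further downstream (default 0).
#' @return a `race_assay`: list with `gene_id` (if present in the model),
#'   `breakpoint_index`, `windows` (tibble `role`, `t_start`, `t_end` in
#'   transcript coordinates) and `genomic` (the windows projected to
#'   genomic pieces).
#' @export
place_primer_windows <- function(gene_model, breakpoint_index, window_len = 300L,
                                 margin = 0L) {
  gm <- arrange(as_tibble(gene_model), .data$exon_number)
  n_ex <- nrow(gm)
  if (breakpoint_index < 1L || breakpoint_index >= n_ex) {
    abort(sprintf("breakpoint after exon %d leaves no exon on one side (gene has %d exons)",
                  breakpoint_index, n_ex),
          class = "racescreen_placement_error")
  }
  len <- gm$end - gm$start + 1L
  t_break <- sum(len[seq_len(breakpoint_index)])
  t_len <- sum(len)

  icp <- c(max(1L, t_break - window_len + 1L), t_break)
  ngsp <- c(t_break + margin + 1L, min(t_len, t_break + margin + window_len))
  gsp <- c(ngsp[2] + 1L, min(t_len, ngsp[2] + window_len))
  if (ngsp[1] > t_len || gsp[1] > t_len) {
    abort("transcript too short downstream of break for NGSP/GSP windows",
          class = "racescreen_placement_error")
  }
  windows <- tibble(
    role = c("icp", "ngsp", "gsp"),
    t_start = c(icp[1], ngsp[1], gsp[1]),
    t_end = c(icp[2], ngsp[2], gsp[2])
  )
  genomic <- windows |>
    pmap(function(role, t_start, t_end) {
      proj <- project_to_genomic(gm, t_start, t_end)
      proj$role <- role
      proj
    }) |>
    bind_rows() |>
    select("role", everything())
  structure(
    list(gene_id = if ("gene_id" %in% names(gm)) gm$gene_id[1] else NA_character_,
         breakpoint_index = as.integer(breakpoint_index),
         windows = windows, genomic = genomic),
    class = "race_assay"
  )
}

# project a transcript interval [a, b] (1-based) onto genomic pieces
project_to_genomic <- function(gm, a, b) {
  len <- gm$end - gm$start + 1L
  cum <- cumsum(len)
  first_t <- c(1L, head(cum, -1L) + 1L)
  pieces <- list()
  for (e in seq_len(nrow(gm))) {
    lo <- max(a, first_t[e]); hi <- min(b, cum[e])
    if (lo > hi) next
    off_lo <- lo - first_t[e]; off_hi <- hi - first_t[e]
    if (gm$strand[e] == 1L) {
      gstart <- gm$start[e] + off_lo; gend <- gm$start[e] + off_hi
    } else {
      gstart <- gm$end[e] - off_hi; gend <- gm$end[e] - off_lo
    }
    pieces[[length(pieces) + 1L]] <-
      tibble(chrom = gm$chrom[e], start = gstart, end = gend,
             strand = gm$strand[e], exon_number = gm$exon_number[e])
  }
  bind_rows(pieces)
}

#' Check a primer sequence against RACE design constraints
#'
#' Touchdown-PCR RACE primers are long and GC-rich: length 23-28 nt and GC
#' content 50-70%. Melting temperature is not computed here (the design
#' constraint Tm > 70 C belongs to the primer-design software) and is
#' reported as unchecked.
#'
#' @param seq primer sequence over A/C/G/T.
#' @return one-row tibble: `length`, `length_ok`, `gc_percent`, `gc_ok`,
#'   `tm_checked` (always `FALSE`).
#' @export
check_primer <- function(seq) {
  assert_dna(seq, "primer")
  n <- nchar(seq)
  gc <- 100 * (stringr::str_count(seq, "[GC]")) / n
  tibble(
    length = n,
    length_ok = n >= 23L & n <= 28L,
    gc_percent = gc,
    gc_ok = gc >= 50 & gc <= 70,
    tm_checked = FALSE
  )
}
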