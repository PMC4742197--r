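#' Plot a gene's exon-level profile across the cohort
#'
#' Shows each sample's normalized probe-set profile 5'->3', highlighting
#' one sample; the visual signature of a 3' fusion partner is a step up in
#' the highlighted profile partway along the gene.
#'
#' @param nm a `norm_matrix`.
#' @param gene_id gene to plot.
#' @param highlight_sample sample drawn in color on top of the cohort.
#' @return a ggplot object.
#' @export
plot_gene_profile <- function(nm, gene_id, highlight_sample = NULL) {
  ann <- nm$probesets |> filter(.data$gene_id == !!gene_id) |> arrange(.data$order_index)
  if (nrow(ann) == 0L) abort(sprintf("unknown gene: %s", gene_id),
                             class = "racescreen_lookup_error")
  df <- as_tibble(nm$values[, ann$probeset_id, drop = FALSE],
                  rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "probeset_id", values_to = "s") |>
    left_join(select(ann, "probeset_id", "order_index"), by = "probeset_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$order_index, y = .data$s,
                                        group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.25, color = "grey50") +
    ggplot2::labs(x = "probe set (5' to 3')", y = "normalized expression (s)",
                  title = gene_id) +
    ggplot2::theme_minimal()
  if (!is.null(highlight_sample)) {
    p <- p + ggplot2::geom_line(data = filter(df, .data$sample_id == highlight_sample),
                                color = "firebrick", linewidth = 1)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rank plot of an EBS screen
#'
#' @param object an `ebs_screen`.
#' @param top_n number of top gene x sample scores to label.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ebs_screen
#' @export
autoplot.ebs_screen <- function(object, top_n = 25L, ...) {
  df <- as_tibble(object) |>
    arrange(desc(.data$ebs)) |>
    mutate(rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ebs)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = slice_head(df, n = top_n), color = "firebrick") +
    ggplot2::labs(x = "rank", y = "expression break score (EBS)") +
    ggplot2::theme_minimal()
}

#' Per-exon RPK coverage plot
#'
#' Read coverage in reads per kilobase of exon sequence along a gene, the
#' standard display for showing which exons of an upstream partner a RACE
#' assay amplified.
#'
#' @param object a `coverage_table`.
#' @param gene_id gene to display.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot coverage_table
#' @export
autoplot.coverage_table <- function(object, gene_id = NULL, ...) {
  df <- object$exons
  if (!is.null(gene_id)) df <- filter(df, .data$gene_id == !!gene_id)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$exon_number), y = .data$rpk)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(sample_id ~ gene_id, scales = "free_x") +
    ggplot2::labs(x = "exon", y = "reads per kilobase exon (RPK)") +
    ggplot2::theme_minimal()
}

#' Validation-fraction plot
#'
#' @param object a `validation_summary` from [validate_junction()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot validation_summary
#' @export
autoplot.validation_summary <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$dataset, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = scales_percent) +
    ggplot2::labs(x = NULL, y = "samples positive") +
    ggplot2::theme_minimal()
}

scales_percent <- function(x) paste0(round(100 * x), "%")
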