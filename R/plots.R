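#' MAF spectrum histogram
#'
#' @param maf A tibble with a `maf` column (e.g. [site_maf()] or the `maf`
#'   component of a [qc_report()]).
#' @param binwidth Histogram bin width (default 0.01).
#' @return A ggplot.
#' @export
plot_maf_spectrum <- function(maf, binwidth = 0.01) {
  ggplot2::ggplot(maf[!is.na(maf$maf), ], ggplot2::aes(x = .data$maf)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "minor allele frequency", y = "SNPs") +
    ggplot2::theme_minimal()
}

#' Missingness versus read depth
#'
#' The per-sample relationship between mean sequencing depth and the
#' proportion of missing calls.
#'
#' @param qc A [qc_report()].
#' @return A ggplot.
#' @export
plot_missingness_depth <- function(qc) {
  x <- qc$sample_stats
  ggplot2::ggplot(x, ggplot2::aes(x = .data$mean_depth,
                                  y = 1 - .data$call_rate)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "mean read depth (X)", y = "proportion missing") +
    ggplot2::theme_minimal()
}

#' SNPs-per-probe distribution
#'
#' @param qc A [qc_report()].
#' @return A ggplot.
#' @export
plot_snps_per_probe <- function(qc) {
  ggplot2::ggplot(qc$snps_per_probe,
                  ggplot2::aes(x = .data$n_snps, y = .data$n_probes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "SNPs per probe", y = "probes") +
    ggplot2::theme_minimal()
}

#' Mismatch profiles per relationship class
#'
#' Histogram of pairwise mismatch percentages by relationship, the
#' clone-identification profile view.
#'
#' @param pairs A pair table (`relationship`, `pct_mismatch`, `included`).
#' @param binwidth Histogram bin width in percentage points.
#' @return A ggplot.
#' @export
plot_mismatch_profiles <- function(pairs, binwidth = 2) {
  x <- pairs[pairs$included & !is.na(pairs$pct_mismatch), ]
  ggplot2::ggplot(x, ggplot2::aes(x = .data$pct_mismatch,
                                  fill = .data$relationship)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~relationship, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "% mismatching SNPs", y = "pairs") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Panel gaps bar chart
#'
#' Ranked view of the ramet/full-sib discrimination gap across panels, with
#' the parent-offspring and unrelated gaps alongside.
#'
#' @param gaps Output of [rank_panels_by_gap()].
#' @return A ggplot.
#' @export
plot_panel_gaps <- function(gaps) {
  long <- tidyr::pivot_longer(
    gaps[, c("panel", "gap_fullsib", "gap_parent_offspring", "gap_unrelated")],
    cols = -"panel", names_to = "class", values_to = "gap")
  long$panel <- factor(long$panel, levels = gaps$panel)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$panel, y = .data$gap,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "gap (% mismatch)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a qc_report
#' @param object A [qc_report()].
#' @param which One of `"maf"`, `"missingness"`, `"snps_per_probe"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qc_report <- function(object, which = c("maf", "missingness",
                                                 "snps_per_probe"), ...) {
  which <- match.arg(which)
  switch(which,
         maf = plot_maf_spectrum(object$maf),
         missingness = plot_missingness_depth(object),
         snps_per_probe = plot_snps_per_probe(object))
}

#' Autoplot a filter_result
#'
#' Per-stage survival of genes, probes and SNPs down the pipeline.
#'
#' @param object A `filter_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.filter_result <- function(object, ...) {
  rep <- object$report
  rep$stage <- factor(rep$stage, levels = rep$stage)
  long <- tidyr::pivot_longer(rep[, c("stage", "n_genes", "n_probes", "n_snps")],
                              cols = -"stage", names_to = "unit",
                              values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$n,
                                     group = .data$unit,
                                     colour = .data$unit)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "surviving (log scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
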