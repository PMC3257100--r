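#' Plot success-rate curves
#'
#' Success rate (fraction of systems with a hit in the top NP) against NP,
#' optionally with the random-ranking baseline for comparison.
#'
#' @param curve Tibble from [success_rate_curve()].
#' @param baseline Optional tibble from [random_baseline_curve()].
#' @return A ggplot object.
#' @export
plot_success_rate <- function(curve, baseline = NULL) {
  curve$ranking <- "score"
  if (!is.null(baseline)) {
    baseline$ranking <- "random"
    curve <- dplyr::bind_rows(curve, baseline)
  }
  ggplot2::ggplot(curve, ggplot2::aes(.data$np, .data$success_rate,
                                      colour = .data$ranking)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "NP (top predictions considered)",
                  y = "success rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot score against ligand RMSD for one decoy set
#'
#' The per-system discrimination picture: a well-behaved scoring function
#' gives near-native (low-RMSD) decoys the most negative scores.
#'
#' @param ranked Per-decoy tibble with `l_rmsd`, `sn_score` (and optionally
#'   `is_hit`), e.g. from [evaluate_decoys()].
#' @param hit_threshold Threshold drawn as a vertical reference line.
#' @return A ggplot object.
#' @export
plot_score_rmsd <- function(ranked, hit_threshold = 4.0) {
  p <- ggplot2::ggplot(ranked, ggplot2::aes(.data$l_rmsd, .data$sn_score))
  if ("is_hit" %in% names(ranked))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$is_hit), alpha = 0.7)
  else p <- p + ggplot2::geom_point(alpha = 0.7)
  p +
    ggplot2::geom_vline(xintercept = hit_threshold, linetype = 2) +
    ggplot2::labs(x = "ligand RMSD (Angstrom)", y = "Sn score",
                  colour = "hit") +
    ggplot2::theme_minimal()
}

#' @describeIn build_network degree/strength scatter of the network's
#'   residues, coloured by chain.
#' @param object A `wrn_network`.
#' @exportS3Method ggplot2::autoplot
autoplot.wrn_network <- function(object, ...) {
  ggplot2::ggplot(node_metrics(object),
                  ggplot2::aes(.data$degree, .data$strength,
                               colour = .data$chain)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "degree k", y = "node strength S_i", colour = "chain") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
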