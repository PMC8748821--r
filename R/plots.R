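#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a phenotype effect map
#'
#' Per-region correlation with the phenotype, ordered by effect size and
#' colored by significance.
#'
#' @param object An `sfc_effect_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sfc_effect_map <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::arrange(.data$r) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$r,
                                  fill = .data$selected)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = sprintf("q < %.2f",
                                              attr(object, "alpha"))) +
    ggplot2::labs(x = "region (ranked)",
                  y = sprintf("r (degree vs %s)", attr(object, "phenotype")),
                  title = "Phenotype-degree effect map") +
    ggplot2::theme_minimal()
}

#' Plot network-level step-degree trajectories of a group contrast
#'
#' t-statistics per network across step distances; significant tests
#' (q < 0.05) are emphasized.
#'
#' @param object An `sfc_contrast` with a network-level table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sfc_contrast <- function(object, ...) {
  if (is.null(object$network)) abort_input("contrast has no network-level table")
  ggplot2::ggplot(object$network,
                  ggplot2::aes(x = .data$step, y = .data$t,
                               color = .data$network)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$q < 0.05), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = "q < 0.05") +
    ggplot2::labs(x = "step distance", y = "t statistic",
                  title = sprintf("%s vs %s step-degree contrast",
                                  object$groups[["test"]],
                                  object$groups[["reference"]])) +
    ggplot2::theme_minimal()
}

#' Plot a behavior association grid
#'
#' Heatmap of network x TFEQ-score correlations, annotated with
#' significance after FDR.
#'
#' @param object An `sfc_behavior`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sfc_behavior <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(score = factor(.data$score, levels = tfeq_score_names),
                  label = ifelse(.data$q < 0.05,
                                 sprintf("%.2f*", .data$r),
                                 sprintf("%.2f", .data$r)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$network,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1) * max(abs(d$r))) +
    ggplot2::labs(x = "TFEQ score", y = "network",
                  title = "Network step degree vs eating behavior",
                  subtitle = "* q < 0.05 (BH-FDR across the grid)") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap stability of the effect map
#'
#' @param object An `sfc_stability`.
#' @param ... Unused.
#' @return A ggplot histogram of per-iteration spatial correlations.
#' @export
autoplot.sfc_stability <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$stability)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = attr(object, "mean"),
                        color = "firebrick") +
    ggplot2::labs(x = "spatial correlation with full-sample map",
                  y = "iterations",
                  title = sprintf("Bootstrap stability: %.2f +/- %.2f",
                                  attr(object, "mean"), attr(object, "sd"))) +
    ggplot2::theme_minimal()
}
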