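# ggplot2 views of the standard result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an inflammation time course
#'
#' @param object An `inflammation_sim`.
#' @param ... Unused.
#' @return A ggplot: inflammation score (dead epithelial cells) and
#'   grid-mean cytokine concentrations against iteration.
#' @method autoplot inflammation_sim
#' @export
autoplot.inflammation_sim <- function(object, ...) {
  ggplot2::ggplot(object$course, ggplot2::aes(x = .data$t, y = .data$score)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(
      x = "iteration", y = "inflammation score (dead epithelial cells)",
      title = sprintf("S = %g, preset %s, seed %d",
                      object$params$stimulus, object$params$aging$preset,
                      object$seed)) +
    ggplot2::theme_minimal()
}

#' Plot mean inflammation courses of an experiment
#'
#' Mean score over replicates with a standard-error ribbon, one panel per
#' stimulus level, coloured by aging preset.
#'
#' @param object An `inflammation_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot inflammation_experiment
#' @export
autoplot.inflammation_experiment <- function(object, ...) {
  course <- experiment_report(object)$course
  ggplot2::ggplot(course,
                  ggplot2::aes(x = .data$t, y = .data$mean_score,
                               colour = .data$preset, fill = .data$preset)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_score - .data$se_score,
                                      ymax = .data$mean_score + .data$se_score),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stimulus), labeller = "label_both") +
    ggplot2::labs(x = "iteration", y = "mean inflammation score") +
    ggplot2::theme_minimal()
}

#' Plot transfer-entropy distributions per condition
#'
#' @param experiment An `inflammation_experiment`.
#' @return A ggplot of the defined pairwise TE densities, one panel per
#'   stimulus, coloured by preset.
#' @export
plot_te_distribution <- function(experiment) {
  te <- experiment_report(experiment)$te_distribution
  te <- te[!is.na(te$te), ]
  ggplot2::ggplot(te, ggplot2::aes(x = .data$te, colour = .data$preset)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stimulus), labeller = "label_both",
                        scales = "free_y") +
    ggplot2::labs(x = "transfer entropy M -> F (bits)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot betweenness-centrality distributions
#'
#' @param experiment An `inflammation_experiment`.
#' @return A ggplot of pooled node betweenness per part (macrophage /
#'   fibroblast), coloured by preset, one panel per stimulus and part.
#' @export
plot_betweenness <- function(experiment) {
  b <- experiment_report(experiment)$betweenness
  ggplot2::ggplot(b, ggplot2::aes(x = .data$betweenness,
                                  colour = .data$preset)) +
    ggplot2::geom_density() +
    ggplot2::facet_grid(ggplot2::vars(.data$kind),
                        ggplot2::vars(.data$stimulus)) +
    ggplot2::labs(x = "normalised betweenness centrality", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot the F/M centrality ratio per condition
#'
#' @param experiment An `inflammation_experiment`.
#' @return A ggplot of mean F/M with standard-error bars against stimulus,
#'   coloured by preset, with the F/M = 1 balance line.
#' @export
plot_fm_ratio <- function(experiment) {
  fm <- experiment_report(experiment)$fm
  ggplot2::ggplot(fm, ggplot2::aes(x = factor(.data$stimulus),
                                   y = .data$mean_fm,
                                   colour = .data$preset,
                                   group = .data$preset)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_fm - .data$se_fm,
                                        ymax = .data$mean_fm + .data$se_fm),
                           width = 0.15) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stimulus S", y = "F/M betweenness ratio") +
    ggplot2::theme_minimal()
}
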