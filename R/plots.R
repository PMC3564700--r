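# ggplot2 displays for the two result types.

#' Plot a perturbation-robustness curve
#'
#' Consensus-to-original symmetric distance against the mutation level,
#' with the per-replicate RF distribution underneath as jittered points.
#'
#' @param object An `rcm_robustness` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rcm_robustness <- function(object, ...) {
  per_rep <- tidy(object)
  curve <- glance(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$rate * 100)) +
    ggplot2::geom_jitter(data = per_rep,
                         ggplot2::aes(y = .data$rf), width = 0.3,
                         height = 0.15, alpha = 0.15, colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rf_consensus),
                       colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(y = .data$rf_consensus),
                        colour = "#2166ac", size = 2) +
    ggplot2::labs(x = "mutation level (%)",
                  y = "symmetric distance to original tree",
                  title = "Robustness of the RCM tree under perturbation",
                  subtitle = "line: MRe consensus vs original; points: individual replicates") +
    ggplot2::theme_minimal()
}

#' Plot simulation-benchmark accuracy
#'
#' Distribution of normalized symmetric distances to the true topology,
#' per reconstruction method.
#'
#' @param object An `rcm_benchmark` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rcm_benchmark <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$rf_normalized,
                               fill = .data$method)) +
    ggplot2::geom_histogram(binwidth = 1 / 26, boundary = 0,
                            position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "normalized symmetric distance to true tree",
                  y = "families",
                  title = sprintf("Reconstruction accuracy (%s model)",
                                  object$config$model)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
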