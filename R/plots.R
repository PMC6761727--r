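#' Plot the distribution of methylation levels by context
#'
#' Histograms of observed beta per sequence context — the standard
#' first look at a methylome (CpG mass near 1, CpH mass near 0).
#'
#' @param x A cytosine matrix.
#' @param samples Samples to pool (default: all).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_beta_distribution <- function(x, samples = sample_ids(x), bins = 40) {
  b <- beta_values(x)[, samples, drop = FALSE]
  d <- tibble::tibble(
    context = rep(x$context, ncol(b)),
    beta = as.vector(b)
  )
  d <- d[!is.na(d$beta), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::facet_wrap(~context, scales = "free_y") +
    ggplot2::labs(x = expression(beta), y = "cytosines") +
    ggplot2::theme_bw()
}

#' Plot developmental trajectory clusters
#'
#' Scatter of per-region glial versus neuronal age slopes coloured by
#' cluster, with centroids marked.
#'
#' @param object A `traj_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.traj_clusters <- function(object, ...) {
  a <- tidy(object)
  centers <- tibble::as_tibble(object$centers)
  ggplot2::ggplot(a, ggplot2::aes(x = .data$glia_slope,
                                  y = .data$neuron_slope,
                                  colour = factor(.data$group))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = centers,
                        ggplot2::aes(x = .data$glia_slope,
                                     y = .data$neuron_slope),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "glial slope (beta / year)",
                  y = "neuronal slope (beta / year)",
                  colour = "group") +
    ggplot2::theme_bw()
}

#' Plot a bump-hunting run
#'
#' Candidate-region areas against the permutation null maxima, marking
#' the regions significant at FWER below 5%.
#'
#' @param object A `bumphunt` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bumphunt <- function(object, ...) {
  r <- object$regions
  r$significant <- r$fwer < 0.05
  ggplot2::ggplot(r, ggplot2::aes(x = .data$area, fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = stats::quantile(object$perm_max, 0.95),
                        linetype = 2) +
    ggplot2::labs(x = "region area", y = "candidate regions",
                  fill = "FWER < 5%",
                  caption = "dashed: 95th percentile of permutation maxima") +
    ggplot2::theme_bw()
}

#' Plot autocorrelation by lag and cell fraction
#'
#' @param result An `autocorr_result` tibble (rows from one or more
#'   [autocorrelation()] calls may be stacked).
#' @return A ggplot object.
#' @export
plot_autocorrelation <- function(result) {
  ggplot2::ggplot(result,
                  ggplot2::aes(x = .data$lag, y = .data$acf,
                               colour = .data$cell_fraction,
                               linetype = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "lag (sites)", y = "mean autocorrelation") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
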