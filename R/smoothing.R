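#' Local-likelihood smoothing of CpG methylation levels
#'
#' Per-sample smoothing of beta along the genome, the substrate for
#' segmentation and region detection. At each site a weighted quadratic in
#' position is fit over the smallest symmetric window containing at least
#' `min_sites` sites and spanning at least `min_width` bp, with
#' tricube(distance) x total-read-count weights (zero-coverage sites get
#' zero weight but are still evaluated), and evaluated at the site; values
#' are clamped to \[0, 1\]. A chromosome with fewer than `min_sites` sites is
#' passed through unsmoothed with a warning.
#'
#' @param x A coverage-filtered cytosine matrix (typically CpG only).
#' @param samples Samples to smooth (default: all).
#' @param min_sites Minimum sites per window.
#' @param min_width Minimum window span in bp.
#' @return `x` with an additional `smoothed` matrix-column (one column per
#'   smoothed sample); attribute `smooth_params` records the window
#'   parameters.
#' @export
smooth_betas <- function(x, samples = sample_ids(x),
                         min_sites = 70, min_width = 1000) {
  b <- beta_values(x)[, samples, drop = FALSE]
  cov <- total_counts(x)[, samples, drop = FALSE]
  out <- matrix(NA_real_, nrow(x), length(samples),
                dimnames = list(NULL, samples))
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    if (length(idx) < min_sites) {
      warning("chromosome '", ch, "' has fewer than ", min_sites,
              " sites; raw beta passed through")
      out[idx, ] <- b[idx, , drop = FALSE]
      next
    }
    out[idx, ] <- .smooth_tracks_cpp(
      as.integer(x$pos[idx]),
      b[idx, , drop = FALSE],
      matrix(as.numeric(cov[idx, , drop = FALSE]), length(idx)),
      as.integer(min_sites), as.numeric(min_width)
    )
  }
  res <- x
  res$smoothed <- out
  attr(res, "smooth_params") <- list(min_sites = min_sites,
                                     min_width = min_width)
  res
}

#' @rdname smooth_betas
#' @param x A smoothed cytosine matrix from [smooth_betas()].
#' @export
smoothed_values <- function(x) {
  sm <- unclass(x)$smoothed
  if (is.null(sm)) stop("no `smoothed` column; run smooth_betas() first")
  sm
}
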