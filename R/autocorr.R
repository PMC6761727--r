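#' Context-stratified methylation autocorrelation
#'
#' Autocorrelation of beta along ordered cytosines, computed per position
#' cluster (maximum gap `max_gap`, at least `min_sites` cytosines) or —
#' when `regions` is supplied — per region, up to `max_lag` site lags with
#' the conventional biased (divide-by-n) estimator. The lag is in site
#' index, not base pairs. Within a cluster, values are centred on the
#' cluster mean and missing betas contribute zero after centring;
#' zero-variance clusters are skipped and counted. Cluster-level values are
#' averaged per sample and then across the samples of each cell fraction.
#'
#' @param x A cytosine matrix (filter to the contexts of interest first or
#'   use `context`).
#' @param meta Sample metadata.
#' @param context One of `"CpG"`, `"CpH"`, `"CHG"`, `"CHH"`, `"allC"`.
#' @param max_gap Cluster gap in bp (ignored when `regions` given).
#' @param min_sites Minimum cytosines per cluster/region.
#' @param max_lag Largest site lag.
#' @param regions Optional region tibble restricting the computation to
#'   sites inside each region (within-DMR autocorrelation).
#' @return An `autocorr_result` tibble: `context`, `scope`,
#'   `cell_fraction`, `lag`, `acf`, with attributes `n_groups_used` and
#'   `n_groups_skipped`.
#' @export
autocorrelation <- function(x, meta,
                            context = c("CpG", "CpH", "CHG", "CHH", "allC"),
                            max_gap = 1000, min_sites = 5, max_lag = 4,
                            regions = NULL) {
  context <- match.arg(context)
  keep <- switch(context,
    CpG = x$context == "CpG",
    CpH = x$context %in% c("CHG", "CHH"),
    CHG = x$context == "CHG",
    CHH = x$context == "CHH",
    allC = rep(TRUE, nrow(x))
  )
  xs <- x[keep, ]
  if (nrow(xs) == 0) stop("no sites of context ", context)
  b <- beta_values(xs)

  if (is.null(regions)) {
    grp <- cluster_positions(
      tibble::tibble(chrom = xs$chrom, pos = xs$pos), max_gap
    )$cluster
    scope <- "genome-wide clusters"
  } else {
    grp <- rep(NA_integer_, nrow(xs))
    for (i in seq_len(nrow(regions))) {
      inside <- xs$chrom == regions$chrom[i] & xs$pos > regions$start[i] &
        xs$pos <= regions$end[i]
      grp[inside & is.na(grp)] <- i
    }
    scope <- "within regions"
  }

  groups <- split(seq_len(nrow(xs))[!is.na(grp)], grp[!is.na(grp)])
  groups <- groups[lengths(groups) >= min_sites]
  n_samp <- ncol(b)
  acc <- array(NA_real_, c(length(groups), n_samp, max_lag))
  skipped <- 0L
  for (g in seq_along(groups)) {
    X <- b[groups[[g]], , drop = FALSE]
    n <- nrow(X)
    mu <- colMeans(X, na.rm = TRUE)
    Xc <- sweep(X, 2L, mu)
    Xc[is.na(Xc)] <- 0
    denom <- colSums(Xc^2)
    ok <- denom > 0
    if (!any(ok)) {
      skipped <- skipped + 1L
      next
    }
    for (k in seq_len(min(max_lag, n - 1L))) {
      num <- colSums(Xc[seq_len(n - k), , drop = FALSE] *
                       Xc[seq(k + 1L, n), , drop = FALSE])
      acc[g, ok, k] <- num[ok] / denom[ok]
    }
  }

  per_sample <- apply(acc, c(2, 3), mean, na.rm = TRUE)
  rownames(per_sample) <- colnames(b)
  out <- purrr::map_dfr(unique(meta$cell_fraction), function(cf) {
    ss <- intersect(meta$sample_id[meta$cell_fraction == cf], colnames(b))
    if (length(ss) == 0) return(NULL)
    tibble::tibble(
      context = context, scope = scope, cell_fraction = cf,
      lag = seq_len(max_lag),
      acf = colMeans(per_sample[ss, , drop = FALSE], na.rm = TRUE)
    )
  })
  attr(out, "n_groups_used") <- length(groups) - skipped
  attr(out, "n_groups_skipped") <- skipped
  class(out) <- c("autocorr_result", class(out))
  out
}
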