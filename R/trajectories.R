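#' Per-region developmental trajectory features
#'
#' For each cell-type by age interaction region (cdDMR), fits per-cytosine
#' regressions of beta on age separately within the glial and neuronal
#' samples and averages the slopes over the region's CpGs, giving one
#' (glia slope, neuron slope) pair per region in beta per year; the mean
#' age-by-cell interaction coefficient over the region is carried along.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, 0-based
#'   half-open; a `region_id` column is created if absent).
#' @param x A cytosine matrix (raw beta is used).
#' @param meta Sample metadata.
#' @return A `trajectory_features` tibble: one row per region with
#'   `glia_slope`, `neuron_slope`, `interaction`, `n_cpg`.
#' @export
compute_trajectory_features <- function(regions, x, meta) {
  if (nrow(regions) == 0) stop("no regions supplied")
  regions <- tibble::as_tibble(regions)
  if (is.null(regions[["region_id"]])) {
    regions$region_id <- sprintf("region_%04d", seq_len(nrow(regions)))
  }
  b <- beta_values(x)
  slope_fit <- function(fraction) {
    sel <- meta$cell_fraction == fraction & !meta$prenatal
    ages <- meta$age[sel]
    bb <- b[, meta$sample_id[sel], drop = FALSE]
    xc <- ages - mean(ages)
    ssx <- sum(xc^2)
    # per-site OLS slope, mean-imputing missing beta within site
    bb_imp <- bb
    na <- is.na(bb_imp)
    if (any(na)) {
      site_mean <- rowMeans(bb, na.rm = TRUE)
      bb_imp[na] <- site_mean[row(bb_imp)[na]]
    }
    as.vector(bb_imp %*% xc) / ssx
  }
  glia_site <- slope_fit("glia")
  neuron_site <- slope_fit("neuron")
  int_fit <- fit_sitewise(x, meta, "age_by_cell_interaction")
  int_site <- rep(NA_real_, nrow(x))
  int_site[match(paste(int_fit$chrom, int_fit$pos),
                 paste(x$chrom, x$pos))] <- int_fit$coefficient

  out <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    inside <- x$chrom == regions$chrom[i] & x$pos > regions$start[i] &
      x$pos <= regions$end[i]
    if (!any(inside)) {
      stop("region ", regions$region_id[i], " contains no cytosines")
    }
    tibble::tibble(
      region_id = regions$region_id[i],
      chrom = regions$chrom[i], start = regions$start[i],
      end = regions$end[i],
      n_cpg = sum(inside),
      glia_slope = mean(glia_site[inside], na.rm = TRUE),
      neuron_slope = mean(neuron_site[inside], na.rm = TRUE),
      interaction = mean(int_site[inside], na.rm = TRUE)
    )
  })
  class(out) <- c("trajectory_features", class(out))
  out
}

#' Cluster trajectory features into developmental groups
#'
#' k-means (best of `n_starts` starts) on the (glia slope, neuron slope)
#' plane. Each cluster receives a semantic label built from the sign
#' pattern of its centroid: a fraction is "static" when the centroid slope
#' magnitude is below `static_threshold` times the largest centroid slope
#' magnitude, otherwise "increasing"/"decreasing".
#'
#' @param features A `trajectory_features` tibble.
#' @param k Number of groups (6 in the standard analysis).
#' @param n_starts Random starts (100 in the standard analysis).
#' @param seed RNG seed.
#' @param static_threshold Relative magnitude below which a centroid slope
#'   counts as static.
#' @return A `traj_clusters` object: `assignments` (features plus `group`),
#'   `centers`, `labels`, `wss` (total within-cluster sum of squares), `k`.
#' @export
kmeans_groups <- function(features, k = 6, n_starts = 100, seed = 1L,
                          static_threshold = 0.1) {
  m <- as.matrix(features[, c("glia_slope", "neuron_slope")])
  if (nrow(m) < k) stop("fewer regions (", nrow(m), ") than clusters (", k, ")")
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = n_starts, iter.max = 50)
  ref <- static_threshold * max(abs(km$centers))
  word <- function(v) {
    ifelse(abs(v) < ref, "static", ifelse(v > 0, "increasing", "decreasing"))
  }
  labels <- paste0(word(km$centers[, "glia_slope"]), " glia / ",
                   word(km$centers[, "neuron_slope"]), " neuron")
  assignments <- features
  assignments$group <- km$cluster
  out <- list(assignments = assignments,
              centers = km$centers, labels = labels,
              wss = km$tot.withinss, k = k)
  class(out) <- "traj_clusters"
  out
}

#' Choose the number of trajectory groups by AIC
#'
#' Runs k-means on mean-centred, scaled features over a range of k and
#' scores each solution with the k-means AIC,
#' `AIC(k) = WSS(k) + 2 * k * d` (d = 2 feature dimensions), returning the
#' curve and its argmin.
#'
#' @param features A `trajectory_features` tibble.
#' @param k_range Candidate cluster counts.
#' @param n_starts Random starts per k.
#' @param seed RNG seed.
#' @param standardize Mean-centre and scale the two features first (the
#'   standard analysis choice). Note that scaling maps any lone cluster to
#'   unit variance, so a single tight cluster is only scored as k = 1 on
#'   the raw scale.
#' @return A tibble with `k`, `wss`, `aic`; attribute `best_k` holds the
#'   argmin.
#' @export
select_k_aic <- function(features, k_range = 1:10, n_starts = 25,
                         seed = 1L, standardize = TRUE) {
  m <- as.matrix(features[, c("glia_slope", "neuron_slope")])
  if (standardize) m <- scale(m)
  d <- ncol(m)
  set.seed(seed)
  res <- purrr::map_dfr(k_range, function(k) {
    wss <- if (k == 1) {
      sum(scale(m, scale = FALSE)^2)
    } else {
      stats::kmeans(m, centers = k, nstart = n_starts, iter.max = 50)$tot.withinss
    }
    tibble::tibble(k = k, wss = wss, aic = wss + 2 * k * d)
  })
  attr(res, "best_k") <- res$k[which.min(res$aic)]
  res
}

#' Neuron/glia ratio of median absolute age effects
#'
#' The ratio of the median absolute neuronal age slope to the median
#' absolute glial age slope across regions (the standard summary of how
#' much faster the neuronal methylome changes with age).
#'
#' @param features A `trajectory_features` tibble.
#' @return A single number; infinite (with a warning) when the glial
#'   median is zero.
#' @export
effect_ratio <- function(features) {
  if (nrow(features) == 0) stop("no features")
  num <- stats::median(abs(features$neuron_slope))
  den <- stats::median(abs(features$glia_slope))
  if (den == 0) {
    warning("glial median absolute slope is zero; ratio infinite")
    return(Inf)
  }
  num / den
}

#' Euclidean sample distances within a region set
#'
#' Pairwise Euclidean distances between samples over the per-site beta of
#' all cytosines inside the regions, with missing beta imputed by the site
#' mean (sites missing in every sample are dropped), plus the
#' average-linkage dendrogram.
#'
#' @param x A cytosine matrix.
#' @param regions Region tibble (0-based half-open).
#' @param meta Optional metadata attached to the result.
#' @return A list: `dist` (a `dist` object), `hclust` (average linkage),
#'   `order` (dendrogram leaf order), `n_sites`.
#' @export
sample_distances <- function(x, regions, meta = NULL) {
  inside <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(regions))) {
    inside <- inside | (x$chrom == regions$chrom[i] &
                          x$pos > regions$start[i] &
                          x$pos <= regions$end[i])
  }
  if (!any(inside)) stop("no cytosines inside the regions")
  b <- beta_values(x)[inside, , drop = FALSE]
  all_missing <- rowSums(!is.na(b)) == 0
  b <- b[!all_missing, , drop = FALSE]
  na <- is.na(b)
  if (any(na)) {
    site_mean <- rowMeans(b, na.rm = TRUE)
    b[na] <- site_mean[row(b)[na]]
  }
  d <- stats::dist(t(b))
  hc <- stats::hclust(d, method = "average")
  list(dist = d, hclust = hc, order = hc$order, n_sites = nrow(b),
       meta = meta)
}
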