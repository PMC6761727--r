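#' Detect differentially methylated regions by bump hunting
#'
#' Fits the site-wise linear model, groups sites into clusters by a maximum
#' gap, and forms candidate regions as maximal same-sign runs of sites whose
#' coefficient of interest exceeds the cutoff in absolute value; each
#' region's area is the sum of the member |coefficients|. Family-wise error
#' rates come from a permutation null: residuals of the nuisance-only model
#' are permuted across samples (Freedman-Lane), the coefficient recomputed,
#' and each region's FWER is the fraction of permutations whose maximum
#' candidate area is at least the region's area (ties counted, which is
#' conservative). A single site whose area beats every permutation maximum
#' is a valid single-CpG region.
#'
#' @param x A cytosine matrix, smoothed when `use_smoothed = TRUE`.
#' @param meta Sample metadata.
#' @param design,coef Model and coefficient of interest, as in
#'   [fit_sitewise()]. Conventional cutoffs: 0.1 for cell-type regions
#'   adjusting for age, 0.005 for age regions adjusting for cell type,
#'   0.009 for the age-by-cell interaction.
#' @param cutoff Coefficient exceedance threshold.
#' @param max_gap Cluster gap in bp.
#' @param n_perms Number of permutations (at least 20).
#' @param seed Permutation seed.
#' @param use_smoothed Model the smoothed track (default) or raw beta.
#' @return A `bumphunt` object: list with `regions` (tibble with `value`,
#'   `area`, `n_cpg`, `direction`, `fwer`), `perm_max` (null maxima),
#'   and the call parameters. `tidy()` extracts the region table.
#' @export
bumphunt <- function(x, meta,
                     design = c("age_plus_cell", "age_only",
                                "age_by_cell_interaction"),
                     coef = NULL, cutoff, max_gap = 1000, n_perms = 250,
                     seed = 1L, use_smoothed = TRUE) {
  design <- match.arg(design)
  if (n_perms < 20) {
    stop("n_perms < 20 gives too coarse an FWER resolution; refuse")
  }
  dm <- design_matrix(meta, design)
  samples <- rownames(dm)
  Y <- if (use_smoothed) smoothed_values(x)[, samples, drop = FALSE]
       else beta_values(x)[, samples, drop = FALSE]
  coef <- coef %||% switch(design, age_only = "age",
                           age_plus_cell = "cell",
                           age_by_cell_interaction = "age:cell")
  complete <- rowSums(is.na(Y)) == 0
  Yc <- Y[complete, , drop = FALSE]
  sites <- tibble::tibble(chrom = x$chrom[complete], pos = x$pos[complete])
  sites <- cluster_positions(sites, max_gap)

  XtXinv <- solve(crossprod(dm))
  hj <- (XtXinv %*% t(dm))[coef, ]          # length n sample weights
  coef_obs <- as.vector(Yc %*% hj)

  regions <- candidate_regions(coef_obs, sites, cutoff)

  # Freedman-Lane: permute residuals of the nuisance-only model
  nuis <- dm[, setdiff(colnames(dm), coef), drop = FALSE]
  H0 <- nuis %*% solve(crossprod(nuis)) %*% t(nuis)
  fitted0 <- Yc %*% t(H0)
  resid0 <- Yc - fitted0
  base_part <- as.vector(fitted0 %*% hj)

  set.seed(seed)
  n <- nrow(dm)
  perm_max <- vapply(seq_len(n_perms), function(b) {
    pp <- sample.int(n)
    coef_b <- base_part + as.vector(resid0[, pp, drop = FALSE] %*% hj)
    max_candidate_area(coef_b, sites, cutoff)
  }, numeric(1))

  regions$fwer <- vapply(regions$area,
                         function(a) mean(perm_max >= a), numeric(1))
  out <- list(
    regions = regions,
    perm_max = perm_max,
    design = design, coef = coef, cutoff = cutoff, max_gap = max_gap,
    n_perms = n_perms, seed = seed, n_sites = nrow(sites)
  )
  class(out) <- "bumphunt"
  out
}

# maximal same-sign runs of |coef| > cutoff within clusters
candidate_regions <- function(coef, sites, cutoff) {
  cat <- ifelse(coef > cutoff, 1L, ifelse(coef < -cutoff, -1L, 0L))
  run_break <- c(TRUE, cat[-1L] != cat[-length(cat)] |
                   sites$cluster[-1L] != sites$cluster[-length(cat)])
  run_id <- cumsum(run_break)
  keep <- cat != 0L
  if (!any(keep)) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_cpg = integer(0),
                          value = numeric(0), area = numeric(0),
                          direction = character(0), cluster = integer(0)))
  }
  idx <- which(keep)
  rid <- run_id[idx]
  first <- idx[!duplicated(rid)]
  last <- idx[rev(!duplicated(rev(rid)))]
  tibble::tibble(
    chrom = sites$chrom[first],
    start = sites$pos[first] - 1,
    end = as.numeric(sites$pos[last]),
    n_cpg = as.integer(tabulate(match(rid, unique(rid)))),
    value = as.vector(tapply(coef[idx], rid, mean)),
    area = as.vector(tapply(abs(coef[idx]), rid, sum)),
    direction = ifelse(cat[first] > 0, "hyper", "hypo"),
    cluster = sites$cluster[first]
  )
}

max_candidate_area <- function(coef, sites, cutoff) {
  keep <- abs(coef) > cutoff
  if (!any(keep)) return(0)
  cat <- ifelse(coef > cutoff, 1L, ifelse(coef < -cutoff, -1L, 0L))
  run_break <- c(TRUE, cat[-1L] != cat[-length(cat)] |
                   sites$cluster[-1L] != sites$cluster[-length(cat)])
  run_id <- cumsum(run_break)
  idx <- which(keep)
  max(as.vector(tapply(abs(coef[idx]), run_id[idx], sum)))
}

#' Regions passing the family-wise error threshold
#'
#' @param object A `bumphunt` object.
#' @param fwer Threshold (default 0.05).
#' @return The significant subset of the region tibble.
#' @export
significant_regions <- function(object, fwer = 0.05) {
  stopifnot(inherits(object, "bumphunt"))
  object$regions[object$regions$fwer < fwer, , drop = FALSE]
}

#' @export
print.bumphunt <- function(x, ...) {
  cat("Bump-hunting result (", x$design, ", coef ", x$coef, ")\n", sep = "")
  cat("  sites: ", x$n_sites, ", cutoff ", x$cutoff, ", maxGap ",
      x$max_gap, ", ", x$n_perms, " permutations\n", sep = "")
  cat("  candidate regions: ", nrow(x$regions),
      " (", sum(x$regions$fwer < 0.05), " at FWER < 5%)\n", sep = "")
  invisible(x)
}
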