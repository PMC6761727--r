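#' Site-wise linear models of methylation
#'
#' Ordinary least squares of per-site beta on the sample design, vectorised
#' across sites. Three designs are supported: `age_only` (`~ age`, for
#' homogenate tissue), `age_plus_cell` (`~ age + cell`), and
#' `age_by_cell_interaction` (`~ age * cell`), with cell coded glia = 0,
#' neuron = 1 and age in years. One coefficient of interest is extracted
#' per run; sites with any missing beta across the used samples are dropped
#' (reported via attribute `n_dropped`).
#'
#' @param x A cytosine matrix; if it carries a `smoothed` column and
#'   `use_smoothed = TRUE`, the smoothed track is modelled, otherwise raw
#'   beta.
#' @param meta Sample metadata ([sample_meta()]); only samples present in
#'   `x` are used, and homogenate samples only under `age_only`.
#' @param design `"age_only"`, `"age_plus_cell"`, or
#'   `"age_by_cell_interaction"`.
#' @param coef Coefficient of interest: `"age"`, `"cell"`, or `"age:cell"`
#'   (default: the design's natural coefficient — `age`, `cell`, and
#'   `age:cell` respectively).
#' @param use_smoothed Model the smoothed track when available.
#' @return A `site_stats` tibble with `chrom`, `pos`, `context`,
#'   `coefficient`, `sigma2` (residual variance), `df` (residual degrees of
#'   freedom); attributes carry the design matrix column of interest and
#'   its unscaled standard error.
#' @export
fit_sitewise <- function(x, meta,
                         design = c("age_only", "age_plus_cell",
                                    "age_by_cell_interaction"),
                         coef = NULL, use_smoothed = FALSE) {
  design <- match.arg(design)
  dm <- design_matrix(meta, design)
  samples <- rownames(dm)
  Y <- if (use_smoothed) {
    smoothed_values(x)[, samples, drop = FALSE]
  } else {
    beta_values(x)[, samples, drop = FALSE]
  }
  coef <- coef %||% switch(design, age_only = "age",
                           age_plus_cell = "cell",
                           age_by_cell_interaction = "age:cell")
  if (!coef %in% colnames(dm)) {
    stop("coefficient '", coef, "' not in design (",
         paste(colnames(dm), collapse = ", "), ")")
  }
  p <- ncol(dm)
  if (nrow(dm) < p + 2) stop("need at least 2 more samples than design columns")
  qrX <- qr(dm)
  if (qrX$rank < p) {
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(dm)[qrX$pivot[seq(qrX$rank + 1, p)]],
               collapse = ", "))
  }

  complete <- rowSums(is.na(Y)) == 0
  Yc <- Y[complete, , drop = FALSE]
  XtXinv <- solve(crossprod(dm))
  H <- XtXinv %*% t(dm)              # p x n
  B <- Yc %*% t(H)                   # sites x p
  colnames(B) <- colnames(dm)
  R <- Yc - B %*% t(dm)
  df <- nrow(dm) - p
  s2 <- rowSums(R^2) / df

  out <- tibble::tibble(
    chrom = x$chrom[complete], pos = x$pos[complete],
    context = x$context[complete],
    coefficient = B[, coef],
    sigma2 = s2,
    df = df
  )
  class(out) <- c("site_stats", class(out))
  attr(out, "design") <- design
  attr(out, "coef") <- coef
  attr(out, "stdev_unscaled") <- sqrt(XtXinv[coef, coef])
  attr(out, "n_dropped") <- sum(!complete)
  attr(out, "coef_matrix") <- B
  out
}

design_matrix <- function(meta, design) {
  use <- if (design == "age_only") meta else
    meta[meta$cell_fraction %in% c("neuron", "glia") & !meta$prenatal, ]
  if (design != "age_only" && nrow(use) < nrow(meta)) {
    # postnatal sorted fractions only for cell-type designs
    use <- use
  }
  cell <- as.numeric(use$cell_fraction == "neuron")
  dm <- switch(design,
    age_only = cbind(intercept = 1, age = use$age),
    age_plus_cell = cbind(intercept = 1, age = use$age, cell = cell),
    age_by_cell_interaction = cbind(intercept = 1, age = use$age,
                                    cell = cell, `age:cell` = use$age * cell)
  )
  rownames(dm) <- use$sample_id
  dm
}

#' Empirical-Bayes moderated t-tests for site statistics
#'
#' Shrinks the per-site residual variances toward a common prior estimated
#' by method of moments on log residual variances, then forms moderated
#' t-statistics with `d0 + d` degrees of freedom and Benjamini-Hochberg
#' adjusted p-values. With prior df `d0 -> Inf` every moderated variance
#' equals the prior variance; with `d0 = 0` the moderated t reduces to the
#' ordinary t.
#'
#' @param stats A `site_stats` tibble from [fit_sitewise()].
#' @param prior_df,prior_var Optional overrides of the estimated
#'   hyperparameters (useful to explore the shrinkage limits).
#' @return The input with `s2_moderated`, `t`, `p`, `q` columns; attributes
#'   `prior_df` and `prior_var` record the hyperparameters.
#' @export
moderated_test <- function(stats, prior_df = NULL, prior_var = NULL) {
  s2 <- stats$sigma2
  d <- stats$df[1L]
  se_unscaled <- attr(stats, "stdev_unscaled")
  if (is.null(se_unscaled)) stop("not a site_stats object")

  if (is.null(prior_df) || is.null(prior_var)) {
    pos <- s2 > 0
    if (!any(pos)) {
      warning("all residual variances are zero; ordinary t reported")
      prior_df <- 0
      prior_var <- 0
    } else {
      if (sum(pos) < 100) {
        warning("fewer than 100 positive variances; hyperparameters noisy")
      }
      z <- log(s2[pos])
      e <- z - digamma(d / 2) + log(d / 2)
      evar <- stats::var(e) - trigamma(d / 2)
      if (is.na(evar) || evar <= 0) {
        prior_df <- prior_df %||% Inf
        prior_var <- prior_var %||% exp(mean(e))
      } else {
        d0 <- 2 * trigamma_inverse(evar)
        prior_df <- prior_df %||% d0
        prior_var <- prior_var %||%
          exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  }

  s2_mod <- if (is.infinite(prior_df)) {
    rep(prior_var, length(s2))
  } else {
    (prior_df * prior_var + d * s2) / (prior_df + d)
  }
  df_total <- d + prior_df
  tstat <- stats$coefficient / (sqrt(s2_mod) * se_unscaled)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- stats
  out$s2_moderated <- s2_mod
  out$t <- tstat
  out$p <- p
  out$q <- stats::p.adjust(p, method = "BH")
  attr(out, "prior_df") <- prior_df
  attr(out, "prior_var") <- prior_var
  out
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Compare cell-type-specific and homogenate site-wise fits
#'
#' Concordance of age effects estimated in sorted cell fractions versus
#' bulk tissue: on the sites significant by age in the homogenate fit
#' (p below `p_threshold`), the correlation of coefficients; across all
#' shared sites, a 2x2 significance cross-table with sample odds ratio and
#' Fisher p; and the fraction of cell-type-significant sites that the
#' homogenate fit misses.
#'
#' @param celltype_stats,homogenate_stats Moderated `site_stats` tibbles
#'   sharing a site index.
#' @param p_threshold Significance threshold applied to both fits.
#' @return A list: `coefficient_correlation` (on homogenate-significant
#'   sites), `cross_table`, `odds_ratio`, `fisher_p`,
#'   `fraction_celltype_only`, `n_shared`.
#' @export
compare_designs <- function(celltype_stats, homogenate_stats,
                            p_threshold = 1e-4) {
  j <- dplyr::inner_join(
    tibble::tibble(chrom = celltype_stats$chrom, pos = celltype_stats$pos,
                   coef_ct = celltype_stats$coefficient,
                   p_ct = celltype_stats$p),
    tibble::tibble(chrom = homogenate_stats$chrom,
                   pos = homogenate_stats$pos,
                   coef_h = homogenate_stats$coefficient,
                   p_h = homogenate_stats$p),
    by = c("chrom", "pos")
  )
  if (nrow(j) == 0) stop("no shared sites between the two fits")
  sel <- j[j$p_h < p_threshold, , drop = FALSE]
  corr <- if (nrow(sel) >= 3) stats::cor(sel$coef_ct, sel$coef_h) else NA_real_
  sig_ct <- j$p_ct < p_threshold
  sig_h <- j$p_h < p_threshold
  tab <- table(celltype = factor(sig_ct, c(FALSE, TRUE)),
               homogenate = factor(sig_h, c(FALSE, TRUE)))
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  fp <- stats::fisher.test(tab)$p.value
  list(
    coefficient_correlation = corr,
    cross_table = tab,
    odds_ratio = or,
    fisher_p = fp,
    fraction_celltype_only = if (any(sig_ct)) mean(!sig_h[sig_ct]) else NA_real_,
    n_shared = nrow(j),
    n_homogenate_selected = nrow(sel)
  )
}
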