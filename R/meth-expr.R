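#' Filter and transform expression tables
#'
#' Applies the standard feature filters — genes kept when mean FPKM is
#' strictly above 0.22, exons above 0.26, splice events (PSI) when their
#' read denominator is at least 10 — and transforms gene/exon values to
#' log2(FPKM + 1) while PSI stays raw in \[0, 1\].
#'
#' @param raw An expression tibble with `feature_id`, `feature_type`
#'   (`gene`/`exon`/`PSI`), a `value` matrix-column (samples), and for PSI
#'   a `denominator` column.
#' @param gene_cutoff,exon_cutoff Mean-FPKM cutoffs (strict).
#' @param psi_min_denominator Minimum PSI denominator.
#' @return The filtered tibble with transformed `value`; attribute
#'   `n_dropped` counts removed features.
#' @export
filter_expression <- function(raw, gene_cutoff = 0.22, exon_cutoff = 0.26,
                              psi_min_denominator = 10) {
  v <- unclass(raw)$value
  mu <- rowMeans(v, na.rm = TRUE)
  keep <- rep(TRUE, nrow(raw))
  g <- raw$feature_type == "gene"
  e <- raw$feature_type == "exon"
  p <- raw$feature_type == "PSI"
  keep[g] <- mu[g] > gene_cutoff
  keep[e] <- mu[e] > exon_cutoff
  if (any(p)) {
    den <- raw$denominator %||% rep(NA_real_, nrow(raw))
    keep[p] <- !is.na(den[p]) & den[p] >= psi_min_denominator
  }
  out <- raw[keep, ]
  vv <- unclass(out)$value
  tr <- out$feature_type %in% c("gene", "exon")
  vv[tr, ] <- log2(vv[tr, , drop = FALSE] + 1)
  out$value <- vv
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Group-mean methylation-expression correlations
#'
#' Averages methylation over a feature-anchored window and expression per
#' (cell fraction x age group) group, then correlates the two across
#' features within each group (Spearman). Windows: `promoter` (2 kb
#' upstream of the gene start through the start), `gene_body` (the gene
#' span), `exon` (the feature span padded by 500 bp), `junction` (50 bp
#' into each flanking intron, approximated by 50 bp outside either end of
#' the feature span).
#'
#' @param x A cytosine matrix (filter to one context to stratify).
#' @param expr A filtered expression tibble.
#' @param meta Sample metadata covering the expression samples.
#' @param window One of `"promoter"`, `"gene_body"`, `"exon"`,
#'   `"junction"`.
#' @param genes Optional gene-model tibble (`gene_id`, `start`, `end`)
#'   used for promoter/gene-body windows; defaults to the feature spans.
#' @param promoter_up,exon_pad,junction_pad Window geometry in bp.
#' @return A tibble with `window`, `group`, `rho`, `n_features`.
#' @export
group_mean_correlation <- function(x, expr, meta,
                                   window = c("promoter", "gene_body",
                                              "exon", "junction"),
                                   genes = NULL, promoter_up = 2000,
                                   exon_pad = 500, junction_pad = 50) {
  window <- match.arg(window)
  b <- beta_values(x)
  v <- unclass(expr)$value
  donors <- colnames(v)
  b <- b[, intersect(colnames(b), donors), drop = FALSE]
  md <- meta[match(colnames(b), meta$sample_id), ]
  grp <- interaction(md$cell_fraction, droplevels(md$age_group), drop = TRUE)

  span_for <- function(i) {
    s <- expr$start[i]; e <- expr$end[i]
    if (!is.null(genes) && window %in% c("promoter", "gene_body")) {
      j <- match(expr$gene_id[i], genes$gene_id)
      if (!is.na(j)) { s <- genes$start[j]; e <- genes$end[j] }
    }
    switch(window,
      promoter = cbind(s - promoter_up, s),
      gene_body = cbind(s, e),
      exon = cbind(s - exon_pad, e + exon_pad),
      junction = rbind(c(s - junction_pad, s), c(e, e + junction_pad))
    )
  }

  meth_mean <- matrix(NA_real_, nrow(expr), ncol(b))
  for (i in seq_len(nrow(expr))) {
    w <- span_for(i)
    inside <- rep(FALSE, nrow(x))
    for (r in seq_len(nrow(w))) {
      inside <- inside | (x$chrom == expr$chrom[i] & x$pos > w[r, 1] &
                            x$pos <= w[r, 2])
    }
    if (any(inside)) {
      meth_mean[i, ] <- colMeans(b[inside, , drop = FALSE], na.rm = TRUE)
    }
  }
  tested <- rowSums(!is.na(meth_mean)) > 0
  purrr::map_dfr(levels(grp), function(g) {
    cols <- grp == g
    mm <- rowMeans(meth_mean[tested, cols, drop = FALSE], na.rm = TRUE)
    ee <- rowMeans(v[tested, colnames(b)[cols], drop = FALSE], na.rm = TRUE)
    ok <- !is.na(mm) & !is.na(ee)
    tibble::tibble(
      window = window, group = g,
      rho = if (sum(ok) >= 3) {
        stats::cor(mm[ok], ee[ok], method = "spearman")
      } else NA_real_,
      n_features = sum(ok)
    )
  })
}

#' Cis scan of cytosine methylation against expression
#'
#' For every (cytosine, expression feature) pair whose distance is at most
#' `window` bp (closed boundary; zero for a cytosine inside the feature
#' span), fits the simple linear regression of expression on beta across
#' donors and keeps pairs with p below `p_threshold`. FDR is
#' Benjamini-Hochberg within each feature type over all tested pairs. The
#' per-pair t equals the correlation identity `r * sqrt((n-2)/(1-r^2))`.
#'
#' @param x A cytosine matrix (one context per scan, as in the standard
#'   analysis).
#' @param expr A filtered expression tibble.
#' @param window Cis distance in bp (inclusive).
#' @param p_threshold Report only pairs below this p.
#' @param genes Optional gene models for the promoter/body/flank
#'   annotation; defaults to feature spans.
#' @return An association tibble: cytosine columns, feature columns,
#'   `slope`, `t`, `p`, `q`, `n_nonzero`, `n_nonone`, `delta_expr` (slope
#'   times the observed beta range), `annotation`, `n_tested` attribute.
#' @export
cis_scan <- function(x, expr, window = 1000, p_threshold = 5e-4,
                     genes = NULL) {
  b <- beta_values(x)
  donors <- colnames(unclass(expr)$value)
  donors <- intersect(colnames(b), donors)
  if (length(donors) < 3) stop("need at least 3 matched donors")
  b <- b[, donors, drop = FALSE]
  v <- unclass(expr)$value[, donors, drop = FALSE]
  n <- length(donors)

  res <- list()
  n_tested <- 0L
  for (i in seq_len(nrow(expr))) {
    near <- x$chrom == expr$chrom[i] &
      x$pos > expr$start[i] - window & x$pos <= expr$end[i] + window
    if (!any(near)) next
    idx <- which(near)
    y <- v[i, ]
    if (stats::sd(y) == 0) next
    bb <- b[idx, , drop = FALSE]
    ok_n <- rowSums(!is.na(bb))
    sds <- apply(bb, 1L, stats::sd, na.rm = TRUE)
    use <- ok_n == n & !is.na(sds) & sds > 0
    if (!any(use)) next
    idx <- idx[use]
    bb <- bb[use, , drop = FALSE]
    n_tested <- n_tested + length(idx)
    yc <- y - mean(y)
    bc <- bb - rowMeans(bb)
    r <- as.vector(bc %*% yc) / sqrt(rowSums(bc^2) * sum(yc^2))
    r <- pmin(1, pmax(-1, r))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    slope <- as.vector(bc %*% yc) / rowSums(bc^2)
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    rng <- apply(bb, 1L, function(z) diff(range(z)))
    res[[length(res) + 1L]] <- tibble::tibble(
      chrom = x$chrom[idx], pos = x$pos[idx], context = x$context[idx],
      trinucleotide = x$trinucleotide[idx],
      feature_id = expr$feature_id[i], feature_type = expr$feature_type[i],
      gene_id = expr$gene_id[i], coding = expr$coding[i],
      slope = slope, t = tt, p = p,
      n_nonzero = as.integer(rowSums(bb > 0)),
      n_nonone = as.integer(rowSums(bb < 1)),
      delta_expr = slope * rng,
      annotation = annotate_relative(x$pos[idx], expr[i, ], genes)
    )
  }
  out <- if (length(res) > 0) dplyr::bind_rows(res) else empty_assoc()
  out <- dplyr::group_by(out, .data$feature_type)
  out <- dplyr::mutate(out, q = stats::p.adjust(.data$p, method = "BH"))
  out <- dplyr::ungroup(out)
  out <- out[out$p < p_threshold, , drop = FALSE]
  attr(out, "n_tested") <- n_tested
  out
}

empty_assoc <- function() {
  tibble::tibble(
    chrom = character(0), pos = numeric(0), context = character(0),
    trinucleotide = character(0), feature_id = character(0),
    feature_type = character(0), gene_id = character(0),
    coding = logical(0), slope = numeric(0), t = numeric(0),
    p = numeric(0), n_nonzero = integer(0), n_nonone = integer(0),
    delta_expr = numeric(0), annotation = character(0)
  )
}

# promoter: 2 kb upstream through the start; body: inside the span;
# flanking: within 5 kb beyond the span (promoter wins ties)
annotate_relative <- function(pos, feature, genes = NULL,
                              promoter_up = 2000, flank = 5000) {
  s <- feature$start; e <- feature$end
  if (!is.null(genes)) {
    j <- match(feature$gene_id, genes$gene_id)
    if (!is.na(j)) { s <- genes$start[j]; e <- genes$end[j] }
  }
  ifelse(pos > s - promoter_up & pos <= s, "promoter",
         ifelse(pos > s & pos <= e, "gene body", "flanking"))
}

#' Rescue marginal CpG associations around significant CpH hits
#'
#' Around every CpH association at FDR below `fdr` the CpGs within
#' `window` bp (closed at exactly `window`) are rescanned against the same
#' feature at the looser `p_marginal` threshold; features are then
#' classified `shared` when a genome-wide CpG hit or a marginal CpG backs
#' the CpH signal, else `CpH-exclusive`.
#'
#' @param cph_hits Association tibble from a CpH [cis_scan()].
#' @param cpg_matrix A CpG cytosine matrix.
#' @param expr The filtered expression tibble used in the scans.
#' @param cpg_hits Optional genome-wide CpG association tibble.
#' @param window Rescue window in bp.
#' @param p_marginal Marginal p threshold.
#' @param fdr CpH FDR threshold defining hits to rescue.
#' @return A list: `marginal` (CpG association records labelled
#'   `marginal = TRUE`) and `feature_classes` (per feature:
#'   `classification`).
#' @export
marginal_cpg_rescue <- function(cph_hits, cpg_matrix, expr,
                                cpg_hits = NULL, window = 1000,
                                p_marginal = 0.01, fdr = 0.05) {
  sig <- cph_hits[cph_hits$q < fdr, , drop = FALSE]
  b <- beta_values(cpg_matrix)
  donors <- colnames(unclass(expr)$value)
  donors <- intersect(colnames(b), donors)
  b <- b[, donors, drop = FALSE]
  v <- unclass(expr)$value[, donors, drop = FALSE]
  n <- length(donors)

  marg <- list()
  for (i in seq_len(nrow(sig))) {
    near <- cpg_matrix$chrom == sig$chrom[i] &
      abs(cpg_matrix$pos - sig$pos[i]) <= window
    if (!any(near)) next
    fi <- match(sig$feature_id[i], expr$feature_id)
    y <- v[fi, ]
    if (stats::sd(y) == 0) next
    idx <- which(near)
    bb <- b[idx, , drop = FALSE]
    use <- rowSums(!is.na(bb)) == n &
      apply(bb, 1L, function(z) stats::sd(z) > 0)
    if (!any(use)) next
    idx <- idx[use]
    bb <- bb[use, , drop = FALSE]
    yc <- y - mean(y)
    bc <- bb - rowMeans(bb)
    r <- as.vector(bc %*% yc) / sqrt(rowSums(bc^2) * sum(yc^2))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    keep <- p < p_marginal
    if (!any(keep)) next
    marg[[length(marg) + 1L]] <- tibble::tibble(
      chrom = sig$chrom[i], pos = cpg_matrix$pos[idx[keep]],
      context = "CpG",
      feature_id = sig$feature_id[i], feature_type = sig$feature_type[i],
      anchor_cph = sig$pos[i],
      slope = as.vector(bc[keep, , drop = FALSE] %*% yc) /
        rowSums(bc[keep, , drop = FALSE]^2),
      t = tt[keep], p = p[keep], marginal = TRUE
    )
  }
  marginal <- if (length(marg) > 0) dplyr::bind_rows(marg) else
    tibble::tibble(feature_id = character(0))

  feats <- unique(sig$feature_id)
  backed <- unique(c(
    marginal$feature_id,
    if (!is.null(cpg_hits)) cpg_hits$feature_id[cpg_hits$q < fdr]
  ))
  classes <- tibble::tibble(
    feature_id = feats,
    classification = ifelse(feats %in% backed, "shared", "CpH-exclusive")
  )
  list(marginal = marginal, feature_classes = classes)
}

#' Filter association records
#'
#' Removes extreme and untrustworthy associations: fewer than
#' `min_nonzero` donors with beta > 0 or fewer than `min_nonone` with
#' beta < 1, features that are not protein-coding, and infinite
#' t-statistics.
#'
#' @param records An association tibble.
#' @param min_nonzero,min_nonone Donor-count thresholds (11 in the
#'   standard analysis).
#' @param require_coding Drop non-protein-coding features.
#' @return The surviving records.
#' @export
filter_associations <- function(records, min_nonzero = 11,
                                min_nonone = 11, require_coding = TRUE) {
  keep <- records$n_nonzero >= min_nonzero &
    records$n_nonone >= min_nonone & is.finite(records$t)
  if (require_coding && !is.null(records$coding)) {
    keep <- keep & records$coding
  }
  records[keep, , drop = FALSE]
}

#' Flag associations confounded by age
#'
#' Refits each association as expression ~ beta + age and flags the record
#' when the methylation coefficient is no longer significant at FDR below
#' `fdr` within the rechecked set. Near-collinear beta and age
#' (|r| > 0.999) is flagged confounded with a warning.
#'
#' @param records An association tibble.
#' @param x The cytosine matrix used in the scan.
#' @param expr The filtered expression tibble.
#' @param meta Sample metadata with donor ages.
#' @param fdr FDR threshold of the recheck.
#' @return `records` with logical `age_confounded` and the adjusted
#'   methylation p (`p_adj_age`).
#' @export
age_confound_check <- function(records, x, expr, meta, fdr = 0.05) {
  b <- beta_values(x)
  donors <- colnames(unclass(expr)$value)
  donors <- intersect(colnames(b), donors)
  ages <- meta$age[match(donors, meta$sample_id)]
  v <- unclass(expr)$value[, donors, drop = FALSE]
  b <- b[, donors, drop = FALSE]
  key_x <- paste(x$chrom, x$pos)

  p_adj <- rep(NA_real_, nrow(records))
  collinear <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(records))) {
    bi <- b[match(paste(records$chrom[i], records$pos[i]), key_x), ]
    y <- v[match(records$feature_id[i], expr$feature_id), ]
    if (abs(stats::cor(bi, ages)) > 0.999) {
      collinear[i] <- TRUE
      next
    }
    fit <- stats::lm(y ~ bi + ages)
    p_adj[i] <- summary(fit)$coefficients["bi", "Pr(>|t|)"]
  }
  if (any(collinear)) {
    warning(sum(collinear), " record(s) with beta collinear to age; ",
            "flagged confounded")
  }
  q_adj <- stats::p.adjust(p_adj, method = "BH")
  out <- records
  out$p_adj_age <- p_adj
  out$age_confounded <- collinear | (!is.na(q_adj) & q_adj >= fdr)
  out
}

#' Attach differential-expression status to association records
#'
#' @param records An association tibble.
#' @param de_table A tibble with `gene_id` and `de_status`
#'   (`"neuron"`/`"glia"`); absent genes get `"none"`.
#' @return `records` with a `de_status` column.
#' @export
annotate_de <- function(records, de_table) {
  st <- de_table$de_status[match(records$gene_id, de_table$gene_id)]
  records$de_status <- ifelse(is.na(st), "none", st)
  records
}

#' Summarise associations by feature type, context, and direction
#'
#' The standard summary table of methylation-expression associations: per
#' (feature type, context, direction of effect) stratum, the number of
#' associations, unique cytosines and features, mean donor counts with
#' non-zero / non-one methylation, mean absolute expression change, and
#' proportions of age-confounded, promoter / gene-body / flanking, CHG /
#' CHH, and differential-expression categories.
#'
#' @param records A filtered, annotated association tibble.
#' @return One row per stratum.
#' @export
summarize_associations <- function(records) {
  r <- records
  r$context_class <- ifelse(r$context == "CpG", "CpG", "CpH")
  r$direction <- ifelse(r$slope < 0, "Down", "Up")
  if (is.null(r[["age_confounded"]])) r$age_confounded <- NA
  if (is.null(r[["de_status"]])) r$de_status <- NA_character_
  dplyr::summarise(
    dplyr::group_by(r, .data$feature_type, .data$context_class,
                    .data$direction),
    n = dplyr::n(),
    n_unique_c = dplyr::n_distinct(paste(.data$chrom, .data$pos)),
    n_unique_features = dplyr::n_distinct(.data$feature_id),
    mean_n_nonzero = mean(.data$n_nonzero),
    mean_n_nonone = mean(.data$n_nonone),
    mean_abs_expr_change = mean(abs(.data$delta_expr)),
    prop_age_confounded = mean(.data$age_confounded, na.rm = TRUE),
    prop_promoter = mean(.data$annotation == "promoter"),
    prop_gene_body = mean(.data$annotation == "gene body"),
    prop_flanking = mean(.data$annotation == "flanking"),
    prop_chg = mean(.data$context == "CHG"),
    prop_chh = mean(.data$context == "CHH"),
    prop_de_glia = mean(.data$de_status == "glia", na.rm = TRUE),
    prop_de_neuron = mean(.data$de_status == "neuron", na.rm = TRUE),
    prop_no_de = mean(.data$de_status == "none", na.rm = TRUE),
    .groups = "drop"
  )
}
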