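#' Simulation benchmarks of the analysis pipeline
#'
#' Self-contained scenario runners that regenerate synthetic data with
#' planted truth, run the corresponding pipeline stage, and score recovery
#' against the truth ledger. They power the package's acceptance checks and
#' are exported so the whole evaluation is reproducible from a single seed.
#'
#' @name benchmarks
#' @param seed Integer seed controlling every random draw in the scenario.
NULL

# adjusted Rand index (pair-counting form)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(sum(tab))
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

#' @describeIn benchmarks Power and error control of DMR detection: 24
#'   samples (12 neuron / 12 glia, ages 0-23) on a 2-Mb genome with 30
#'   planted cell-type DMRs (delta beta 0.2, 8-20 CpGs) and 20 planted
#'   interaction DMRs; the cell-type scan runs on raw beta at cutoff 0.1,
#'   the interaction scan on a lightly smoothed track at cutoff 0.009, both
#'   with maxGap 1000 and 250 permutations. Detection and false-discovery
#'   rates are pooled over `n_replicates` independent simulations, scoring
#'   called regions against the union of planted differential regions.
#' @param n_replicates Number of replicate simulations pooled.
#' @param n_perms Permutations per bump-hunting run.
#' @export
benchmark_dmr_power <- function(seed, n_replicates = 3, n_perms = 250) {
  detected <- c()
  class_of <- c()
  n_sig <- 0L
  n_false <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(
      seed = seed + 1000L * r, genome_length = 2e6,
      features = sim_features(n_umr = 0L, n_lmr = 0L, n_dmv = 0L,
                              pmd_lengths = numeric(0), n_desert = 0L)
    )
    sim <- simulate_methylome(cfg)
    mf <- filter_by_coverage(dplyr::filter(sim$matrix, context == "CpG"),
                             3, quiet = TRUE)
    sm <- smooth_betas(mf, min_sites = 5, min_width = 500)
    bh_ct <- bumphunt(mf, sim$meta, "age_plus_cell", coef = "cell",
                      cutoff = 0.1, max_gap = 1000, n_perms = n_perms,
                      seed = seed + r, use_smoothed = FALSE)
    bh_int <- bumphunt(sm, sim$meta, "age_by_cell_interaction",
                       cutoff = 0.009, max_gap = 1000, n_perms = n_perms,
                       seed = seed + r)
    tf <- sim$truth$features
    ct_t <- tf[tf$kind == "DMR_celltype", ]
    int_t <- tf[tf$kind == "DMR_interaction", ]
    all_t <- dplyr::bind_rows(ct_t, int_t)
    hit <- function(bh, truth) {
      sig <- significant_regions(bh)
      vapply(seq_len(nrow(truth)), function(i) {
        any(sig$end > truth$start[i] & sig$start < truth$end[i])
      }, logical(1))
    }
    detected <- c(detected, hit(bh_ct, ct_t), hit(bh_int, int_t))
    class_of <- c(class_of, rep("celltype", nrow(ct_t)),
                  rep("interaction", nrow(int_t)))
    for (bh in list(bh_ct, bh_int)) {
      sig <- significant_regions(bh)
      n_sig <- n_sig + nrow(sig)
      if (nrow(sig) > 0) {
        n_false <- n_false + sum(vapply(seq_len(nrow(sig)), function(i) {
          !any(all_t$end > sig$start[i] & all_t$start < sig$end[i])
        }, logical(1)))
      }
    }
  }
  list(
    sensitivity = mean(detected),
    sensitivity_celltype = mean(detected[class_of == "celltype"]),
    sensitivity_interaction = mean(detected[class_of == "interaction"]),
    empirical_fdr = if (n_sig > 0) n_false / n_sig else 0,
    n_planted = length(detected),
    n_significant = n_sig
  )
}

#' @describeIn benchmarks Family-wise error control under the global null:
#'   replicate simulations with no planted differential regions; reports the
#'   fraction of replicates yielding zero regions at FWER < 5%.
#' @export
benchmark_null_fwer <- function(seed, n_replicates = 20, n_perms = 250) {
  zero <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(
      seed = seed + 500L * r, genome_length = 1e6,
      features = sim_features(n_celltype_dmr = 0L, n_interaction_dmr = 0L,
                              pmd_lengths = 1.5e5)
    )
    sim <- simulate_methylome(cfg)
    mf <- filter_by_coverage(dplyr::filter(sim$matrix, context == "CpG"),
                             3, quiet = TRUE)
    bh <- bumphunt(mf, sim$meta, "age_plus_cell", coef = "cell",
                   cutoff = 0.1, n_perms = n_perms, seed = seed + r,
                   use_smoothed = FALSE)
    zero[r] <- nrow(significant_regions(bh)) == 0
  }
  list(fraction_zero = mean(zero), n_replicates = n_replicates)
}

#' @describeIn benchmarks Segmentation recovery: a planted
#'   UMR/LMR/PMD/DMV landscape (no DMRs) on the default 4-Mb genome,
#'   segmented for the first neuronal sample; per-kind base-level Jaccard
#'   against the planted features (planted DMVs count as UMRs for the UMR
#'   class).
#' @export
benchmark_segmentation <- function(seed) {
  cfg <- sim_config(
    seed = seed,
    features = sim_features(n_celltype_dmr = 0L, n_interaction_dmr = 0L)
  )
  sim <- simulate_methylome(cfg)
  mf <- filter_by_coverage(dplyr::filter(sim$matrix, context == "CpG"),
                           3, quiet = TRUE)
  sm <- smooth_betas(mf, min_sites = 10, min_width = 1000)
  seg <- suppressWarnings(
    segment_methylome(sm, sample_ids(mf)[1], gaps = sim$truth$gaps)
  )
  tf <- sim$truth$features
  list(
    jaccard_umr = region_jaccard(seg[seg$kind %in% c("UMR", "DMV"), ],
                                 tf[tf$kind %in% c("UMR", "DMV"), ]),
    jaccard_lmr = region_jaccard(seg[seg$kind == "LMR", ],
                                 tf[tf$kind == "LMR", ]),
    jaccard_pmd = region_jaccard(seg[seg$kind == "PMD", ],
                                 tf[tf$kind == "PMD", ]),
    jaccard_dmv = region_jaccard(seg[seg$kind == "DMV", ],
                                 tf[tf$kind == "DMV", ]),
    cutoff = attr(seg, "calibration")$cutoff,
    n_regions = nrow(seg)
  )
}

#' @describeIn benchmarks Trajectory decomposition: 300 interaction DMRs
#'   drawn from the six archetypes; k-means recovery (ARI against planted
#'   groups, k = 6, 100 starts), the AIC argmin over `n_aic_seeds`
#'   clustering seeds, and the recovered neuron/glia median absolute
#'   age-effect ratio.
#' @param n_aic_seeds Clustering seeds over which the AIC argmin is scored.
#' @export
benchmark_trajectories <- function(seed, n_aic_seeds = 20) {
  cfg <- sim_config(
    seed = seed,
    features = sim_features(n_interaction_dmr = 300L, n_celltype_dmr = 0L,
                            n_umr = 2L, n_lmr = 2L, n_dmv = 0L,
                            dmr_n_cpg = c(15L, 30L),
                            pmd_lengths = numeric(0), n_desert = 0L)
  )
  sim <- simulate_methylome(cfg)
  mf <- filter_by_coverage(dplyr::filter(sim$matrix, context == "CpG"),
                           3, quiet = TRUE)
  cd <- sim$truth$features[sim$truth$features$kind == "DMR_interaction", ]
  cd$region_id <- cd$id
  ft <- compute_trajectory_features(cd, mf, sim$meta)
  km <- kmeans_groups(ft, k = 6, n_starts = 100, seed = seed)
  hits <- vapply(seq_len(n_aic_seeds), function(s) {
    attr(select_k_aic(ft, k_range = 1:10, seed = seed + s), "best_k") == 6
  }, logical(1))
  list(
    ari = adjusted_rand(km$assignments$group, cd$group),
    effect_ratio = effect_ratio(ft),
    aic_argmin6_fraction = mean(hits),
    n_regions = nrow(ft)
  )
}

#' @describeIn benchmarks Autocorrelation calibration on constructed
#'   methylation fields at the measurement scale of the study: a
#'   first-order autoregressive field (rho = 0.7) and an i.i.d. field, each
#'   60 clusters x 150 sites, plus the mixed-context comparison — regions
#'   where CpG and CpH share one autoregressive surface versus an
#'   interleaved-context background.
#' @export
benchmark_autocorrelation <- function(seed) {
  set.seed(seed)
  meta2 <- sample_meta(c("s1", "s2"), c("neuron", "glia"), c(5, 5))
  series_matrix <- function(gen, tri) {
    n_cl <- 60L; n_per <- 150L
    pos <- unlist(lapply(seq_len(n_cl), function(cl) {
      (cl - 1L) * 20000L + seq(1L, by = 50L, length.out = n_per)
    }))
    beta <- cbind(s1 = unlist(replicate(n_cl, gen(n_per), simplify = FALSE)),
                  s2 = unlist(replicate(n_cl, gen(n_per), simplify = FALSE)))
    cytosine_matrix(
      tibble::tibble(chrom = "c1", pos = pos, strand = "+",
                     trinucleotide = tri),
      round(beta * 1e4),
      matrix(1e4L, length(pos), 2, dimnames = list(NULL, c("s1", "s2")))
    )
  }
  ar1 <- function(n) {
    0.5 + 0.1 * as.numeric(stats::filter(
      stats::rnorm(n, 0, sqrt(1 - 0.49)), 0.7, method = "recursive"))
  }
  iid <- function(n) stats::runif(n, 0.2, 0.8)
  res_ar <- autocorrelation(series_matrix(ar1, "CAC"), meta2,
                            context = "CHH", max_lag = 4)
  res_iid <- autocorrelation(series_matrix(iid, "CAC"), meta2,
                             context = "CHH", max_lag = 4)

  # shared-surface regions vs interleaved-context background
  n_regions <- 40L; region_size <- 60L
  gen_shared <- function(n) {
    prof <- 0.5 + 0.15 * as.numeric(stats::filter(
      stats::rnorm(n, 0, sqrt(1 - 0.64)), 0.8, method = "recursive"))
    clamp01(prof + stats::rnorm(n, 0, 0.02))
  }
  pos <- c(); tri <- c(); b1 <- c(); b2 <- c()
  tri_pat <- rep(c("CGA", "CAC", "CAC"), length.out = region_size)
  for (r in seq_len(n_regions)) {
    base_pos <- (r - 1L) * 50000L
    pos <- c(pos, base_pos + seq(1L, by = 40L, length.out = region_size))
    tri <- c(tri, tri_pat)
    b1 <- c(b1, gen_shared(region_size)); b2 <- c(b2, gen_shared(region_size))
    pos <- c(pos, base_pos + 10000L +
               seq(1L, by = 40L, length.out = region_size))
    tri <- c(tri, tri_pat)
    bg <- function() {
      ifelse(tri_pat == "CGA", stats::runif(region_size, 0.85, 0.95),
             stats::runif(region_size, 0, 0.1))
    }
    b1 <- c(b1, bg()); b2 <- c(b2, bg())
  }
  mixed <- cytosine_matrix(
    tibble::tibble(chrom = "c1", pos = pos, strand = "+",
                   trinucleotide = tri),
    round(cbind(s1 = b1, s2 = b2) * 1e4),
    matrix(1e4L, length(pos), 2, dimnames = list(NULL, c("s1", "s2")))
  )
  regions <- tibble::tibble(
    chrom = "c1",
    start = (seq_len(n_regions) - 1) * 50000,
    end = (seq_len(n_regions) - 1) * 50000 + 40 * region_size + 50
  )
  within <- autocorrelation(mixed, meta2, context = "allC",
                            regions = regions)
  genome <- autocorrelation(mixed, meta2, context = "allC",
                            max_gap = 1000)
  list(
    ar1_lag1 = mean(res_ar$acf[res_ar$lag == 1]),
    iid_lag1 = mean(res_iid$acf[res_iid$lag == 1]),
    mixed_within_lag1 = mean(within$acf[within$lag == 1]),
    mixed_genome_lag1 = mean(genome$acf[genome$lag == 1])
  )
}

#' @describeIn benchmarks Methylation-expression association scan with 22
#'   neuronal donors: power at p < 5e-4 over planted cis effects
#'   (realized R-squared 0.5) that survive the site filters, the
#'   genome-wide null pass rate against the nominal level, the
#'   classification accuracy of planted CpH-exclusive effects, and the
#'   largest deviation of the scan's t from the closed-form correlation
#'   identity.
#' @export
benchmark_association <- function(seed) {
  cfg <- sim_config(
    seed = seed, n_neuron = 22L, n_glia = 0L, genome_length = 2e6,
    features = sim_features(n_celltype_dmr = 0L, n_interaction_dmr = 0L,
                            pmd_lengths = numeric(0)),
    assoc = sim_assoc(n_cpg = 40L, n_cph_shared = 10L,
                      n_cph_exclusive = 20L, exclusive_in_desert = 12L)
  )
  sim <- simulate_methylome(cfg)
  ex <- simulate_expression(sim, target_r2 = 0.5)
  expr <- filter_expression(ex$expression)
  mcpg <- filter_by_coverage(dplyr::filter(sim$matrix, context == "CpG"),
                             3, quiet = TRUE)
  mcph <- filter_by_coverage(dplyr::filter(sim$matrix, context != "CpG"),
                             5, 5, quiet = TRUE)
  hits_cpg <- cis_scan(mcpg, expr, window = 1000, p_threshold = 5e-4)
  hits_cph <- cis_scan(mcph, expr, window = 1000, p_threshold = 5e-4)

  # power over planted effects whose cytosine survived the site filters
  planted <- ex$truth[ex$truth$kind %in%
                        c("cpg", "cph_shared", "cph_exclusive"), ]
  tested <- vapply(seq_len(nrow(planted)), function(i) {
    if (planted$context[i] == "CpG") planted$pos[i] %in% mcpg$pos
    else planted$pos[i] %in% mcph$pos
  }, logical(1))
  found <- vapply(seq_len(nrow(planted)), function(i) {
    h <- if (planted$context[i] == "CpG") hits_cpg else hits_cph
    any(h$feature_id == planted$feature_id[i] & h$pos == planted$pos[i])
  }, logical(1))

  # null pass rate: tested pairs on null features
  null_features <- setdiff(expr$feature_id, ex$truth$feature_id)
  all_cpg <- cis_scan(mcpg, expr[expr$feature_id %in% null_features, ],
                      window = 1000, p_threshold = 1)
  null_rate <- mean(all_cpg$p < 5e-4)
  n_null <- nrow(all_cpg)

  # CpH-exclusive classification among planted exclusives with a hit
  resc <- marginal_cpg_rescue(hits_cph, mcpg, expr, cpg_hits = hits_cpg)
  excl_feats <- ex$truth$feature_id[ex$truth$kind == "cph_exclusive"]
  cls <- resc$feature_classes
  cls_excl <- cls[cls$feature_id %in% excl_feats, ]
  excl_acc <- if (nrow(cls_excl) > 0) {
    mean(cls_excl$classification == "CpH-exclusive")
  } else NA_real_

  # t identity against a direct refit on a subset of hits
  b <- beta_values(mcpg)[, colnames(unclass(expr)$value), drop = FALSE]
  key <- paste(mcpg$chrom, mcpg$pos)
  check <- utils::head(hits_cpg, 10L)
  terr <- vapply(seq_len(nrow(check)), function(i) {
    x <- b[match(paste(check$chrom[i], check$pos[i]), key), ]
    y <- unclass(expr)$value[match(check$feature_id[i], expr$feature_id), ]
    r <- stats::cor(x, y)
    abs(check$t[i] - r * sqrt((length(x) - 2) / (1 - r^2)))
  }, numeric(1))

  list(
    power = mean(found[tested]),
    n_planted_tested = sum(tested),
    null_rate = null_rate,
    null_rate_z = (null_rate - 5e-4) /
      sqrt(5e-4 * (1 - 5e-4) / n_null),
    n_null_pairs = n_null,
    exclusive_accuracy = excl_acc,
    n_exclusive_classified = nrow(cls_excl),
    t_identity_max_err = max(terr)
  )
}

#' @describeIn benchmarks Calibration of the moderated site test: 10,000
#'   null sites with Gaussian methylation noise across 24 samples; the
#'   fraction of moderated p-values below 0.05.
#' @param n_sites Null sites simulated.
#' @export
benchmark_moderated_null <- function(seed, n_sites = 10000) {
  set.seed(seed)
  meta <- sample_meta(
    sprintf("s%02d", 1:24), rep(c("neuron", "glia"), each = 12),
    rep(seq(0, 23, length.out = 12), 2)
  )
  beta <- matrix(clamp01(stats::rnorm(n_sites * 24, 0.5, 0.1)),
                 n_sites, 24, dimnames = list(NULL, meta$sample_id))
  total <- matrix(30L, n_sites, 24, dimnames = list(NULL, meta$sample_id))
  m <- cytosine_matrix(
    tibble::tibble(chrom = "c", pos = seq_len(n_sites) * 10L,
                   strand = "+", trinucleotide = "CGA"),
    round(beta * 30), total
  )
  st <- fit_sitewise(m, meta, "age_plus_cell", coef = "cell")
  mt <- moderated_test(st)
  list(fraction_p05 = mean(mt$p < 0.05), n_sites = n_sites)
}
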