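#' Configuration for the synthetic bisulfite-methylome generator
#'
#' Bundles every knob of the generator with defaults that emulate the study
#' conditions the analysis assumes: 12 neuronal + 12 glial samples spanning
#' ages 0-23 years, negative-binomial coverage around 15x, a highly methylated
#' CpG background (roughly three quarters of observed CpGs above beta = 0.8),
#' sparse low-level CpH methylation (~99% of observed CpHs below beta = 0.2),
#' CpG positions laid down as an island + background mixture, and planted
#' UMR / LMR / PMD / DMV features, cell-type and cell-type-by-age DMRs in six
#' trajectory archetypes, and neuronal CpH accumulation with age.
#'
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   output.
#' @param n_neuron,n_glia,n_homogenate Sample counts per cell fraction.
#' @param ages_neuron,ages_glia,ages_homogenate Ages in years; default an
#'   even grid over `age_range`.
#' @param age_range Postnatal age span (years).
#' @param genome_length Simulated genome size in bp (single chromosome).
#' @param chrom Chromosome name.
#' @param cpg_background_rate,cpg_island_rate CpG sites per bp outside /
#'   inside CpG islands.
#' @param island_length,island_spacing Island geometry (bp).
#' @param cph_rate CpH sites per bp (uniform).
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and size
#'   for per-cell total read counts.
#' @param cpg_beta_weights,cpg_beta_shapes Baseline CpG beta mixture: weights
#'   and a 3x2 matrix of Beta shape pairs (high / intermediate / low
#'   components).
#' @param cph_beta_shapes Beta shapes of the baseline CpH level.
#' @param cph_age_fraction,cph_age_slope Fraction of CpH sites that gain
#'   methylation with age in neurons, and the gain (beta per year).
#' @param features Feature layout, see [sim_features()].
#' @param traj_diff Magnitude D (beta per year) of the neuron-minus-glia
#'   age-slope difference shared by all six trajectory archetypes; the
#'   archetype pattern fixes the planted neuron/glia median absolute age
#'   effect ratio at 1.5. Equal |D| across groups keeps the permutation
#'   null comparable across archetypes.
#' @param celltype_delta Cell-type DMR methylation difference (beta units).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_neuron = 12L, n_glia = 12L, n_homogenate = 0L,
                       ages_neuron = NULL, ages_glia = NULL,
                       ages_homogenate = NULL,
                       age_range = c(0, 23),
                       genome_length = 4e6, chrom = "chrS",
                       cpg_background_rate = 0.002,
                       cpg_island_rate = 0.05,
                       island_length = 1000, island_spacing = 10000,
                       cph_rate = 0.02,
                       coverage_mean = 15, coverage_dispersion = 8,
                       cpg_beta_weights = c(0.94, 0.04, 0.02),
                       cpg_beta_shapes = rbind(c(45, 4), c(5, 5), c(1.5, 15)),
                       cph_beta_shapes = c(0.5, 30),
                       cph_age_fraction = 0.30, cph_age_slope = 0.004,
                       features = sim_features(),
                       traj_diff = 0.016,
                       celltype_delta = 0.2,
                       assoc = sim_assoc()) {
  grid_ages <- function(n) {
    if (n == 0L) return(numeric(0))
    seq(age_range[1L], age_range[2L], length.out = n)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_neuron = n_neuron, n_glia = n_glia, n_homogenate = n_homogenate,
    ages_neuron = ages_neuron %||% grid_ages(n_neuron),
    ages_glia = ages_glia %||% grid_ages(n_glia),
    ages_homogenate = ages_homogenate %||% grid_ages(n_homogenate),
    genome_length = genome_length, chrom = chrom,
    cpg_background_rate = cpg_background_rate,
    cpg_island_rate = cpg_island_rate,
    island_length = island_length, island_spacing = island_spacing,
    cph_rate = cph_rate,
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    cpg_beta_weights = cpg_beta_weights / sum(cpg_beta_weights),
    cpg_beta_shapes = cpg_beta_shapes,
    cph_beta_shapes = cph_beta_shapes,
    cph_age_fraction = cph_age_fraction, cph_age_slope = cph_age_slope,
    features = features,
    traj_diff = traj_diff,
    celltype_delta = celltype_delta,
    assoc = assoc
  )
  stopifnot(
    genome_length > 0, cph_rate > 0, coverage_mean > 0,
    all(cfg$ages_neuron >= 0), all(cfg$ages_glia >= 0),
    length(cfg$ages_neuron) == n_neuron,
    length(cfg$ages_glia) == n_glia
  )
  structure(cfg, class = "sim_config")
}

#' Planted feature layout
#'
#' Counts, sizes (bp) and local CpG densities (sites per bp) for the planted
#' methylome features. DMR CpG counts are drawn uniformly from `dmr_n_cpg`.
#'
#' @param n_umr,n_lmr,n_dmv Numbers of planted unmethylated, low-methylated,
#'   and valley regions.
#' @param umr_length,lmr_length,dmv_length Length ranges (bp).
#' @param umr_density,lmr_density,dmv_density,dmr_density Local CpG densities.
#' @param umr_beta,lmr_beta True methylation level inside UMRs / LMRs.
#' @param pmd_lengths Lengths of planted partially methylated domains
#'   (site-level beta drawn from `pmd_beta_shapes`).
#' @param pmd_beta_shapes Beta shapes of the disordered PMD methylation.
#' @param n_celltype_dmr,n_interaction_dmr Numbers of planted DMRs.
#' @param dmr_n_cpg Range of CpGs per planted DMR.
#' @param gap_lengths,gap_labels Assembly gaps (no cytosines); gaps labelled
#'   `"heterochromatin"` are exempt from PMD exclusion and are placed inside
#'   the first PMD when one exists.
#' @param min_spacing Minimum distance between small features (bp).
#' @return A list consumed by [sim_config()].
#' @export
sim_features <- function(n_umr = 8L, umr_length = c(3000, 4500),
                         umr_density = 0.03, umr_beta = 0.05,
                         n_lmr = 10L, lmr_length = c(1200, 1800),
                         lmr_density = 0.01, lmr_beta = 0.2,
                         n_dmv = 2L, dmv_length = c(6000, 8000),
                         dmv_density = 0.03,
                         pmd_lengths = c(3e5, 1.5e5),
                         pmd_beta_shapes = c(2, 2),
                         n_celltype_dmr = 30L, n_interaction_dmr = 20L,
                         dmr_n_cpg = c(8L, 20L), dmr_density = 0.04,
                         gap_lengths = c(30000, 20000),
                         gap_labels = c("telomere", "heterochromatin"),
                         n_desert = 12L, desert_length = 3000,
                         min_spacing = 2500) {
  as.list(environment())
}

#' Planted methylation-expression association sites
#'
#' Designates background cytosines that carry donor-level methylation
#' variability and will anchor planted cis associations: CpG effects, CpH
#' effects sharing their donor surface with a CpG within 1 kb (`shared`),
#' CpH effects with no nearby tested CpG (`exclusive`, placed in CpG
#' deserts or sparse background), and CpG sites whose methylation tracks
#' age (material for the age-confounding check).
#'
#' @param n_cpg,n_cph_shared,n_cph_exclusive,n_cpg_age Site counts.
#' @param exclusive_in_desert How many exclusive CpH sites go into CpG-free
#'   desert segments (the rest land in sparse background).
#' @param donor_sd SD of the per-donor methylation deviation (beta units).
#' @param age_slope Beta-per-year slope of the age-tracking CpG sites.
#' @return A list consumed by [sim_config()].
#' @export
sim_assoc <- function(n_cpg = 15L, n_cph_shared = 5L, n_cph_exclusive = 10L,
                      n_cpg_age = 4L, exclusive_in_desert = 6L,
                      donor_sd = 0.15, age_slope = 0.022) {
  as.list(environment())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The six developmental trajectory archetypes as (glia, neuron) age-slope
# multipliers of the configured slope-difference magnitude D. Every group
# has |neuron - glia| = D, and the multiplier pattern puts the median
# absolute neuronal slope at 0.6 D and the glial at 0.4 D (ratio 1.5).
trajectory_archetypes <- function(config) {
  D <- config$traj_diff
  gm <- c(0, -0.4, 0, 2 / 3, -2 / 3, 0.4)
  nm <- c(1, 0.6, -1, -1 / 3, 1 / 3, -0.6)
  tibble::tibble(
    group = 1:6,
    glia_slope = gm * D,
    neuron_slope = nm * D,
    label = c("static glia / increasing neuron",
              "decreasing glia / increasing neuron",
              "static glia / decreasing neuron",
              "increasing glia / decreasing neuron",
              "decreasing glia / increasing neuron (glia-led)",
              "increasing glia / decreasing neuron (glia-led)")
  )
}

# Lay out non-overlapping feature spans (0-based half-open).
layout_features <- function(config) {
  f <- config$features
  G <- config$genome_length

  # Large blocks first: PMDs in the back 45% of the genome.
  regions <- list()
  pmd_n <- length(f$pmd_lengths)
  if (pmd_n > 0) {
    anchor <- floor(G * 0.55)
    avail <- G - anchor - 10000
    if (sum(f$pmd_lengths) + pmd_n * 20000 > avail) {
      stop("PMD layout infeasible for this genome length")
    }
    start <- anchor
    for (i in seq_len(pmd_n)) {
      regions[[length(regions) + 1L]] <- tibble::tibble(
        kind = "PMD", start = start, end = start + f$pmd_lengths[i],
        id = paste0("PMD_", i)
      )
      start <- start + f$pmd_lengths[i] + 20000
    }
  }

  # Assembly gaps: heterochromatin-labelled gaps sit inside the first PMD,
  # other gaps in free space before the PMD block.
  gaps <- tibble::tibble(
    kind = "gap",
    label = f$gap_labels,
    length = f$gap_lengths
  )
  gap_rows <- list()
  het <- which(gaps$label == "heterochromatin")
  if (length(het) > 0 && pmd_n > 0) {
    pmd1 <- regions[[1L]]
    at <- pmd1$start + floor((pmd1$end - pmd1$start) / 3)
    for (i in het) {
      gap_rows[[length(gap_rows) + 1L]] <- tibble::tibble(
        kind = "gap", start = at, end = at + gaps$length[i],
        id = paste0("gap_", i), label = gaps$label[i]
      )
      at <- at + gaps$length[i] + 5000
    }
  }
  nonhet <- setdiff(seq_len(nrow(gaps)), if (pmd_n > 0) het else integer(0))
  at <- floor(G * 0.50)
  for (i in nonhet) {
    at <- at - gaps$length[i] - 5000
    gap_rows[[length(gap_rows) + 1L]] <- tibble::tibble(
      kind = "gap", start = at, end = at + gaps$length[i],
      id = paste0("gap_", i), label = gaps$label[i]
    )
  }

  # Small features on a jittered grid over the front of the genome
  # (before the gaps/PMD block).
  runs <- function(n, range) {
    if (n == 0L) return(numeric(0))
    stats::runif(n, range[1L], range[2L])
  }
  dmr_sizes <- function(n) {
    if (n == 0L) return(integer(0))
    sample(seq(f$dmr_n_cpg[1L], f$dmr_n_cpg[2L]), n, replace = TRUE)
  }
  small <- tibble::tibble(
    kind = c(rep("UMR", f$n_umr), rep("LMR", f$n_lmr), rep("DMV", f$n_dmv),
             rep("DMR_celltype", f$n_celltype_dmr),
             rep("DMR_interaction", f$n_interaction_dmr),
             rep("desert", f$n_desert)),
    length = c(round(runs(f$n_umr, f$umr_length)),
               round(runs(f$n_lmr, f$lmr_length)),
               round(runs(f$n_dmv, f$dmv_length)),
               rep(NA_real_, f$n_celltype_dmr + f$n_interaction_dmr),
               rep(f$desert_length, f$n_desert)),
    density = c(rep(f$umr_density, f$n_umr), rep(f$lmr_density, f$n_lmr),
                rep(f$dmv_density, f$n_dmv),
                rep(f$dmr_density, f$n_celltype_dmr + f$n_interaction_dmr),
                rep(0, f$n_desert)),
    n_cpg_target = c(rep(NA_integer_, f$n_umr + f$n_lmr + f$n_dmv),
                     dmr_sizes(f$n_celltype_dmr + f$n_interaction_dmr),
                     rep(NA_integer_, f$n_desert))
  )
  dmr <- is.na(small$length)
  small$length[dmr] <- ceiling(small$n_cpg_target[dmr] / f$dmr_density)
  small <- small[sample.int(nrow(small)), ]

  front_end <- if (length(gap_rows) > 0 || pmd_n > 0) {
    min(c(vapply(gap_rows, function(g) g$start, numeric(1)),
          if (pmd_n > 0) regions[[1L]]$start else G)) - 5000
  } else {
    G - 5000
  }
  need <- sum(small$length) + nrow(small) * f$min_spacing
  if (need > front_end - 5000) {
    stop("feature layout infeasible: ", nrow(small),
         " features need ~", need, " bp but only ", front_end,
         " bp available; enlarge the genome or reduce feature counts")
  }
  slack <- (front_end - 5000 - sum(small$length)) / nrow(small)
  start <- 5000
  small$start <- NA_real_
  for (i in seq_len(nrow(small))) {
    offset <- stats::runif(1, f$min_spacing, max(slack, f$min_spacing + 1))
    small$start[i] <- round(start + offset - f$min_spacing)
    start <- small$start[i] + small$length[i] + f$min_spacing
  }
  small$end <- small$start + small$length
  small$id <- paste0(small$kind, "_", stats::ave(seq_len(nrow(small)),
                                                 small$kind, FUN = seq_along))

  big <- dplyr::bind_rows(regions)
  if (nrow(big) > 0) {
    big$density <- config$cpg_background_rate
    big$length <- big$end - big$start
  }
  out <- dplyr::bind_rows(
    small[, c("kind", "id", "start", "end", "length", "density",
              "n_cpg_target")],
    big
  )
  list(features = out, gaps = dplyr::bind_rows(gap_rows))
}

#' Simulate a whole-genome bisulfite methylome with planted features
#'
#' Draws cytosine positions (CpG as an island/background mixture, CpH
#' uniform), builds the true per-site, per-sample methylation surface
#' `clamp01(b0 + b_cell * cell + b_age * age + b_int * age * cell)` with the
#' configured planted features, then samples counts: total reads per cell
#' from a negative binomial and methylated reads binomially at the true beta.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_methylome` with elements `matrix` (a
#'   cytosine matrix), `meta` (sample metadata), and `truth` (planted
#'   regions, gap track, archetype table, true beta surface and site table —
#'   sufficient to score every downstream stage).
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  f <- config$features
  lay <- layout_features(config)
  feats <- lay$features
  gaps <- lay$gaps
  feats$chrom <- rep(config$chrom, nrow(feats))
  if (nrow(gaps) > 0) gaps$chrom <- config$chrom

  meta <- sample_meta(
    sample_id = c(sprintf("neuron_%02d", seq_len(config$n_neuron)),
                  sprintf("glia_%02d", seq_len(config$n_glia)),
                  sprintf("homog_%02d", seq_len(config$n_homogenate))),
    cell_fraction = c(rep("neuron", config$n_neuron),
                      rep("glia", config$n_glia),
                      rep("homogenate", config$n_homogenate)),
    age = c(config$ages_neuron, config$ages_glia, config$ages_homogenate)
  )
  n_samp <- nrow(meta)

  # ---- positions -----------------------------------------------------------
  G <- config$genome_length
  # segment the genome into (background | island | feature | gap) pieces
  brk <- sort(unique(c(0, G,
                       feats$start, feats$end,
                       if (nrow(gaps) > 0) c(gaps$start, gaps$end),
                       seq(0, G, by = config$island_spacing),
                       seq(config$island_length, G,
                           by = config$island_spacing))))
  seg <- tibble::tibble(start = brk[-length(brk)], end = brk[-1L])
  seg_mid <- (seg$start + seg$end) / 2
  in_island <- (seg_mid %% config$island_spacing) < config$island_length
  seg$rate <- ifelse(in_island, config$cpg_island_rate,
                     config$cpg_background_rate)
  fidx <- overlap_index(seg_mid, feats)
  seg$rate[!is.na(fidx)] <- feats$density[fidx[!is.na(fidx)]]
  gidx <- overlap_index(seg_mid, gaps)
  seg$rate[!is.na(gidx)] <- 0

  cpg_pos <- draw_positions(seg, seg$rate)
  # guarantee planted DMRs their target CpG count
  dmr_rows <- which(grepl("^DMR", feats$kind))
  for (i in dmr_rows) {
    inside <- cpg_pos > feats$start[i] & cpg_pos <= feats$end[i]
    deficit <- feats$n_cpg_target[i] - sum(inside)
    if (deficit > 0) {
      extra <- sample(seq(feats$start[i] + 1L, feats$end[i]), deficit)
      cpg_pos <- c(cpg_pos, extra)
    }
  }
  cpg_pos <- sort(unique(cpg_pos))

  seg$cph_rate <- ifelse(!is.na(gidx), 0, config$cph_rate)
  # CpH runs about twice as dense as CpG inside the interaction DMRs
  int_rows <- which(feats$kind == "DMR_interaction")
  iidx <- overlap_index(seg_mid, feats[int_rows, , drop = FALSE])
  seg$cph_rate[!is.na(iidx)] <- 2 * f$dmr_density
  cph_pos <- draw_positions(seg, seg$cph_rate)
  cph_pos <- sort(setdiff(cph_pos, cpg_pos))

  n_cpg <- length(cpg_pos)
  n_cph <- length(cph_pos)
  sites <- tibble::tibble(
    chrom = config$chrom,
    pos = c(cpg_pos, cph_pos),
    strand = sample(c("+", "-"), n_cpg + n_cph, replace = TRUE),
    trinucleotide = c(
      paste0("CG", sample(c("A", "C", "T", "G"), n_cpg, replace = TRUE)),
      sample(c("CAC", "CAG", "CAT", "CAA", "CTG", "CCG", "CTA", "CCT"),
             n_cph, replace = TRUE,
             prob = c(0.25, 0.20, 0.12, 0.12, 0.11, 0.08, 0.06, 0.06))
    )
  )
  ord <- order(sites$pos)
  sites <- sites[ord, ]
  sites$context <- context_from_trinucleotide(sites$trinucleotide)
  n_sites <- nrow(sites)

  # ---- true beta surface ---------------------------------------------------
  is_cpg <- sites$context == "CpG"
  base <- numeric(n_sites)
  comp <- sample.int(3L, sum(is_cpg), replace = TRUE,
                     prob = config$cpg_beta_weights)
  sh <- config$cpg_beta_shapes
  base[is_cpg] <- stats::rbeta(sum(is_cpg), sh[comp, 1L], sh[comp, 2L])
  base[!is_cpg] <- stats::rbeta(sum(!is_cpg), config$cph_beta_shapes[1L],
                                config$cph_beta_shapes[2L])

  b_cell <- numeric(n_sites)   # added for neuron samples
  b_age <- numeric(n_sites)    # per year, all fractions
  b_int <- numeric(n_sites)    # per year, neurons only
  arch <- trajectory_archetypes(config)

  feats$group <- NA_integer_
  feats$delta_beta <- NA_real_
  feats$glia_slope <- NA_real_
  feats$neuron_slope <- NA_real_
  feats$true_beta <- NA_real_

  site_feature <- overlap_index(sites$pos - 0.5, feats)
  ct_i <- 0L
  int_i <- 0L
  for (i in seq_len(nrow(feats))) {
    rows <- which(site_feature == i)
    kind <- feats$kind[i]
    if (kind == "UMR") {
      base[rows] <- clamp01(stats::rnorm(length(rows), f$umr_beta, 0.02))
      feats$true_beta[i] <- f$umr_beta
    } else if (kind == "DMV") {
      base[rows] <- clamp01(stats::rnorm(length(rows), f$umr_beta, 0.02))
      feats$true_beta[i] <- f$umr_beta
    } else if (kind == "LMR") {
      base[rows] <- clamp01(stats::rnorm(length(rows), f$lmr_beta, 0.03))
      feats$true_beta[i] <- f$lmr_beta
    } else if (kind == "PMD") {
      cg <- rows[is_cpg[rows]]
      base[cg] <- stats::rbeta(length(cg), f$pmd_beta_shapes[1L],
                               f$pmd_beta_shapes[2L])
    } else if (kind == "DMR_celltype") {
      ct_i <- ct_i + 1L
      sgn <- if (ct_i %% 2L == 0L) -1 else 1
      delta <- sgn * config$celltype_delta
      cg <- rows[is_cpg[rows]]
      base[cg] <- stats::runif(1, 0.35, 0.6) - delta / 2 +
        stats::rnorm(length(cg), 0, 0.01)
      b_cell[cg] <- delta
      feats$delta_beta[i] <- delta
    } else if (kind == "DMR_interaction") {
      int_i <- int_i + 1L
      g <- ((int_i - 1L) %% 6L) + 1L
      s_g <- arch$glia_slope[g]
      s_n <- arch$neuron_slope[g]
      mid_age <- mean(range(c(config$ages_neuron, config$ages_glia)))
      b0 <- 0.5 - mid_age * (s_g + s_n) / 2 + stats::runif(1, -0.04, 0.04)
      # smooth spatial profile shared by every cytosine (CpG and CpH) in
      # the region: first-order autoregressive along site order, truncated
      # so the trajectory endpoints stay off the [0, 1] boundaries
      profile <- as.numeric(stats::filter(
        stats::rnorm(length(rows) + 20L, 0, 0.10 * sqrt(1 - 0.8^2)),
        0.8, method = "recursive"))[-seq_len(20L)]
      profile <- pmax(pmin(profile, 0.2), -0.2)
      base[rows] <- b0 + profile
      b_age[rows] <- s_g
      b_int[rows] <- s_n - s_g
      feats$group[i] <- g
      feats$glia_slope[i] <- s_g
      feats$neuron_slope[i] <- s_n
    }
  }

  # background neuronal CpH accumulation with age
  cph_gain <- !is_cpg & is.na(site_feature) &
    stats::runif(n_sites) < config$cph_age_fraction
  b_int[cph_gain] <- b_int[cph_gain] + config$cph_age_slope

  is_neuron <- as.numeric(meta$cell_fraction == "neuron")
  # homogenate = average of the two fractions
  cell_w <- ifelse(meta$cell_fraction == "homogenate", 0.5, is_neuron)
  age <- meta$age
  beta_true <- clamp01(
    base +
      outer(b_cell, cell_w) +
      outer(b_age, age) +
      outer(b_int, age * cell_w)
  )
  colnames(beta_true) <- meta$sample_id

  # ---- planted association sites ------------------------------------------
  a <- config$assoc
  desert_rows <- which(feats$kind == "desert")
  in_desert <- !is.na(site_feature) & site_feature %in% desert_rows
  bg <- is.na(site_feature) | in_desert
  bg_cpg_idx <- which(is_cpg & is.na(site_feature))
  bg_cph_idx <- which(!is_cpg & bg & !cph_gain)
  pick <- function(idx, n) {
    if (length(idx) < n) stop("too few background sites for planted associations")
    sample(idx, n)
  }
  used <- integer(0)
  assoc_rows <- list()
  add_assoc <- function(idx, kind, pair) {
    tibble::tibble(site = idx, kind = kind, pair_id = pair)
  }

  cpg_pick <- pick(bg_cpg_idx, a$n_cpg)
  used <- c(used, cpg_pick)
  assoc_rows$cpg <- add_assoc(cpg_pick, "cpg", paste0("cpg_", seq_along(cpg_pick)))

  # shared pairs: a CpH with a background CpG within 800 bp
  cpg_pos_all <- sites$pos[bg_cpg_idx]
  shared_cph <- integer(0)
  shared_cpg <- integer(0)
  cand <- setdiff(bg_cph_idx[!in_desert[bg_cph_idx]], used)
  for (i in sample(cand)) {
    if (length(shared_cph) >= a$n_cph_shared) break
    d <- abs(cpg_pos_all - sites$pos[i])
    j <- which.min(d)
    if (d[j] <= 800 && !(bg_cpg_idx[j] %in% used)) {
      shared_cph <- c(shared_cph, i)
      shared_cpg <- c(shared_cpg, bg_cpg_idx[j])
      used <- c(used, i, bg_cpg_idx[j])
    }
  }
  pair <- paste0("shared_", seq_along(shared_cph))
  assoc_rows$shared_cph <- add_assoc(shared_cph, "cph_shared", pair)
  assoc_rows$shared_cpg <- add_assoc(shared_cpg, "cpg_partner", pair)

  # exclusive CpH: deserts first, then the CpHs farthest from any CpG
  desert_cph <- setdiff(which(!is_cpg & in_desert), used)
  n_des <- min(a$exclusive_in_desert, a$n_cph_exclusive, length(desert_cph))
  excl <- if (n_des > 0) sample(desert_cph, n_des) else integer(0)
  remaining <- a$n_cph_exclusive - length(excl)
  if (remaining > 0) {
    cand <- setdiff(bg_cph_idx, c(used, excl))
    dist_cpg <- vapply(sites$pos[cand],
                       function(p) min(abs(cpg_pos_all - p)), numeric(1))
    excl <- c(excl, cand[order(-dist_cpg)][seq_len(remaining)])
  }
  used <- c(used, excl)
  assoc_rows$excl <- add_assoc(excl, "cph_exclusive",
                               paste0("excl_", seq_along(excl)))

  age_pick <- pick(setdiff(bg_cpg_idx, used), a$n_cpg_age)
  used <- c(used, age_pick)
  assoc_rows$age <- add_assoc(age_pick, "cpg_age",
                              paste0("age_", seq_along(age_pick)))

  assoc_sites <- dplyr::bind_rows(assoc_rows)
  assoc_sites$b0 <- stats::runif(nrow(assoc_sites), 0.35, 0.65)
  # shared pairs use one b0 and one donor-deviation vector
  mid_age <- mean(range(age))
  for (p in unique(assoc_sites$pair_id[assoc_sites$kind %in%
                                       c("cph_shared", "cpg_partner")])) {
    rows <- which(assoc_sites$pair_id == p)
    assoc_sites$b0[rows] <- assoc_sites$b0[rows[1L]]
  }
  for (i in seq_len(nrow(assoc_sites))) {
    r <- assoc_sites$site[i]
    if (assoc_sites$kind[i] == "cpg_age") {
      beta_true[r, ] <- clamp01(assoc_sites$b0[i] +
                                  a$age_slope * (age - mid_age))
    } else if (assoc_sites$kind[i] == "cpg_partner") {
      next # filled together with its CpH below
    } else {
      u <- stats::rnorm(n_samp, 0, a$donor_sd)
      beta_true[r, ] <- clamp01(assoc_sites$b0[i] + u)
      if (assoc_sites$kind[i] == "cph_shared") {
        partner <- assoc_sites$site[assoc_sites$pair_id ==
                                      assoc_sites$pair_id[i] &
                                      assoc_sites$kind == "cpg_partner"]
        beta_true[partner, ] <- clamp01(assoc_sites$b0[i] + u)
      }
    }
  }
  assoc_sites$pos <- sites$pos[assoc_sites$site]
  assoc_sites$context <- sites$context[assoc_sites$site]

  # ---- counts --------------------------------------------------------------
  total <- matrix(
    stats::rnbinom(n_sites * n_samp, mu = config$coverage_mean,
                   size = config$coverage_dispersion),
    nrow = n_sites, dimnames = list(NULL, meta$sample_id)
  )
  meth <- matrix(
    stats::rbinom(n_sites * n_samp, as.vector(total), as.vector(beta_true)),
    nrow = n_sites, dimnames = list(NULL, meta$sample_id)
  )

  mat <- cytosine_matrix(sites, meth, total)
  # cytosine_matrix re-sorts by (chrom, strand, pos); carry truth along
  ord2 <- order(sites$chrom, sites$pos, sites$strand)

  truth <- list(
    features = feats,
    gaps = gaps,
    archetypes = arch,
    sites = sites[ord2, c("chrom", "pos", "strand", "context",
                          "trinucleotide")],
    beta_true = beta_true[ord2, , drop = FALSE],
    site_feature = site_feature[ord2],
    cph_age_gain = cph_gain[ord2],
    assoc_sites = assoc_sites[, c("pos", "context", "kind", "pair_id", "b0")]
  )
  structure(list(matrix = mat, meta = meta, truth = truth, config = config),
            class = "sim_methylome")
}

# index of the (first) feature span covering each point, NA if none;
# spans are 0-based half-open
overlap_index <- function(points, spans) {
  if (is.null(spans) || nrow(spans) == 0) return(rep(NA_integer_, length(points)))
  out <- rep(NA_integer_, length(points))
  for (i in seq_len(nrow(spans))) {
    hit <- points >= spans$start[i] & points < spans$end[i]
    out[hit & is.na(out)] <- i
  }
  out
}

# Poisson draws of positions over segments with per-segment rates
draw_positions <- function(seg, rate) {
  keep <- rate > 0 & seg$end > seg$start
  pos <- purrr::map(which(keep), function(i) {
    n <- stats::rpois(1L, rate[i] * (seg$end[i] - seg$start[i]))
    if (n == 0L) return(integer(0))
    sort(sample(seq(seg$start[i] + 1L, seg$end[i]), min(n, seg$end[i] - seg$start[i])))
  })
  sort(unique(unlist(pos)))
}

clamp01 <- function(x) {
  x[which(x < 0)] <- 0
  x[which(x > 1)] <- 1
  x
}
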