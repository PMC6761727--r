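small_features <- sim_features(n_umr = 2L, n_lmr = 2L, n_dmv = 1L,
                               n_celltype_dmr = 8L, n_interaction_dmr = 6L,
                               pmd_lengths = numeric(0), n_desert = 4L)

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 101, genome_length = 5e5,
                    features = small_features)
  a <- simulate_methylome(cfg)
  b <- simulate_methylome(cfg)
  expect_identical(meth_counts(a$matrix), meth_counts(b$matrix))
  expect_identical(a$truth$features, b$truth$features)
  expect_false(identical(
    meth_counts(a$matrix),
    meth_counts(simulate_methylome(sim_config(
      seed = 102, genome_length = 5e5, features = small_features
    ))$matrix)
  ))
})

test_that("marginal beta distributions match the configured mixture", {
  sim <- simulate_methylome(sim_config(seed = 7))
  b <- beta_values(sim$matrix)
  cg <- sim$matrix$context == "CpG"
  # highly methylated CpG landscape and sparse CpH methylation
  expect_gt(mean(b[cg, ] > 0.8, na.rm = TRUE), 0.65)
  expect_lt(mean(b[cg, ] > 0.8, na.rm = TRUE), 0.80)
  expect_gt(mean(b[!cg, ] < 0.2, na.rm = TRUE), 0.92)
  # coverage close to the configured mean
  expect_equal(mean(total_counts(sim$matrix)), 15, tolerance = 0.05)
})

test_that("counts respect the binomial structure and truth aligns with sites", {
  sim <- simulate_methylome(sim_config(seed = 5, genome_length = 5e5,
                                       features = small_features))
  expect_true(all(meth_counts(sim$matrix) <= total_counts(sim$matrix)))
  expect_equal(nrow(sim$truth$beta_true), nrow(sim$matrix))
  expect_equal(sim$truth$sites$pos, sim$matrix$pos)
  # observed beta is centred on the truth where coverage is decent
  b <- beta_values(sim$matrix)
  hi <- total_counts(sim$matrix) >= 10
  err <- (b - sim$truth$beta_true)[hi]
  expect_lt(abs(mean(err, na.rm = TRUE)), 0.005)
})

test_that("null effect configuration yields a null methylome", {
  cfg <- sim_config(seed = 31, genome_length = 6e5,
                    cph_age_fraction = 0, traj_diff = 0, celltype_delta = 0,
                    features = sim_features(n_celltype_dmr = 2L,
                                            n_interaction_dmr = 2L,
                                            pmd_lengths = numeric(0)))
  sim <- simulate_methylome(cfg)
  meta <- sim$meta
  b <- beta_values(sim$matrix)
  neu <- rowMeans(b[, meta$sample_id[meta$cell_fraction == "neuron"]],
                  na.rm = TRUE)
  gli <- rowMeans(b[, meta$sample_id[meta$cell_fraction == "glia"]],
                  na.rm = TRUE)
  expect_lt(abs(mean(neu - gli, na.rm = TRUE)), 0.002)
})

test_that("infeasible feature layouts fail before sampling", {
  expect_error(
    simulate_methylome(sim_config(seed = 1, genome_length = 2e5)),
    "infeasible"
  )
})

test_that("planted expression effects realize the target R2", {
  cfg <- sim_config(seed = 19, n_neuron = 22L, n_glia = 0L,
                    genome_length = 1e6,
                    features = sim_features(n_celltype_dmr = 0L,
                                            n_interaction_dmr = 0L,
                                            pmd_lengths = numeric(0)))
  sim <- simulate_methylome(cfg)
  ex <- simulate_expression(sim, target_r2 = 0.5)
  b <- beta_values(sim$matrix)[, ex$donors]
  planted <- ex$truth[ex$truth$kind == "cpg", ]
  r2 <- vapply(seq_len(nrow(planted)), function(i) {
    x <- b[match(planted$pos[i], sim$matrix$pos), ]
    y <- unclass(ex$expression)$value[
      match(planted$feature_id[i], ex$expression$feature_id), ]
    if (planted$feature_type[i] %in% c("gene", "exon")) y <- log2(y + 1)
    cor(x, y, use = "complete.obs")^2
  }, numeric(1))
  # mean realized R2 near the target (per-pair values vary at n = 22)
  expect_equal(mean(r2), 0.5, tolerance = 0.12)
})

test_that("PSI stays in [0, 1] and null features are independent of methylation", {
  cfg <- sim_config(seed = 23, genome_length = 1e6,
                    features = sim_features(n_celltype_dmr = 0L,
                                            n_interaction_dmr = 0L,
                                            pmd_lengths = numeric(0)))
  sim <- simulate_methylome(cfg)
  ex <- simulate_expression(sim)
  v <- unclass(ex$expression)$value
  psi <- ex$expression$feature_type == "PSI"
  expect_true(all(v[psi, ] >= 0 & v[psi, ] <= 1))
  expect_true(all(v >= 0))
  # a null feature's values do not correlate with a random cytosine
  b <- beta_values(sim$matrix)[, ex$donors]
  set.seed(1)
  nulls <- grep("null", ex$expression$feature_id)[1:15]
  rs <- vapply(nulls, function(i) {
    x <- b[sample.int(nrow(b), 1), ]
    suppressWarnings(cor(x, v[i, ], use = "complete.obs"))
  }, numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.15)
})

test_that("annotation tracks tile the genome and support enrichment recovery", {
  cfg <- sim_config(seed = 29, genome_length = 1e6,
                    features = sim_features(n_celltype_dmr = 0L,
                                            n_interaction_dmr = 0L,
                                            pmd_lengths = numeric(0)))
  sim <- simulate_methylome(cfg)
  ann <- simulate_annotation(cfg, sim$truth)
  expect_equal(sum(ann$states$end - ann$states$start), cfg$genome_length)
  expect_true(all(ann$states$start < ann$states$end))
  expect_equal(length(unique(ann$states$state)) <= 15, TRUE)
  # planted bias of the active-TSS state inside UMRs is recoverable
  umrs <- sim$truth$features[sim$truth$features$kind %in% c("UMR", "DMV"), ]
  sc <- state_composition(umrs, ann$states)
  expect_gt(sc$log2_enrichment[sc$state == "1_TssA"], 0.5)
  # gene models do not overlap
  g <- ann$genes[order(ann$genes$start), ]
  expect_true(all(utils::head(g$end, -1) <= utils::tail(g$start, -1)))
})

test_that("written simulation files are readable plain text", {
  cfg <- sim_config(seed = 41, genome_length = 3e5, n_neuron = 2L,
                    n_glia = 2L,
                    features = sim_features(n_umr = 1L, n_lmr = 1L,
                                            n_dmv = 0L, n_celltype_dmr = 2L,
                                            n_interaction_dmr = 2L,
                                            pmd_lengths = numeric(0),
                                            n_desert = 2L,
                                            gap_lengths = numeric(0),
                                            gap_labels = character(0)))
  sim <- simulate_methylome(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  reports <- list.files(dir, pattern = "cx_report", full.names = TRUE)
  expect_length(reports, 4L)
  names(reports) <- sub("\\.cx_report\\.txt$", "", basename(reports))
  m2 <- read_cytosine_report(reports[sample_ids(sim$matrix)])
  expect_identical(meth_counts(m2), meth_counts(sim$matrix))
  expect_true(file.exists(file.path(dir, "truth.json")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_true("features" %in% names(truth))
})
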