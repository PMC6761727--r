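test_that("site-wise OLS recovers exact linear structure", {
  meta <- balanced_meta(3)  # 6 samples
  cell <- as.numeric(meta$cell_fraction == "neuron")
  beta <- matrix(0.5 + 0.1 * cell, nrow = 1,
                 dimnames = list(NULL, meta$sample_id))
  m <- beta_matrix_fixture(rbind(beta, beta + 0.01), coverage = 1e6L)
  st <- fit_sitewise(m, meta, "age_plus_cell", coef = "cell")
  expect_equal(st$coefficient, c(0.1, 0.1), tolerance = 1e-6)
  expect_equal(st$sigma2, c(0, 0), tolerance = 1e-10)
})

test_that("site-wise coefficients match the closed-form normal equations", {
  set.seed(21)
  meta <- balanced_meta(3)
  beta <- matrix(runif(6 * 6, 0.2, 0.8), 6, 6,
                 dimnames = list(NULL, meta$sample_id))
  m <- beta_matrix_fixture(beta, coverage = 1000L)
  st <- fit_sitewise(m, meta, "age_by_cell_interaction")
  X <- cbind(1, meta$age, as.numeric(meta$cell_fraction == "neuron"),
             meta$age * as.numeric(meta$cell_fraction == "neuron"))
  bv <- beta_values(m)
  for (i in 1:6) {
    coefs <- solve(t(X) %*% X) %*% t(X) %*% bv[i, ]
    expect_equal(st$coefficient[i], coefs[4, 1], tolerance = 1e-10)
    res <- bv[i, ] - X %*% coefs
    expect_equal(st$sigma2[i], sum(res^2) / (6 - 4), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  meta <- sample_meta(paste0("s", 1:8), rep("neuron", 8), age = 1:8)
  m <- beta_matrix_fixture(matrix(0.5, 3, 8,
                                  dimnames = list(NULL, meta$sample_id)))
  expect_error(fit_sitewise(m, meta, "age_plus_cell"), "collinear")
})

test_that("permuted null coefficients centre at zero", {
  set.seed(13)
  meta <- balanced_meta(12)
  beta <- matrix(runif(500 * 24, 0.4, 0.6), 500, 24,
                 dimnames = list(NULL, meta$sample_id))
  meta_perm <- meta
  meta_perm$cell_fraction <- sample(meta$cell_fraction)
  m <- beta_matrix_fixture(beta, coverage = 30L)
  st <- fit_sitewise(m, meta_perm, "age_plus_cell", coef = "cell")
  expect_lt(abs(mean(st$coefficient)), 0.005)
})

test_that("moderated variance interpolates between the limits", {
  set.seed(17)
  meta <- balanced_meta(12)
  beta <- matrix(rnorm(500 * 24, 0.5, 0.05), 500, 24,
                 dimnames = list(NULL, meta$sample_id))
  m <- beta_matrix_fixture(pmin(pmax(beta, 0), 1), coverage = 50L)
  st <- fit_sitewise(m, meta, "age_plus_cell", coef = "cell")
  # d0 -> Inf: every moderated variance is the prior variance
  inf_fit <- moderated_test(st, prior_df = Inf, prior_var = 0.003)
  expect_true(all(inf_fit$s2_moderated == 0.003))
  # d0 = 0: moderated t equals the ordinary t
  zero_fit <- moderated_test(st, prior_df = 0, prior_var = 1)
  t_ord <- st$coefficient / (sqrt(st$sigma2) * attr(st, "stdev_unscaled"))
  expect_equal(zero_fit$t, t_ord, tolerance = 1e-12)
  # estimated fit shrinks between the two
  est <- moderated_test(st)
  expect_true(all(
    (est$s2_moderated - st$sigma2) *
      (attr(est, "prior_var") - st$sigma2) >= -1e-12
  ))
  # q monotone in p
  expect_true(all(diff(est$q[order(est$p)]) >= -1e-12))
})

test_that("moderated statistics agree with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(23)
  meta <- balanced_meta(12)
  beta <- matrix(pmin(pmax(rnorm(800 * 24, 0.5, 0.1), 0), 1), 800, 24,
                 dimnames = list(NULL, meta$sample_id))
  m <- beta_matrix_fixture(beta, coverage = 30L)
  st <- fit_sitewise(m, meta, "age_plus_cell", coef = "cell")
  mt <- moderated_test(st)
  X <- cbind(1, meta$age, as.numeric(meta$cell_fraction == "neuron"))
  ref <- limma::eBayes(limma::lmFit(beta_values(m), X))
  expect_equal(attr(mt, "prior_df"), ref$df.prior, tolerance = 1e-6)
  expect_equal(mt$t, ref$t[, 3], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(mt$p, ref$p.value[, 3], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("bump hunting refuses a useless number of permutations", {
  meta <- balanced_meta(3)
  m <- beta_matrix_fixture(matrix(0.5, 10, 6,
                                  dimnames = list(NULL, meta$sample_id)))
  expect_error(bumphunt(m, meta, "age_plus_cell", cutoff = 0.1,
                        n_perms = 10, use_smoothed = FALSE), "refuse")
})

test_that("bump hunting is reproducible and symmetric under sign flips", {
  set.seed(31)
  meta <- balanced_meta(6)
  cell <- as.numeric(meta$cell_fraction == "neuron")
  n <- 300
  truth <- matrix(0.5, n, 12)
  truth[101:110, ] <- truth[101:110, ] + 0.25 * rep(cell, each = 10)
  beta <- pmin(pmax(truth + rnorm(n * 12, 0, 0.03), 0), 1)
  colnames(beta) <- meta$sample_id
  m <- beta_matrix_fixture(beta, coverage = 60L)
  bh1 <- bumphunt(m, meta, "age_plus_cell", coef = "cell", cutoff = 0.1,
                  n_perms = 50, seed = 5, use_smoothed = FALSE)
  bh2 <- bumphunt(m, meta, "age_plus_cell", coef = "cell", cutoff = 0.1,
                  n_perms = 50, seed = 5, use_smoothed = FALSE)
  expect_identical(bh1$regions, bh2$regions)
  expect_true(all(bh1$regions$fwer >= 0 & bh1$regions$fwer <= 1))
  # FWER non-increasing in area
  ord <- order(bh1$regions$area)
  expect_true(all(diff(bh1$regions$fwer[ord]) <= 1e-12))
  # planted region found
  sig <- significant_regions(bh1)
  expect_true(any(sig$start < 110 * 10 & sig$end > 101 * 10))
  # sign flip: mirrored beta gives the same regions with flipped direction
  m_flip <- beta_matrix_fixture(1 - beta, coverage = 60L)
  bh3 <- bumphunt(m_flip, meta, "age_plus_cell", coef = "cell", cutoff = 0.1,
                  n_perms = 50, seed = 5, use_smoothed = FALSE)
  expect_equal(bh3$regions$start, bh1$regions$start)
  expect_equal(bh3$regions$area, bh1$regions$area, tolerance = 1e-12)
  expect_true(all(bh3$regions$direction != bh1$regions$direction))
})

test_that("a single extreme CpG can be a valid region", {
  set.seed(37)
  meta <- balanced_meta(6)
  cell <- as.numeric(meta$cell_fraction == "neuron")
  n <- 200
  beta <- matrix(pmin(pmax(rnorm(n * 12, 0.5, 0.02), 0), 1), n, 12,
                 dimnames = list(NULL, meta$sample_id))
  beta[50, ] <- 0.2 + 0.6 * cell  # one huge single-site difference
  m <- beta_matrix_fixture(beta, coverage = 200L)
  bh <- bumphunt(m, meta, "age_plus_cell", coef = "cell", cutoff = 0.1,
                 n_perms = 100, seed = 1, use_smoothed = FALSE)
  sig <- significant_regions(bh)
  expect_true(any(sig$n_cpg == 1 & sig$start == 499))
})

test_that("design comparison quantifies concordance and mixture masking", {
  set.seed(41)
  meta <- balanced_meta(12)
  n <- 2000
  cell <- as.numeric(meta$cell_fraction == "neuron")
  base <- matrix(0.5, n, 24)
  # 100 sites change with age in opposite directions per fraction
  idx <- 1:100
  slope <- 0.012
  base[idx, ] <- 0.5 +
    outer(rep(slope, 100), meta$age * ifelse(cell == 1, 1, -1))
  beta <- pmin(pmax(base + rnorm(n * 24, 0, 0.02), 0), 1)
  colnames(beta) <- meta$sample_id
  m <- beta_matrix_fixture(beta, coverage = 100L)
  ct <- moderated_test(fit_sitewise(m, meta, "age_by_cell_interaction",
                                    coef = "age:cell"))
  # homogenate = average of fractions: opposite effects cancel
  hom_beta <- (beta[, cell == 1] + beta[, cell == 0]) / 2
  hmeta <- sample_meta(colnames(hom_beta), rep("homogenate", 12),
                       meta$age[cell == 1])
  colnames(hom_beta) <- hmeta$sample_id
  hm <- beta_matrix_fixture(hom_beta, coverage = 100L)
  hom <- moderated_test(fit_sitewise(hm, hmeta, "age_only"))
  hom$chrom <- ct$chrom[match(hom$pos, ct$pos)]
  cmp <- compare_designs(ct, hom, p_threshold = 1e-4)
  expect_equal(cmp$n_shared, n)
  # the cell-specific sites are invisible in homogenate
  expect_gt(cmp$fraction_celltype_only, 0.9)
  # identical fits give perfect concordance
  cmp2 <- compare_designs(ct, ct, p_threshold = 1e-4)
  expect_equal(cmp2$coefficient_correlation, 1)
})
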