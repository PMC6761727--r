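expr_fixture <- function(values, types = "gene", starts = 1000L,
                         denominator = NA_integer_, coding = TRUE) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("d%02d", seq_len(ncol(values)))
  }
  n <- nrow(values)
  out <- tibble::tibble(
    feature_id = sprintf("f%03d", seq_len(n)),
    feature_type = rep(types, length.out = n),
    chrom = "chrT",
    start = rep(starts, length.out = n),
    end = rep(starts, length.out = n) + 500L,
    strand = "+",
    gene_id = sprintf("g%03d", seq_len(n)),
    coding = rep(coding, length.out = n)
  )
  out$value <- values
  out$denominator <- rep(denominator, length.out = n)
  out
}

test_that("expression filters apply the strict cutoffs and transforms", {
  v <- rbind(rep(0.22, 4), rep(0.3, 4), rep(0.3, 4), rep(0.5, 4),
             rep(0.5, 4))
  raw <- expr_fixture(v, types = c("gene", "gene", "exon", "PSI", "PSI"),
                      denominator = c(NA, NA, NA, 25L, 5L))
  out <- filter_expression(raw)
  # gene at exactly 0.22 dropped (strict >); PSI with denominator 5 dropped
  expect_equal(out$feature_id, c("f002", "f003", "f004"))
  vv <- unclass(out)$value
  expect_equal(unname(vv[1, 1]), log2(0.3 + 1))
  expect_equal(unname(vv[3, 1]), 0.5)  # PSI untransformed

  # brute-force agreement on a random toy table
  set.seed(12)
  v2 <- matrix(runif(10 * 4, 0, 0.6), 10)
  raw2 <- expr_fixture(v2, types = rep(c("gene", "exon"), 5))
  keep <- ifelse(raw2$feature_type == "gene",
                 rowMeans(v2) > 0.22, rowMeans(v2) > 0.26)
  expect_equal(filter_expression(raw2)$feature_id, raw2$feature_id[keep])
})

test_that("cis scan matches the closed-form correlation identity and lm", {
  set.seed(14)
  n_donor <- 22
  beta <- matrix(runif(5 * n_donor, 0.1, 0.9), 5)
  m <- beta_matrix_fixture(beta, coverage = 1e6L,
                           pos = c(900L, 1100L, 1300L, 1501L, 2501L))
  y <- 2 - 1.5 * beta[2, ] + rnorm(n_donor, 0, 0.3)
  raw <- expr_fixture(matrix(2^pmax(y, 0) - 1, 1), starts = 1000L)
  colnames(raw$value) <- sample_ids(m)
  expr <- filter_expression(raw)
  hits <- cis_scan(m, expr, window = 1000, p_threshold = 1)
  # window rule: the feature spans [1000, 1500]; site 2501 is 1001 bp past
  # the end and is excluded; site 900 (100 bp upstream) is included
  expect_setequal(hits$pos, c(900L, 1100L, 1300L, 1501L))
  yy <- unclass(expr)$value[1, ]
  for (i in seq_len(nrow(hits))) {
    x <- beta_values(m)[match(hits$pos[i], m$pos), ]
    r <- cor(x, yy)
    t_closed <- r * sqrt((n_donor - 2) / (1 - r^2))
    expect_equal(hits$t[i], t_closed, tolerance = 1e-8)
    fit <- summary(lm(yy ~ x))
    expect_equal(hits$slope[i], fit$coefficients["x", "Estimate"],
                 tolerance = 1e-8)
    expect_equal(hits$p[i], fit$coefficients["x", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
})

test_that("cis scan t and p are invariant to affine rescaling of expression", {
  set.seed(15)
  beta <- matrix(runif(3 * 10, 0.2, 0.8), 3)
  m <- beta_matrix_fixture(beta, coverage = 1e6L,
                           pos = c(1100L, 1200L, 1300L))
  y <- rnorm(10, 5, 1)
  mk <- function(vals) {
    raw <- expr_fixture(matrix(vals, 1), types = "PSI", denominator = 25L)
    colnames(raw$value) <- sample_ids(m)
    filter_expression(raw)
  }
  h1 <- cis_scan(m, mk(y / 10), window = 1000, p_threshold = 1)
  h2 <- cis_scan(m, mk(y / 10 * 3 - 0.5), window = 1000, p_threshold = 1)
  expect_equal(h1$t, h2$t, tolerance = 1e-10)
  expect_equal(h1$p, h2$p, tolerance = 1e-10)
  expect_equal(h2$slope, 3 * h1$slope, tolerance = 1e-10)
})

test_that("association filters drop extreme and non-coding records", {
  rec <- tibble::tibble(
    n_nonzero = c(10L, 11L, 22L, 22L),
    n_nonone = c(22L, 22L, 10L, 22L),
    t = c(3, 3, 3, Inf),
    coding = TRUE
  )
  expect_equal(nrow(filter_associations(rec)), 1L)
  rec2 <- rec[2, ]; rec2$coding <- FALSE
  expect_equal(nrow(filter_associations(rec2)), 0L)
  expect_equal(nrow(filter_associations(rec2, require_coding = FALSE)), 1L)
  # brute force on a random set
  set.seed(16)
  rec3 <- tibble::tibble(
    n_nonzero = sample(5:22, 50, TRUE), n_nonone = sample(5:22, 50, TRUE),
    t = rnorm(50), coding = sample(c(TRUE, FALSE), 50, TRUE)
  )
  brute <- rec3[rec3$n_nonzero >= 11 & rec3$n_nonone >= 11 &
                  is.finite(rec3$t) & rec3$coding, ]
  expect_equal(filter_associations(rec3), brute)
})

test_that("marginal rescue classifies features by nearby CpG support", {
  set.seed(17)
  n_donor <- 20
  u <- runif(n_donor, -0.2, 0.2)
  # CpH at 5000 with a supporting CpG at 5400 (shared surface);
  # CpH at 50000 with no CpG within 1 kb
  cph_beta <- rbind(0.5 + u, 0.5 + runif(n_donor, -0.2, 0.2))
  cph <- beta_matrix_fixture(pmin(pmax(cph_beta, 0), 1), coverage = 1e5L,
                             pos = c(5000L, 50000L), trinucleotide = "CAC")
  cpg <- beta_matrix_fixture(
    matrix(pmin(pmax(0.5 + u + rnorm(n_donor, 0, 0.02), 0), 1), 1),
    coverage = 1e5L, pos = 6000L, trinucleotide = "CGA"
  )
  y1 <- 3 - 2 * (0.5 + u) + rnorm(n_donor, 0, 0.1)
  y2 <- 3 - 2 * cph_beta[2, ] + rnorm(n_donor, 0, 0.1)
  raw <- expr_fixture(rbind(2^y1 - 1, 2^y2 - 1),
                      starts = c(4800L, 49800L))
  colnames(raw$value) <- sample_ids(cph)
  expr <- filter_expression(raw)
  cph_hits <- cis_scan(cph, expr, window = 1000, p_threshold = 0.05)
  cph_hits$q <- cph_hits$p  # tiny example: treat p as already adjusted
  out <- marginal_cpg_rescue(cph_hits, cpg, expr, window = 1000,
                             p_marginal = 0.01)
  cls <- out$feature_classes
  expect_equal(cls$classification[cls$feature_id == "f001"], "shared")
  expect_equal(cls$classification[cls$feature_id == "f002"],
               "CpH-exclusive")
  expect_true(all(out$marginal$marginal))
  # CpG at exactly 1 kb from the CpH is inside the closed window
  expect_true(all(abs(out$marginal$pos - 5000) <= 1000))
})

test_that("age adjustment flags associations explained by age", {
  set.seed(18)
  n_donor <- 22
  meta <- sample_meta(sprintf("d%02d", 1:n_donor), rep("neuron", n_donor),
                      age = seq(0, 21, length.out = n_donor))
  # site 1: beta tracks age exactly; expression driven by age
  # site 2: beta independent of age; expression driven by beta
  b1 <- 0.3 + 0.02 * meta$age
  b2 <- runif(n_donor, 0.2, 0.8)
  m <- beta_matrix_fixture(rbind(b1, b2), coverage = 1e6L,
                           pos = c(1100L, 1200L))
  colnames(m$meth) <- colnames(m$total) <- meta$sample_id
  m$meth <- unclass(m)$meth; m$total <- unclass(m)$total
  y1 <- 1 + 0.2 * meta$age + rnorm(n_donor, 0, 0.05)
  y2 <- 4 - 2 * b2 + rnorm(n_donor, 0, 0.1)
  raw <- expr_fixture(rbind(2^y1 - 1, 2^y2 - 1), starts = c(1000L, 1000L))
  colnames(raw$value) <- meta$sample_id
  expr <- filter_expression(raw)
  hits <- cis_scan(m, expr, window = 1000, p_threshold = 0.01)
  hits <- hits[(hits$feature_id == "f001" & hits$pos == 1100) |
                 (hits$feature_id == "f002" & hits$pos == 1200), ]
  expect_warning(out <- age_confound_check(hits, m, expr, meta),
                 "collinear")
  expect_true(out$age_confounded[out$feature_id == "f001"])
  expect_false(out$age_confounded[out$feature_id == "f002"])
})

test_that("group-mean correlation recovers constructed monotone coupling", {
  set.seed(19)
  n_donor <- 18
  meta <- sample_meta(sprintf("d%02d", 1:n_donor),
                      rep(c("neuron", "glia"), each = 9),
                      age = rep(c(0.5, 5, 14), 6))
  n_feat <- 30
  meth_level <- runif(n_feat, 0.1, 0.9)
  beta <- matrix(rep(meth_level, n_donor), n_feat) +
    matrix(rnorm(n_feat * n_donor, 0, 0.02), n_feat)
  m <- beta_matrix_fixture(pmin(pmax(beta, 0), 1), coverage = 1e5L,
                           pos = seq(1200L, by = 5000L,
                                     length.out = n_feat))
  colnames(m$meth) <- colnames(m$total) <- meta$sample_id
  vals <- 2^(6 - 4 * beta) - 1  # expression = -methylation on log scale
  raw <- expr_fixture(vals, starts = seq(1000L, by = 5000L,
                                         length.out = n_feat))
  colnames(raw$value) <- meta$sample_id
  expr <- filter_expression(raw)
  g <- group_mean_correlation(m, expr, meta, window = "gene_body")
  expect_true(all(g$rho < -0.95))
})

test_that("the association summary equals brute-force aggregation", {
  set.seed(20)
  rec <- tibble::tibble(
    chrom = "c", pos = sample.int(1e5, 40),
    context = sample(c("CpG", "CHG", "CHH"), 40, TRUE),
    trinucleotide = "CAC",
    feature_id = sample(sprintf("f%02d", 1:10), 40, TRUE),
    feature_type = sample(c("gene", "exon", "PSI"), 40, TRUE),
    slope = rnorm(40),
    n_nonzero = sample(11:22, 40, TRUE),
    n_nonone = sample(11:22, 40, TRUE),
    delta_expr = rnorm(40),
    annotation = sample(c("promoter", "gene body", "flanking"), 40, TRUE),
    age_confounded = sample(c(TRUE, FALSE), 40, TRUE),
    de_status = sample(c("neuron", "glia", "none"), 40, TRUE)
  )
  s <- summarize_associations(rec)
  one <- s[s$feature_type == s$feature_type[1] &
             s$context_class == s$context_class[1] &
             s$direction == s$direction[1], ]
  sub <- rec[rec$feature_type == one$feature_type &
               ifelse(rec$context == "CpG", "CpG", "CpH") ==
                 one$context_class &
               ifelse(rec$slope < 0, "Down", "Up") == one$direction, ]
  expect_equal(one$n, nrow(sub))
  expect_equal(one$mean_n_nonzero, mean(sub$n_nonzero))
  expect_equal(one$prop_promoter, mean(sub$annotation == "promoter"))
  expect_equal(one$prop_de_glia, mean(sub$de_status == "glia"))
  # annotation proportions partition to one
  expect_equal(s$prop_promoter + s$prop_gene_body + s$prop_flanking,
               rep(1, nrow(s)))
})
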