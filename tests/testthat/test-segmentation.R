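test_that("DMV rules are inclusive at both boundaries", {
  umrs <- tibble::tibble(
    sample_id = "s", chrom = "c",
    start = c(0, 10000, 20000, 30000),
    end = c(5000, 20000, 24999, 40000),
    width = c(5000, 10000, 4999, 10000),
    n_cpg = 40L,
    pmeth = c(0.15, 0.16, 0.05, 0.10),
    kind = "UMR"
  )
  dmv <- call_dmvs(umrs)
  # pmeth 0.15 & width 5000 qualifies; 0.16 and 4999 do not
  expect_equal(dmv$start, c(0, 30000))
  expect_true(all(dmv$kind == "DMV"))
})

test_that("hypomethylated segments respect the minimum run length and split rule", {
  # 3 sub-cutoff sites -> nothing; 30 -> UMR; 10 -> LMR
  beta <- c(rep(0.9, 20), rep(0.02, 3), rep(0.9, 20), rep(0.02, 30),
            rep(0.9, 20), rep(0.02, 10), rep(0.9, 20))
  m <- beta_matrix_fixture(matrix(beta, ncol = 1), coverage = 1000L)
  m$smoothed <- matrix(beta, ncol = 1,
                       dimnames = list(NULL, sample_ids(m)))
  seg <- call_umrs_lmrs(m, "s01", cutoff = 0.5)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$kind[seg$n_cpg == 30], "UMR")
  expect_equal(seg$kind[seg$n_cpg == 10], "LMR")
  expect_equal(seg$width, seg$end - seg$start)
})

test_that("fully methylated chromosomes give no PMDs; length filter applies", {
  set.seed(2)
  n <- 600
  beta <- matrix(rbinom(n, 40, 0.9) / 40, ncol = 1)
  m <- beta_matrix_fixture(beta, coverage = 40L,
                           pos = sort(sample.int(3e5, n)))
  expect_equal(nrow(call_pmds(m, "s01")), 0L)

  # disordered middle block of ~80 kb is removed by the > 100 kb rule,
  # a ~200 kb block survives
  mk <- function(len_bp) {
    pos_bg1 <- sort(sample.int(2e5, 400))
    pos_dis <- sort(sample(2e5 + seq_len(len_bp), round(len_bp / 500)))
    pos_bg2 <- sort(2e5 + len_bp + sample.int(2e5, 400))
    pos <- c(pos_bg1, pos_dis, pos_bg2)
    truth <- c(rep(0.95, 400), runif(length(pos_dis), 0.3, 0.7),
               rep(0.95, 400))
    total <- matrix(40L, length(pos), 1, dimnames = list(NULL, "s1"))
    meth <- matrix(rbinom(length(pos), 40, truth), ncol = 1,
                   dimnames = dimnames(total))
    cytosine_matrix(tibble::tibble(chrom = "c", pos = pos, strand = "+",
                                   trinucleotide = "CGA"), meth, total)
  }
  short <- call_pmds(mk(8e4), "s1")
  expect_equal(nrow(short), 0L)
  long <- call_pmds(mk(2e5), "s1")
  expect_equal(nrow(long), 1L)
  expect_gt(long$width, 1e5)
})

test_that("assembly gaps are subtracted except heterochromatin labels", {
  set.seed(4)
  pos <- sort(sample.int(4e5, 900))
  truth <- runif(length(pos), 0.3, 0.7)
  total <- matrix(40L, length(pos), 1, dimnames = list(NULL, "s1"))
  meth <- matrix(rbinom(length(pos), 40, truth), ncol = 1,
                 dimnames = dimnames(total))
  m <- cytosine_matrix(tibble::tibble(chrom = "c", pos = pos, strand = "+",
                                      trinucleotide = "CGA"), meth, total)
  gaps_het <- tibble::tibble(chrom = "c", start = 1e5, end = 1.5e5,
                             label = "heterochromatin")
  gaps_tel <- tibble::tibble(chrom = "c", start = 1e5, end = 1.5e5,
                             label = "telomere")
  with_het <- call_pmds(m, "s1", gaps = gaps_het)
  with_tel <- call_pmds(m, "s1", gaps = gaps_tel)
  expect_gt(sum(with_het$width), sum(with_tel$width))
})

test_that("cutoff calibration is deterministic and errors without structure", {
  sim <- simulate_methylome(
    sim_config(seed = 55, genome_length = 1e6,
               features = sim_features(n_celltype_dmr = 0L,
                                       n_interaction_dmr = 0L,
                                       pmd_lengths = numeric(0)))
  )
  m <- filter_by_coverage(dplyr::filter(sim$matrix, context == "CpG"), 3,
                          quiet = TRUE)
  sm <- smooth_betas(m, min_sites = 10, min_width = 1000)
  cal1 <- calibrate_cutoff(sm, "neuron_01", shuffle_seed = 3)
  cal2 <- calibrate_cutoff(sm, "neuron_01", shuffle_seed = 3)
  expect_identical(cal1$cutoff, cal2$cutoff)
  expect_true(all(cal1$fdr_table$fdr[cal1$fdr_table$cutoff == cal1$cutoff]
                  <= 10))

  # flat hypermethylated track: no hypomethylated structure at any cutoff
  flat <- beta_matrix_fixture(matrix(0.95, 300, 1), coverage = 1000L)
  flat$smoothed <- matrix(0.95, 300, 1,
                          dimnames = list(NULL, sample_ids(flat)))
  expect_error(calibrate_cutoff(flat, "s01"), "no cutoff")
})

test_that("planted methylome features are recovered with high base-level overlap", {
  cfg <- sim_config(seed = 11,
                    features = sim_features(n_celltype_dmr = 0L,
                                            n_interaction_dmr = 0L))
  sim <- simulate_methylome(cfg)
  m <- filter_by_coverage(dplyr::filter(sim$matrix, context == "CpG"), 3,
                          quiet = TRUE)
  sm <- smooth_betas(m, min_sites = 10, min_width = 1000)
  seg <- suppressWarnings(segment_methylome(sm, "neuron_01",
                                            gaps = sim$truth$gaps))
  tf <- sim$truth$features
  jac <- function(kind_called, kind_truth) {
    region_jaccard(seg[seg$kind %in% kind_called, ],
                   tf[tf$kind %in% kind_truth, ])
  }
  expect_gt(jac(c("UMR", "DMV"), c("UMR", "DMV")), 0.85)
  expect_gt(jac("PMD", "PMD"), 0.85)
  expect_gt(jac("DMV", "DMV"), 0.85)
  expect_gt(jac("LMR", "LMR"), 0.7)
  # structural invariants: DMVs are UMRs; UMR and LMR site sets disjoint
  expect_true(all(seg$kind[seg$kind == "DMV"] == "DMV"))
  umr <- seg[seg$kind == "UMR", ]; lmr <- seg[seg$kind == "LMR", ]
  if (nrow(umr) > 0 && nrow(lmr) > 0) {
    expect_equal(sum(IRanges::width(IRanges::intersect(
      IRanges::IRanges(umr$start + 1, umr$end),
      IRanges::IRanges(lmr$start + 1, lmr$end)
    ))), 0)
  }
})

test_that("lowering the cutoff never increases hypomethylated bases", {
  set.seed(8)
  beta <- matrix(runif(400, 0, 1), ncol = 1)
  m <- beta_matrix_fixture(beta, coverage = 1000L)
  m$smoothed <- matrix(beta, ncol = 1, dimnames = list(NULL, sample_ids(m)))
  widths <- vapply(c(0.6, 0.4, 0.2), function(cc) {
    seg <- call_umrs_lmrs(m, "s01", cutoff = cc)
    sum(seg$n_cpg)
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})
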