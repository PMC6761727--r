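#' Simulate expression tables tied to planted methylation-association sites
#'
#' Builds gene-level FPKM, exon-level FPKM and splice-event PSI tables for
#' the neuronal donors of a simulated methylome. Every planted association
#' site in the methylome truth gets one expression feature whose span lies
#' within the cis window of the cytosine; the feature's value responds
#' linearly to the donor's methylation level at that cytosine, with Gaussian
#' noise scaled so the realized coefficient of determination matches
#' `target_r2` in expectation. Null features are independent of methylation,
#' a block of lowly expressed features exercises the expression filters, and
#' PSI values are clamped to \[0, 1\].
#'
#' @param sim A `sim_methylome` from [simulate_methylome()].
#' @param target_r2 Planted variance explained (observed methylation vs
#'   transformed expression).
#' @param slope Effect on the log2(FPKM + 1) scale per unit beta (genes,
#'   exons); `psi_slope` is the PSI analogue.
#' @param psi_slope PSI change per unit beta.
#' @param n_null_gene,n_null_exon,n_null_psi Null feature counts.
#' @param n_low Features below the expression filters.
#' @param seed Seed for the expression noise (defaults to the methylome
#'   seed + 1).
#' @return A list of class `sim_expression`: `expression` (tibble with
#'   feature columns and a `value` matrix-column over donors; PSI features
#'   carry `denominator`), `truth` (planted feature-cytosine links), and
#'   `donors` (the neuronal sample ids).
#' @export
simulate_expression <- function(sim, target_r2 = 0.5, slope = -2,
                                psi_slope = -0.5,
                                n_null_gene = 30L, n_null_exon = 30L,
                                n_null_psi = 20L, n_low = 10L,
                                seed = NULL) {
  stopifnot(inherits(sim, "sim_methylome"))
  set.seed(seed %||% (sim$config$seed + 1L))
  meta <- sim$meta
  donors <- meta$sample_id[meta$cell_fraction == "neuron"]
  if (length(donors) < 3) stop("need at least 3 neuronal donors")
  mat <- sim$matrix
  b_obs <- beta_values(mat)[, donors, drop = FALSE]
  chrom <- mat$chrom[1L]

  assoc <- sim$truth$assoc_sites
  # one feature per planted site / shared pair
  planted <- assoc[assoc$kind != "cpg_partner", ]
  types <- rep(c("gene", "exon", "PSI"), length.out = nrow(planted))
  ages <- meta$age[match(donors, meta$sample_id)]

  feature_rows <- list()
  value_rows <- list()
  truth_rows <- list()
  denom_rows <- numeric(0)

  make_value <- function(x, type, kind) {
    # expression responds to the donor's observed methylation level; noise
    # SD chosen from the realized spread so E[R^2] = target_r2
    if (kind == "cpg_age") {
      # driven by age, not methylation: exercises the confounding check
      y <- 3 + 0.08 * ages + stats::rnorm(length(ages), 0, 0.2)
      return(if (type == "PSI") clamp01(y / 6) else pmax(2^y - 1, 0))
    }
    s <- if (type == "PSI") psi_slope else slope
    sd_sig <- abs(s) * stats::sd(x)
    noise <- stats::rnorm(length(x), 0, sd_sig * sqrt((1 - target_r2) / target_r2))
    if (type == "PSI") {
      clamp01(0.75 + s * x + noise)
    } else {
      pmax(2^(4 + s * x + noise) - 1, 0)
    }
  }

  for (i in seq_len(nrow(planted))) {
    type <- types[i]
    pos <- planted$pos[i]
    id <- paste0(type, "_", planted$pair_id[i])
    feature_rows[[length(feature_rows) + 1L]] <- tibble::tibble(
      feature_id = id, feature_type = type, chrom = chrom,
      start = pos + 150L, end = pos + 650L, strand = "+",
      gene_id = paste0("g_", id), coding = TRUE
    )
    x <- b_obs[match(pos, mat$pos), ]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    value_rows[[length(value_rows) + 1L]] <-
      make_value(x, type, planted$kind[i])
    denom_rows <- c(denom_rows, if (type == "PSI") 25L else NA_integer_)
    truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
      feature_id = id, feature_type = type, pos = pos,
      context = planted$context[i], kind = planted$kind[i],
      pair_id = planted$pair_id[i], target_r2 = target_r2
    )
  }

  # null and low-expressed features scattered over the genome
  null_spec <- tibble::tibble(
    feature_type = c(rep("gene", n_null_gene), rep("exon", n_null_exon),
                     rep("PSI", n_null_psi), rep("gene", n_low)),
    low = c(rep(FALSE, n_null_gene + n_null_exon + n_null_psi),
            rep(TRUE, n_low))
  )
  G <- max(mat$pos)
  starts <- sort(sample.int(G - 2000L, nrow(null_spec)))
  for (i in seq_len(nrow(null_spec))) {
    type <- null_spec$feature_type[i]
    id <- sprintf("%s_null_%03d", type, i)
    feature_rows[[length(feature_rows) + 1L]] <- tibble::tibble(
      feature_id = id, feature_type = type, chrom = chrom,
      start = starts[i], end = starts[i] + 1500L, strand = "+",
      gene_id = paste0("g_", id), coding = i %% 7L != 0L
    )
    value_rows[[length(value_rows) + 1L]] <- if (type == "PSI") {
      clamp01(stats::rnorm(length(donors), 0.6, 0.15))
    } else if (null_spec$low[i]) {
      stats::runif(length(donors), 0, 0.2)
    } else {
      pmax(2^stats::rnorm(length(donors), 3, 0.6) - 1, 0)
    }
    denom_rows <- c(denom_rows,
                    if (type == "PSI") sample(c(5L, 25L), 1L, prob = c(0.2, 0.8))
                    else NA_integer_)
  }

  expr <- dplyr::bind_rows(feature_rows)
  value <- do.call(rbind, value_rows)
  colnames(value) <- donors
  expr$value <- value
  expr$denominator <- denom_rows
  structure(
    list(expression = expr, truth = dplyr::bind_rows(truth_rows),
         donors = donors),
    class = "sim_expression"
  )
}

#' Simulate annotation tracks for a synthetic genome
#'
#' Produces a 15-state chromatin-state tiling of the genome (tiles covering
#' planted UMRs are biased to the active-TSS state so enrichment recovery is
#' scorable), non-overlapping gene models, a few gene sets, and the
#' assembly-gap track from the methylome truth.
#'
#' @param config A [sim_config()].
#' @param truth Optional truth component of a `sim_methylome` (enables the
#'   UMR state bias and the gap track).
#' @param umr_state_bias Probability that a tile inside a planted UMR gets
#'   the `1_TssA` state.
#' @param seed Seed (defaults to `config$seed + 2`).
#' @return A list with `states`, `genes`, `gene_sets`, `gaps` tibbles
#'   (0-based half-open coordinates).
#' @export
simulate_annotation <- function(config, truth = NULL, umr_state_bias = 0.8,
                                seed = NULL) {
  set.seed(seed %||% (config$seed + 2L))
  G <- config$genome_length
  state_names <- c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk",
                   "6_EnhG", "7_Enh", "8_ZNF/Rpts", "9_Het", "10_TssBiv",
                   "11_BivFlnk", "12_EnhBiv", "13_ReprPC", "14_ReprPCWk",
                   "15_Quies")
  state_prob <- c(2, 2, 1, 6, 8, 2, 4, 2, 6, 1, 1, 2, 4, 8, 24)
  lens <- numeric(0)
  while (sum(lens) < G) {
    lens <- c(lens, pmax(200, round(stats::rexp(200, 1 / 2000))))
  }
  ends <- pmin(cumsum(lens), G)
  ends <- ends[!duplicated(ends)]
  starts <- c(0, utils::head(ends, -1L))
  states <- tibble::tibble(
    chrom = config$chrom, start = starts, end = ends,
    state = sample(state_names, length(starts), replace = TRUE,
                   prob = state_prob)
  )
  if (!is.null(truth)) {
    umrs <- truth$features[truth$features$kind %in% c("UMR", "DMV"), ]
    mid <- (states$start + states$end) / 2
    inside <- !is.na(overlap_index(mid, umrs))
    flip <- inside & stats::runif(nrow(states)) < umr_state_bias
    states$state[flip] <- "1_TssA"
  }

  n_gene <- max(10L, floor(G / 15000))
  gstart <- sort(sample.int(G - 12000L, n_gene))
  glen <- round(stats::runif(n_gene, 2000, 10000))
  gend <- pmin(gstart + glen, G)
  keep <- c(TRUE, gstart[-1L] >= utils::head(gend, -1L))
  genes <- tibble::tibble(
    gene_id = sprintf("gene_%03d", seq_len(sum(keep))),
    chrom = config$chrom,
    start = gstart[keep], end = gend[keep],
    strand = sample(c("+", "-"), sum(keep), replace = TRUE),
    coding = stats::runif(sum(keep)) < 0.85
  )

  gene_sets <- list(
    set_A = sample(genes$gene_id, max(3L, floor(nrow(genes) / 8))),
    set_B = sample(genes$gene_id, max(3L, floor(nrow(genes) / 5))),
    set_C = sample(genes$gene_id, max(3L, floor(nrow(genes) / 10)))
  )

  gaps <- if (!is.null(truth) && nrow(truth$gaps) > 0) {
    truth$gaps[, c("start", "end", "label")]
  } else {
    tibble::tibble(start = numeric(0), end = numeric(0),
                   label = character(0))
  }
  if (nrow(gaps) > 0) gaps$chrom <- config$chrom

  list(states = states, genes = genes, gene_sets = gene_sets, gaps = gaps)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits one per-cytosine report per sample, a metadata TSV, the truth
#' ledger as JSON, and (if supplied) expression TSVs and annotation BED
#' files under `dir`.
#'
#' @param sim A `sim_methylome`.
#' @param dir Output directory (created if needed).
#' @param expression Optional `sim_expression`.
#' @param annotation Optional annotation list from [simulate_annotation()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, expression = NULL, annotation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sample_ids(sim$matrix)) {
    write_cytosine_report(sim$matrix, s,
                          file.path(dir, paste0(s, ".cx_report.txt")))
  }
  readr::write_tsv(sim$meta, file.path(dir, "sample_meta.tsv"),
                   progress = FALSE)
  truth <- sim$truth
  truth$beta_true <- NULL # large; reproducible from config + seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(expression)) {
    e <- expression$expression
    v <- tibble::as_tibble(unclass(e)$value)
    readr::write_tsv(dplyr::bind_cols(e[, setdiff(names(e), "value")], v),
                     file.path(dir, "expression.tsv"), progress = FALSE)
  }
  if (!is.null(annotation)) {
    readr::write_tsv(annotation$states, file.path(dir, "chrom_states.bed"),
                     col_names = FALSE, progress = FALSE)
    readr::write_tsv(annotation$genes, file.path(dir, "genes.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}
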