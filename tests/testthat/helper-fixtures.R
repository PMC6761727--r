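# Small in-memory fixtures shared across tests.

# cytosine matrix from explicit beta values at fixed coverage
beta_matrix_fixture <- function(beta, coverage = 100L, pos = NULL,
                                chrom = "chrT", trinucleotide = "CGA") {
  beta <- as.matrix(beta)
  if (is.null(colnames(beta))) {
    colnames(beta) <- sprintf("s%02d", seq_len(ncol(beta)))
  }
  if (is.null(pos)) pos <- seq_len(nrow(beta)) * 10L
  total <- matrix(coverage, nrow(beta), ncol(beta),
                  dimnames = dimnames(beta))
  meth <- round(beta * total)
  cytosine_matrix(
    tibble::tibble(chrom = chrom, pos = pos, strand = "+",
                   trinucleotide = trinucleotide),
    meth, total
  )
}

balanced_meta <- function(n_per_group = 12L, age_max = 23) {
  sample_meta(
    sample_id = c(sprintf("n%02d", seq_len(n_per_group)),
                  sprintf("g%02d", seq_len(n_per_group))),
    cell_fraction = rep(c("neuron", "glia"), each = n_per_group),
    age = rep(seq(0, age_max, length.out = n_per_group), 2)
  )
}

# adjusted Rand index, direct from the pair-counting definition
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

overlaps_any <- function(regions, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    any(regions$end > truth$start[i] & regions$start < truth$end[i])
  }, logical(1))
}
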