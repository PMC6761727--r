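#' Call partially methylated domains for one sample
#'
#' Slides a 101-CpG window along each chromosome, computes the fraction of
#' sites with intermediate raw beta (`beta_low` < beta < `beta_high`) — the
#' disorder statistic of PMDs — and decodes a two-state (ordered vs
#' disordered) hidden-state model over the window series by Viterbi.
#' Contiguous disordered stretches become candidate PMDs; candidates not
#' longer than `min_length` bp are dropped, and assembly-gap intervals are
#' subtracted except for gaps labelled `"heterochromatin"`.
#'
#' @param x A coverage-filtered cytosine matrix (CpG).
#' @param sample Sample to segment.
#' @param window_sites Sliding window size in CpGs.
#' @param beta_low,beta_high Bounds of the intermediate-methylation band.
#' @param emission_means Expected disorder fraction in the ordered and
#'   disordered states.
#' @param emission_sd Gaussian emission SD of the window statistic.
#' @param transition Per-site probability of switching state.
#' @param min_length Candidates must be strictly longer than this (bp).
#' @param gaps Optional gap track (`chrom`, `start`, `end`, `label`,
#'   0-based half-open).
#' @return A tibble of PMD regions (`sample_id`, `chrom`, `start`, `end`,
#'   `width`, `n_cpg`, `pmeth`, `kind = "PMD"`), 0-based half-open.
#' @export
call_pmds <- function(x, sample, window_sites = 101,
                      beta_low = 0.3, beta_high = 0.7,
                      emission_means = c(0.08, 0.5), emission_sd = 0.1,
                      transition = 1e-4, min_length = 1e5, gaps = NULL) {
  b <- beta_values(x)[, sample]
  out <- list()
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    if (length(idx) < window_sites) {
      warning("chromosome '", ch, "' has fewer than ", window_sites,
              " CpGs; no PMDs called")
      next
    }
    bi <- b[idx]
    d <- as.numeric(!is.na(bi) & bi > beta_low & bi < beta_high)
    frac <- stats::filter(d, rep(1 / window_sites, window_sites),
                          sides = 2)
    frac <- as.numeric(frac)
    # extend the half-windows at the ends with their nearest full window
    first <- which(!is.na(frac))[1L]
    last <- max(which(!is.na(frac)))
    frac[seq_len(first - 1L)] <- frac[first]
    frac[seq(last + 1L, length.out = length(frac) - last)] <- frac[last]

    state <- viterbi_two_state(frac, emission_means, emission_sd, transition)
    r <- rle(state == 2L)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    hits <- which(r$values)
    if (length(hits) == 0) next
    reg <- tibble::tibble(
      chrom = ch,
      start = x$pos[idx[starts_i[hits]]] - 1,
      end = as.numeric(x$pos[idx[ends_i[hits]]])
    )
    reg$width <- reg$end - reg$start
    reg <- reg[reg$width > min_length, , drop = FALSE]
    if (nrow(reg) == 0) next
    if (!is.null(gaps) && nrow(gaps) > 0) {
      excl <- gaps[gaps$label != "heterochromatin", , drop = FALSE]
      if ("chrom" %in% names(excl)) {
        excl <- excl[excl$chrom == ch, , drop = FALSE]
      }
      if (nrow(excl) > 0) {
        kept <- IRanges::setdiff(
          IRanges::IRanges(reg$start + 1, reg$end),
          IRanges::IRanges(excl$start + 1, excl$end)
        )
        reg <- tibble::tibble(chrom = ch,
                              start = IRanges::start(kept) - 1,
                              end = as.numeric(IRanges::end(kept)))
        reg$width <- reg$end - reg$start
        reg <- reg[reg$width > min_length, , drop = FALSE]
      }
    }
    if (nrow(reg) == 0) next
    reg$n_cpg <- purrr::map_int(seq_len(nrow(reg)), function(i) {
      sum(x$pos[idx] > reg$start[i] & x$pos[idx] <= reg$end[i])
    })
    reg$pmeth <- purrr::map_dbl(seq_len(nrow(reg)), function(i) {
      mean(bi[x$pos[idx] > reg$start[i] & x$pos[idx] <= reg$end[i]],
           na.rm = TRUE)
    })
    out[[ch]] <- reg
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), width = numeric(0),
                          n_cpg = integer(0), pmeth = numeric(0))
  }
  res$kind <- rep("PMD", nrow(res))
  res$sample_id <- rep(sample, nrow(res))
  res[, c("sample_id", "chrom", "start", "end", "width", "n_cpg",
          "pmeth", "kind")]
}

# Viterbi decoding of a 2-state Gaussian-emission chain.
viterbi_two_state <- function(obs, means, sd, transition) {
  n <- length(obs)
  logp <- cbind(stats::dnorm(obs, means[1L], sd, log = TRUE),
                stats::dnorm(obs, means[2L], sd, log = TRUE))
  stay <- log(1 - transition)
  move <- log(transition)
  v <- matrix(-Inf, n, 2L)
  back <- matrix(1L, n, 2L)
  v[1L, ] <- log(0.5) + logp[1L, ]
  for (t in 2:n) {
    for (s in 1:2) {
      from1 <- v[t - 1L, 1L] + (if (s == 1L) stay else move)
      from2 <- v[t - 1L, 2L] + (if (s == 2L) stay else move)
      if (from1 >= from2) {
        v[t, s] <- from1 + logp[t, s]
        back[t, s] <- 1L
      } else {
        v[t, s] <- from2 + logp[t, s]
        back[t, s] <- 2L
      }
    }
  }
  state <- integer(n)
  state[n] <- which.max(v[n, ])
  for (t in seq(n - 1L, 1L)) state[t] <- back[t + 1L, state[t + 1L]]
  state
}

#' Calibrate the hypomethylation cutoff for UMR/LMR segmentation
#'
#' For a grid of methylation cutoffs (up to the maximum segment methylation
#' `m`), counts hypomethylated segments (runs of at least
#' `min_segment_sites` consecutive CpGs below the cutoff) in the observed
#' smoothed track and in a methylation-shuffled track, and computes
#' FDR(cutoff) = 100 * null / observed. Returns the least stringent
#' (largest) cutoff whose FDR is at or below `fdr_target`.
#'
#' @param x A smoothed cytosine matrix ([smooth_betas()]).
#' @param sample Sample to calibrate.
#' @param m Maximum methylation a hypomethylated segment may have; caps the
#'   cutoff grid.
#' @param fdr_target FDR ceiling in percent.
#' @param pmd_mask Optional PMD regions to mask out (tibble with `chrom`,
#'   `start`, `end`).
#' @param cutoffs Cutoff grid.
#' @param min_segment_sites Minimum CpGs per segment.
#' @param n_shuffles Number of methylation shuffles averaged into the null
#'   segment count (a single shuffle makes the null/observed ratio too
#'   noisy to rank cutoffs reliably).
#' @param shuffle_seed Seed of the methylation shuffles.
#' @param mask_pad Padding (bp) added around masked regions.
#' @return A list with `cutoff` (selected value) and `fdr_table` (tibble of
#'   cutoff, observed and mean null segment counts, fdr).
#' @export
calibrate_cutoff <- function(x, sample, m = 0.5, fdr_target = 10,
                             pmd_mask = NULL,
                             cutoffs = seq(0.02, 0.6, by = 0.02),
                             min_segment_sites = 4, n_shuffles = 10L,
                             shuffle_seed = 1L, mask_pad = 0) {
  sm <- smoothed_values(x)[, sample]
  masked <- masked_sites(x, pmd_mask, mask_pad)
  usable <- sm[!masked]
  usable <- usable[!is.na(usable)]
  set.seed(shuffle_seed)
  cutoffs <- cutoffs[cutoffs <= m]
  count_segments <- function(vals, cutoff) {
    r <- rle(!is.na(vals) & vals < cutoff)
    sum(r$values & r$lengths >= min_segment_sites)
  }
  null_counts <- matrix(0, n_shuffles, length(cutoffs))
  for (b in seq_len(n_shuffles)) {
    null_vals <- sample(usable)
    null_counts[b, ] <- vapply(cutoffs,
                               function(cc) count_segments(null_vals, cc),
                               integer(1))
  }
  tab <- tibble::tibble(
    cutoff = cutoffs,
    observed = vapply(cutoffs, function(cc) count_segments(usable, cc),
                      integer(1)),
    null = colMeans(null_counts)
  )
  tab$fdr <- ifelse(tab$observed > 0, 100 * tab$null / tab$observed, Inf)
  ok <- which(tab$fdr <= fdr_target)
  if (length(ok) == 0) {
    stop("no cutoff reaches FDR <= ", fdr_target,
         "%; consider changing `m`, the grid, or the FDR target")
  }
  list(cutoff = tab$cutoff[max(ok)], fdr_table = tab)
}

masked_sites <- function(x, mask, pad = 0) {
  if (is.null(mask) || nrow(mask) == 0) return(rep(FALSE, nrow(x)))
  out <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(mask))) {
    out <- out | (x$chrom == mask$chrom[i] & x$pos > mask$start[i] - pad &
                    x$pos <= mask$end[i] + pad)
  }
  out
}

#' Call UMRs and LMRs from a smoothed track
#'
#' Maximal runs of at least `min_segment_sites` consecutive CpGs with
#' smoothed beta below the calibrated cutoff become hypomethylated
#' segments; segments with at least `umr_min_sites` CpGs are unmethylated
#' regions (UMRs), the rest low-methylated regions (LMRs). Masked (PMD)
#' sites break runs.
#'
#' @param x A smoothed cytosine matrix.
#' @param sample Sample to segment.
#' @param cutoff Methylation cutoff (see [calibrate_cutoff()]).
#' @param min_segment_sites Minimum CpGs per segment.
#' @param umr_min_sites CpG count separating UMRs from LMRs.
#' @param pmd_mask Optional PMD regions to mask.
#' @param pmeth_smoothed Use smoothed (default) or raw beta for the
#'   per-region mean methylation `pmeth`.
#' @return A tibble of regions (0-based half-open) with `kind` in
#'   `c("UMR", "LMR")`, `pmeth`, `n_cpg`, `width`.
#' @export
call_umrs_lmrs <- function(x, sample, cutoff, min_segment_sites = 4,
                           umr_min_sites = 30, pmd_mask = NULL,
                           pmeth_smoothed = TRUE, mask_pad = 0) {
  sm <- smoothed_values(x)[, sample]
  raw <- beta_values(x)[, sample]
  masked <- masked_sites(x, pmd_mask, mask_pad)
  below <- !is.na(sm) & sm < cutoff & !masked
  out <- list()
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    r <- rle(below[idx])
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    hits <- which(r$values & r$lengths >= min_segment_sites)
    if (length(hits) == 0) next
    vals <- if (pmeth_smoothed) sm else raw
    reg <- tibble::tibble(
      chrom = ch,
      start = x$pos[idx[starts_i[hits]]] - 1,
      end = as.numeric(x$pos[idx[ends_i[hits]]]),
      n_cpg = r$lengths[hits],
      pmeth = purrr::map_dbl(seq_along(hits), function(k) {
        mean(vals[idx[seq(starts_i[hits[k]], ends_i[hits[k]])]],
             na.rm = TRUE)
      })
    )
    out[[ch]] <- reg
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_cpg = integer(0),
                          pmeth = numeric(0))
  }
  res$width <- res$end - res$start
  res$kind <- ifelse(res$n_cpg >= umr_min_sites, "UMR", "LMR")
  res$sample_id <- rep(sample, nrow(res))
  res[, c("sample_id", "chrom", "start", "end", "width", "n_cpg",
          "pmeth", "kind")]
}

#' Identify DNA methylation valleys among UMRs
#'
#' DMVs are the UMRs whose mean methylation `pmeth` is at most 0.15 and
#' whose width is at least 5 kb (both boundaries inclusive).
#'
#' @param umrs A region tibble from [call_umrs_lmrs()].
#' @param max_pmeth,min_width The two DMV rules.
#' @return The qualifying regions relabelled `kind = "DMV"`.
#' @export
call_dmvs <- function(umrs, max_pmeth = 0.15, min_width = 5000) {
  dmv <- umrs[umrs$kind == "UMR" & umrs$pmeth <= max_pmeth &
                umrs$width >= min_width, , drop = FALSE]
  dmv$kind <- rep("DMV", nrow(dmv))
  dmv
}

#' Segment one sample's methylome
#'
#' Convenience pipeline: PMDs, cutoff calibration with PMDs masked,
#' UMR/LMR calling, and DMV identification, returning one region tibble.
#'
#' @param x A smoothed cytosine matrix ([smooth_betas()] on coverage-
#'   filtered CpGs).
#' @param sample Sample to segment.
#' @param gaps Optional assembly-gap track.
#' @param m,fdr_target Calibration parameters (see [calibrate_cutoff()]).
#' @param umr_min_sites,min_segment_sites Segment-size rules.
#' @param pmd_pad Padding (bp) added around called PMDs before UMR/LMR
#'   calling and calibration; defaults to the boundary uncertainty of the
#'   101-CpG PMD window at background CpG spacing.
#' @param ... Passed to [call_pmds()].
#' @return A tibble of UMR/LMR/PMD/DMV regions; attribute `calibration`
#'   records the chosen cutoff and FDR table.
#' @export
segment_methylome <- function(x, sample, gaps = NULL, m = 0.5,
                              fdr_target = 10, umr_min_sites = 30,
                              min_segment_sites = 4, pmd_pad = 25000, ...) {
  pmds <- call_pmds(x, sample, gaps = gaps, ...)
  cal <- calibrate_cutoff(x, sample, m = m, fdr_target = fdr_target,
                          pmd_mask = pmds, mask_pad = pmd_pad)
  seg <- call_umrs_lmrs(x, sample, cutoff = cal$cutoff,
                        min_segment_sites = min_segment_sites,
                        umr_min_sites = umr_min_sites, pmd_mask = pmds,
                        mask_pad = pmd_pad)
  dmvs <- call_dmvs(seg[seg$kind == "UMR", , drop = FALSE])
  out <- dplyr::bind_rows(seg, dmvs, pmds)
  attr(out, "calibration") <- cal
  out
}

#' Base-level Jaccard index between two region sets
#'
#' Overlap agreement of two interval sets on the same genome: intersection
#' over union in base pairs after merging overlapping intervals within each
#' set.
#'
#' @param a,b Region tibbles with `start`, `end` (0-based half-open).
#' @return A number in \[0, 1\] (1 when both sets are empty).
#' @export
region_jaccard <- function(a, b) {
  ra <- IRanges::reduce(IRanges::IRanges(a$start + 1, a$end))
  rb <- IRanges::reduce(IRanges::IRanges(b$start + 1, b$end))
  inter <- sum(IRanges::width(IRanges::intersect(ra, rb)))
  uni <- sum(IRanges::width(IRanges::union(ra, rb)))
  if (uni == 0) return(1)
  inter / uni
}
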