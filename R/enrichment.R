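#' Chromatin-state composition of a region set
#'
#' Base-pair proportion of each chromatin state inside the regions versus
#' the whole annotated genome, with the log2 enrichment of the two
#' proportions. Regions extending beyond the annotated span are clipped
#' with a warning.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param state_track State tiling (`chrom`, `start`, `end`, `state`)
#'   covering the genome without overlap.
#' @return A tibble per state: `observed_bp`, `observed_prop`,
#'   `background_prop`, `log2_enrichment`.
#' @export
state_composition <- function(regions, state_track) {
  gr_states <- GenomicRanges::GRanges(
    state_track$chrom,
    IRanges::IRanges(state_track$start + 1, state_track$end)
  )
  span <- GenomicRanges::reduce(gr_states)
  gr_reg <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1, regions$end)
  ))
  outside <- GenomicRanges::setdiff(gr_reg, span)
  if (sum(GenomicRanges::width(outside)) > 0) {
    warning("region bases outside the annotated span were clipped")
  }
  gr_reg <- GenomicRanges::intersect(gr_reg, span)

  states <- sort(unique(state_track$state))
  bg_total <- sum(GenomicRanges::width(gr_states))
  reg_total <- sum(GenomicRanges::width(gr_reg))
  purrr::map_dfr(states, function(st) {
    gs <- gr_states[state_track$state == st]
    bg_bp <- sum(GenomicRanges::width(gs))
    ov <- GenomicRanges::intersect(gr_reg, gs)
    obs_bp <- sum(GenomicRanges::width(ov))
    obs_p <- if (reg_total > 0) obs_bp / reg_total else NA_real_
    bg_p <- bg_bp / bg_total
    tibble::tibble(
      state = st, observed_bp = obs_bp, observed_prop = obs_p,
      background_prop = bg_p,
      log2_enrichment = log2(obs_p / bg_p)
    )
  })
}

#' Fisher enrichment of hit regions in a target track
#'
#' Classifies every background region by (overlaps target yes/no) x (is a
#' hit yes/no) and tests the 2x2 table with Fisher's exact test. Both the
#' sample odds ratio ad/bc and the conditional-MLE odds ratio are
#' reported; a zero margin triggers the Haldane-Anscombe correction for
#' the sample OR and a flag.
#'
#' @param hits Hit regions (must be a subset of `background_regions`,
#'   matched by chrom/start/end).
#' @param targets Target region track.
#' @param background_regions The universe of regions (e.g. all CpG
#'   clusters used for detection).
#' @return A one-row tibble: counts, `odds_ratio` (ad/bc),
#'   `odds_ratio_cmle`, `p`, `log2_enrichment`, `flagged`.
#' @export
region_fisher <- function(hits, targets, background_regions) {
  key <- function(d) paste(d$chrom, d$start, d$end)
  bg_key <- key(background_regions)
  if (!all(key(hits) %in% bg_key)) {
    stop("`hits` must be a subset of `background_regions`")
  }
  is_hit <- bg_key %in% key(hits)
  gr_bg <- GenomicRanges::GRanges(
    background_regions$chrom,
    IRanges::IRanges(background_regions$start + 1, background_regions$end)
  )
  gr_t <- GenomicRanges::GRanges(
    targets$chrom, IRanges::IRanges(targets$start + 1, targets$end)
  )
  overlaps <- IRanges::overlapsAny(gr_bg, gr_t)
  a <- sum(is_hit & overlaps)
  b <- sum(is_hit & !overlaps)
  cc <- sum(!is_hit & overlaps)
  d <- sum(!is_hit & !overlaps)
  fisher_2x2(a, b, cc, d)
}

fisher_2x2 <- function(a, b, cc, d) {
  tab <- matrix(c(a, cc, b, d), 2L)
  flagged <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- if (b == 0 || cc == 0) {
    if (a == 0 || d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * cc)
  }
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  ft <- stats::fisher.test(tab)
  obs_p <- if (a + b > 0) a / (a + b) else NA_real_
  bg_p <- if (a + b + cc + d > 0) (a + cc) / (a + b + cc + d) else NA_real_
  tibble::tibble(
    n_hit_overlap = a, n_hit_no = b,
    n_bg_overlap = cc, n_bg_no = d,
    observed_prop = obs_p, background_prop = bg_p,
    log2_enrichment = log2(obs_p / bg_p),
    odds_ratio = if (flagged) or_h else or,
    odds_ratio_cmle = unname(ft$estimate),
    p = ft$p.value,
    flagged = flagged
  )
}

#' Fisher enrichment of a gene set among hit genes
#'
#' Intersects the hit and target sets with the background universe, then
#' tests the 2x2 membership table as in [region_fisher()].
#'
#' @param hit_genes Genes carrying the signal (e.g. DMR-overlapping).
#' @param set_genes The annotated gene set.
#' @param background_genes The universe (e.g. all expressed genes).
#' @return A one-row tibble as in [region_fisher()].
#' @export
gene_set_fisher <- function(hit_genes, set_genes, background_genes) {
  bg <- unique(background_genes)
  hits <- intersect(unique(hit_genes), bg)
  set <- intersect(unique(set_genes), bg)
  if (length(set) == 0) {
    stop("gene set empty after intersecting with the background")
  }
  a <- length(intersect(hits, set))
  b <- length(setdiff(hits, set))
  cc <- length(setdiff(set, hits))
  d <- length(bg) - a - b - cc
  fisher_2x2(a, b, cc, d)
}

#' Adjust a family of enrichment tests
#'
#' Benjamini-Hochberg adjustment across one named batch of enrichment
#' results (one BH run per comparison family).
#'
#' @param results A tibble of stacked enrichment rows with a `p` column.
#' @return The input with a `q` column.
#' @export
adjust_enrichment <- function(results) {
  results$q <- stats::p.adjust(results$p, method = "BH")
  results
}

#' Fraction of one region set's bases covered by another
#'
#' Merges overlapping intervals within each set and returns
#' bp(merged a intersect merged b) / bp(merged a). Not symmetric unless the
#' merged totals coincide.
#'
#' @param a_regions,b_regions Region tibbles (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return A number in \[0, 1\].
#' @export
base_overlap_fraction <- function(a_regions, b_regions) {
  if (nrow(a_regions) == 0) stop("`a_regions` is empty")
  gr_a <- GenomicRanges::reduce(GenomicRanges::GRanges(
    a_regions$chrom, IRanges::IRanges(a_regions$start + 1, a_regions$end)
  ))
  gr_b <- GenomicRanges::reduce(GenomicRanges::GRanges(
    b_regions$chrom, IRanges::IRanges(b_regions$start + 1, b_regions$end)
  ))
  inter <- GenomicRanges::intersect(gr_a, gr_b)
  sum(GenomicRanges::width(inter)) / sum(GenomicRanges::width(gr_a))
}
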