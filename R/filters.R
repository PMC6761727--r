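#' Filter cytosines by coverage and methylation positivity
#'
#' Keeps sites where every sample reaches `min_cov` total reads and — when
#' `min_positive_samples > 0` — at least that many samples show beta > 0.
#' These are the standard CpG (`min_cov = 3`) and CpH
#' (`min_cov = 5`, `min_positive_samples = 5`) site filters.
#'
#' @param x A cytosine matrix.
#' @param min_cov Minimum per-sample total count required at every sample.
#' @param min_positive_samples Minimum number of samples with beta > 0
#'   (0 disables the positivity condition).
#' @param quiet Suppress the retained-count message.
#' @return The filtered cytosine matrix; attribute `n_retained` records the
#'   number of surviving sites.
#' @export
filter_by_coverage <- function(x, min_cov, min_positive_samples = 0,
                               quiet = FALSE) {
  if (nrow(x) == 0) stop("empty cytosine matrix")
  tt <- total_counts(x)
  keep <- rowSums(tt >= min_cov) == ncol(tt)
  if (min_positive_samples > 0) {
    b <- beta_values(x)
    npos <- rowSums(b > 0, na.rm = TRUE)
    keep <- keep & npos >= min_positive_samples
  }
  out <- x[keep, ]
  attr(out, "n_retained") <- sum(keep)
  if (!quiet) {
    message(sum(keep), " of ", length(keep), " sites passed the filter")
  }
  out
}

#' Cluster genomic positions by a maximum gap
#'
#' Groups consecutive positions whose gap is at most `max_gap` base pairs;
#' labels never span chromosomes. This is the grouping used both for
#' autocorrelation clusters and as the candidate-region substrate for bump
#' hunting (`max_gap = 1000`).
#'
#' @param x A data frame with `chrom` and `pos` columns (positions sorted
#'   ascending within chromosome), or a bare numeric vector of positions on
#'   one chromosome.
#' @param max_gap Maximum distance (bp) joining two consecutive positions.
#' @return For a data frame input, the input with an integer `cluster`
#'   column (labels unique genome-wide); for a vector, an integer vector of
#'   labels.
#' @export
cluster_positions <- function(x, max_gap) {
  if (is.numeric(x)) {
    return(cluster_one_chrom(x, max_gap))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "pos") %in% names(x)))
  labels <- integer(nrow(x))
  offset <- 0L
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    lab <- cluster_one_chrom(x$pos[idx], max_gap)
    labels[idx] <- lab + offset
    offset <- offset + max(lab)
  }
  out <- x
  out$cluster <- labels
  out
}

cluster_one_chrom <- function(pos, max_gap) {
  if (length(pos) == 0) return(integer(0))
  if (is.unsorted(pos)) stop("positions must be sorted ascending")
  breaks <- c(TRUE, diff(pos) > max_gap)
  cumsum(breaks)
}

#' Per-sample trinucleotide methylation accumulation
#'
#' For each sample and trinucleotide class, the proportion of sites whose
#' beta exceeds `threshold` — e.g. the number of > 10% methylated CAC (or
#' CAG) sites divided by the number of CAC (or CAG) sites. The standard
#' summary of CpH methylation accumulation across development.
#'
#' @param x A cytosine matrix (typically coverage/positivity-filtered CpH).
#' @param meta Optional sample metadata joined onto the result.
#' @param threshold Beta threshold; default 0.10.
#' @param trinucleotides Optional subset of trinucleotide classes to report
#'   (default: all present).
#' @return A tibble with `sample_id`, `trinucleotide`, `n_sites`,
#'   `n_above`, `proportion` (NA for empty classes), plus metadata columns
#'   when `meta` is given.
#' @export
context_accumulation <- function(x, meta = NULL, threshold = 0.10,
                                 trinucleotides = NULL) {
  b <- beta_values(x)
  classes <- if (is.null(trinucleotides)) sort(unique(x$trinucleotide)) else trinucleotides
  out <- purrr::map_dfr(classes, function(tri) {
    rows <- x$trinucleotide == tri
    n_class <- sum(rows)
    above <- if (n_class > 0) {
      unname(colSums(b[rows, , drop = FALSE] > threshold, na.rm = TRUE))
    } else {
      rep(0L, ncol(b))
    }
    prop <- if (n_class > 0) above / n_class else rep(NA_real_, ncol(b))
    tibble::tibble(
      sample_id = colnames(b),
      trinucleotide = tri,
      n_sites = n_class,
      n_above = as.integer(above),
      proportion = prop
    )
  })
  if (!is.null(meta)) out <- dplyr::left_join(out, meta, by = "sample_id")
  out
}
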