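#' Build a cytosine matrix
#'
#' The central container of the package: one row per cytosine (a given
#' `chrom`, `pos`, `strand`) with its sequence context, and two integer
#' matrix-columns `meth` and `total` holding per-sample methylated and total
#' read counts. Because the counts live in matrix-columns, the object is still
#' an ordinary tibble — it pipes through [dplyr::filter()], [dplyr::arrange()]
#' and friends row-wise — while exposing the sites-by-samples layout that the
#' smoothing and site-wise model code works on.
#'
#' @param sites A data frame with columns `chrom`, `pos` (1-based),
#'   `strand` (`"+"`/`"-"`), and `trinucleotide` (3 bases starting with C).
#'   `context` is derived from the trinucleotide if absent, and validated
#'   against it if present.
#' @param meth,total Integer matrices, `nrow(sites)` x n_samples, with matching
#'   sample column names. `meth <= total` cell-wise.
#' @return A `cyto_tbl` tibble sorted by (chrom, strand, pos).
#' @export
cytosine_matrix <- function(sites, meth, total) {
  sites <- tibble::as_tibble(sites)
  req <- c("chrom", "pos", "strand", "trinucleotide")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols) > 0) {
    stop("`sites` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  if (all(meth == round(meth)) && all(total == round(total))) {
    storage.mode(meth) <- "integer"
    storage.mode(total) <- "integer"
  }
  if (is.null(colnames(meth)) || is.null(colnames(total))) {
    stop("`meth` and `total` must carry sample names as column names")
  }
  if (!identical(colnames(meth), colnames(total))) {
    stop("`meth` and `total` sample names differ")
  }
  if (nrow(meth) != nrow(sites) || nrow(total) != nrow(sites)) {
    stop("count matrices must have one row per site")
  }
  if (any(meth < 0) || any(total < 0)) stop("negative counts")
  if (any(meth > total)) {
    stop("meth_count exceeds total_count at ",
         sum(meth > total), " cell(s)")
  }
  derived <- context_from_trinucleotide(sites$trinucleotide)
  if (!is.null(sites[["context"]])) {
    bad <- which(sites[["context"]] != derived)
    if (length(bad) > 0) {
      stop("context inconsistent with trinucleotide at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  sites$context <- derived

  out <- sites[, c("chrom", "pos", "strand", "context", "trinucleotide")]
  out$meth <- meth
  out$total <- total
  ord <- order(out$chrom, out$pos, out$strand)
  out <- out[ord, ]
  dup <- duplicated(out[, c("chrom", "pos", "strand")])
  if (any(dup)) stop("duplicated (chrom, pos, strand) rows")
  class(out) <- c("cyto_tbl", class(out))
  out
}

#' Derive context from a trinucleotide
#'
#' Second base G gives CpG; otherwise third base G gives CHG; otherwise CHH.
#'
#' @param trinucleotide Character vector of 3-base strings starting with C.
#' @return Character vector in `c("CpG", "CHG", "CHH")`.
#' @export
context_from_trinucleotide <- function(trinucleotide) {
  tri <- toupper(trinucleotide)
  bad <- !grepl("^C[ACGT][ACGT]$", tri)
  if (any(bad)) {
    stop("invalid trinucleotide(s): ",
         paste(utils::head(unique(trinucleotide[bad]), 5L), collapse = ", "))
  }
  ifelse(substr(tri, 2L, 2L) == "G", "CpG",
         ifelse(substr(tri, 3L, 3L) == "G", "CHG", "CHH"))
}

#' Accessors for a cytosine matrix
#'
#' `meth_counts()` and `total_counts()` return the integer count matrices;
#' `beta_values()` returns methylated/total with `NA` wherever a sample has no
#' coverage at a site (zero-coverage beta is missing, never 0); `sample_ids()`
#' returns the sample names.
#'
#' @param x A cytosine matrix from [cytosine_matrix()].
#' @return A matrix (or character vector for `sample_ids()`).
#' @export
beta_values <- function(x) {
  m <- meth_counts(x)
  tt <- total_counts(x)
  b <- m / tt
  b[tt == 0] <- NA_real_
  b
}

#' @rdname beta_values
#' @export
meth_counts <- function(x) {
  stopifnot(is.data.frame(x), !is.null(x$meth))
  unclass(x)$meth
}

#' @rdname beta_values
#' @export
total_counts <- function(x) {
  stopifnot(is.data.frame(x), !is.null(x$total))
  unclass(x)$total
}

#' @rdname beta_values
#' @export
sample_ids <- function(x) colnames(meth_counts(x))

#' Pool complementary-strand CpG counts into dinucleotide units
#'
#' By default every cytosine is kept as an independent row (the per-cytosine
#' tests and all CpH work require this). This optional transform collapses the
#' two cytosines of a CpG dinucleotide — plus-strand position p and
#' minus-strand position p+1 — into one plus-strand row with summed counts.
#' Unpaired CpG cytosines are kept as-is; non-CpG rows pass through.
#'
#' @param x A cytosine matrix.
#' @return A cytosine matrix with pooled CpG rows.
#' @export
pool_cpg_strands <- function(x) {
  cg <- x$context == "CpG"
  if (!any(cg)) return(x)
  plus <- x[cg & x$strand == "+", ]
  minus <- x[cg & x$strand == "-", ]
  key_plus <- paste(plus$chrom, plus$pos + 1L)
  key_minus <- paste(minus$chrom, minus$pos)
  hit <- match(key_minus, key_plus)
  pooled_plus <- plus
  mc <- unclass(pooled_plus)$meth
  tc <- unclass(pooled_plus)$total
  paired <- which(!is.na(hit))
  if (length(paired) > 0) {
    mc[hit[paired], ] <- mc[hit[paired], ] + meth_counts(minus)[paired, , drop = FALSE]
    tc[hit[paired], ] <- tc[hit[paired], ] + total_counts(minus)[paired, , drop = FALSE]
  }
  pooled_plus$meth <- mc
  pooled_plus$total <- tc
  keep_minus <- minus[is.na(hit), ]
  out <- dplyr::bind_rows(x[!cg, ], pooled_plus, keep_minus)
  out <- out[order(out$chrom, out$pos, out$strand), ]
  class(out) <- unique(c("cyto_tbl", class(out)))
  out
}
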