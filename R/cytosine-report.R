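#' Read per-cytosine reports into a cytosine matrix
#'
#' Reads the 7-column tab-separated per-cytosine report emitted by standard
#' bisulfite methylation extractors: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide. One file per
#' sample; all files must describe the same set of (chrom, pos, strand) sites.
#'
#' @param paths Character vector of report file paths, named by sample; if
#'   unnamed, `samples` supplies the names.
#' @param samples Sample identifiers defining the column order of the result.
#'   Defaults to `names(paths)`.
#' @return A cytosine matrix (see [cytosine_matrix()]); counts preserved
#'   exactly, zero-coverage cells give missing beta.
#' @export
read_cytosine_report <- function(paths, samples = names(paths)) {
  if (is.null(samples)) stop("`samples` required when `paths` is unnamed")
  if (is.null(names(paths))) names(paths) <- samples
  paths <- paths[samples]
  if (anyNA(paths)) stop("sample(s) missing from `paths`")

  per_sample <- purrr::map(samples, function(s) parse_one_report(paths[[s]]))
  ref <- per_sample[[1L]][, c("chrom", "pos", "strand", "trinucleotide")]
  key <- paste(ref$chrom, ref$pos, ref$strand)
  for (i in seq_along(per_sample)[-1L]) {
    key_i <- paste(per_sample[[i]]$chrom, per_sample[[i]]$pos,
                   per_sample[[i]]$strand)
    if (!identical(sort(key), sort(key_i))) {
      stop("report for sample '", samples[i],
           "' covers a different site set than sample '", samples[1L], "'")
    }
    per_sample[[i]] <- per_sample[[i]][match(key, key_i), ]
  }
  meth <- vapply(per_sample, function(d) d$meth, numeric(nrow(ref)))
  total <- vapply(per_sample, function(d) d$meth + d$unmeth, numeric(nrow(ref)))
  if (nrow(ref) == 1L) {
    meth <- matrix(meth, nrow = 1L)
    total <- matrix(total, nrow = 1L)
  }
  colnames(meth) <- colnames(total) <- samples
  cytosine_matrix(ref, meth, total)
}

parse_one_report <- function(path) {
  d <- tryCatch(
    suppressWarnings(readr::read_tsv(
      path,
      col_names = c("chrom", "pos", "strand", "meth", "unmeth",
                    "context", "trinucleotide"),
      col_types = "ciciicc", progress = FALSE,
      na = character()
    )),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e))
  )
  probs <- readr::problems(d)
  if (nrow(probs) > 0) {
    stop("malformed line ", probs$row[1L], " in '", path, "': ",
         probs$expected[1L], " expected, got ", probs$actual[1L])
  }
  if (any(d$strand %in% c("+", "-") == FALSE)) {
    stop("invalid strand at line ",
         which(!d$strand %in% c("+", "-"))[1L], " in '", path, "'")
  }
  derived <- context_from_trinucleotide(d$trinucleotide)
  norm <- ifelse(toupper(d$context) %in% c("CPG", "CG"), "CpG",
                 toupper(d$context))
  bad <- which(norm != derived)
  if (length(bad) > 0) {
    stop("context/trinucleotide mismatch at line ", bad[1L], " in '", path,
         "': ", d$context[bad[1L]], " vs ", d$trinucleotide[bad[1L]])
  }
  d
}

#' Write one sample of a cytosine matrix as a per-cytosine report
#'
#' Inverse of [read_cytosine_report()]: 7 tab-separated columns, 1-based
#' positions, methylated and unmethylated counts. Reading the file back
#' reproduces the counts exactly.
#'
#' @param x A cytosine matrix.
#' @param sample Sample identifier (a column of the count matrices).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(x, sample, path) {
  m <- meth_counts(x)[, sample]
  tt <- total_counts(x)[, sample]
  d <- tibble::tibble(
    chrom = x$chrom, pos = x$pos, strand = x$strand,
    meth = as.integer(m), unmeth = as.integer(tt - m),
    context = x$context, trinucleotide = x$trinucleotide
  )
  readr::write_tsv(d, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Annotate cytosine context from a reference sequence
#'
#' For each position, takes the base at `pos` plus the next two bases in
#' strand orientation (reverse-complement for the minus strand) and derives
#' the CpG/CHG/CHH context. Positions that are not a cytosine on the requested
#' strand raise an error; positions with fewer than two downstream bases are
#' dropped (context undeterminable near contig ends) with a message.
#'
#' @param reference_sequence A single reference sequence: a character string
#'   or a [Biostrings::DNAString].
#' @param pos Integer vector of 1-based positions (plus-strand coordinates).
#' @param strand Character vector (`"+"`/`"-"`), recycled to `length(pos)`.
#' @return A tibble with `pos`, `strand`, `context`, `trinucleotide`, one row
#'   per retained position.
#' @export
annotate_context <- function(reference_sequence, pos, strand = "+") {
  seq <- toupper(as.character(reference_sequence))
  n <- nchar(seq)
  strand <- rep_len(strand, length(pos))
  base_at <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- which(p >= 1L & p <= n)
    if (length(ok) > 0) out[ok] <- substring(seq, p[ok], p[ok])
    out
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ref_base <- base_at(pos)
  is_c <- ifelse(strand == "+", ref_base == "C", ref_base == "G")
  if (any(!is_c, na.rm = TRUE) || anyNA(ref_base)) {
    bad <- which(is.na(ref_base) | !is_c)[1L]
    stop("position ", pos[bad], " is not a cytosine on strand '",
         strand[bad], "'")
  }
  p1 <- ifelse(strand == "+", pos + 1L, pos - 1L)
  p2 <- ifelse(strand == "+", pos + 2L, pos - 2L)
  b1 <- base_at(p1)
  b2 <- base_at(p2)
  minus <- strand == "-"
  b1[minus] <- comp[b1[minus]]
  b2[minus] <- comp[b2[minus]]
  keep <- !is.na(b1) & !is.na(b2)
  if (any(!keep)) {
    message(sum(!keep), " site(s) dropped: fewer than 2 downstream bases")
  }
  if (!any(keep)) {
    return(tibble::tibble(pos = integer(0), strand = character(0),
                          context = character(0),
                          trinucleotide = character(0)))
  }
  tri <- paste0("C", b1[keep], b2[keep])
  tibble::tibble(
    pos = pos[keep], strand = strand[keep],
    context = context_from_trinucleotide(tri), trinucleotide = tri
  )
}

#' Build sample metadata
#'
#' Standardises the per-sample design information: cell fraction, prenatal
#' flag, age in years, and the derived developmental age group with
#' boundaries infant \[0, 1\], child (1, 10\], teen (10, 17\], adult (17, Inf).
#'
#' @param sample_id Character vector of sample identifiers.
#' @param cell_fraction One of `"neuron"`, `"glia"`, `"homogenate"` per sample.
#' @param age Age in years (postnatal ages are non-negative).
#' @param prenatal Logical; prenatal samples carry `age = 0` by convention.
#' @return A tibble with one row per sample and an `age_group` factor.
#' @export
sample_meta <- function(sample_id, cell_fraction, age, prenatal = FALSE) {
  cell_fraction <- match.arg(cell_fraction,
                             c("neuron", "glia", "homogenate"),
                             several.ok = TRUE)
  prenatal <- rep_len(prenatal, length(sample_id))
  if (any(age < 0 & !prenatal)) stop("postnatal age must be >= 0")
  tibble::tibble(
    sample_id = as.character(sample_id),
    cell_fraction = rep_len(cell_fraction, length(sample_id)),
    prenatal = prenatal,
    age = as.numeric(age),
    age_group = age_group(age)
  )
}

#' @rdname sample_meta
#' @export
age_group <- function(age) {
  cut(age, breaks = c(-Inf, 1, 10, 17, Inf),
      labels = c("infant", "child", "teen", "adult"),
      right = TRUE)
}
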