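#' Write regions as BED6
#'
#' Internal 0-based half-open coordinates map directly onto BED. The name
#' field takes the region kind (and id when present); the score field
#' carries `round(1000 * pmeth)` when a `pmeth` column exists.
#'
#' @param regions Region tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- regions[["id"]] %||% regions[["kind"]] %||% rep(".", nrow(regions))
  score <- if (!is.null(regions[["pmeth"]])) {
    round(1000 * regions$pmeth)
  } else {
    rep(0L, nrow(regions))
  }
  strand <- regions[["strand"]] %||% rep(".", nrow(regions))
  d <- tibble::tibble(
    chrom = regions$chrom,
    start = format(regions$start, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    name = name, score = score, strand = strand
  )
  readr::write_tsv(d, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED file (3-6 columns, optional extra label column)
#'
#' @param path BED file path.
#' @return A tibble with `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand` present in the file.
#' @export
read_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       show_col_types = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(d) <- c(nm[seq_len(min(ncol(d), 6L))],
                if (ncol(d) > 6L) paste0("extra_", seq_len(ncol(d) - 6L)))
  d$start <- as.numeric(d$start)
  d$end <- as.numeric(d$end)
  d
}
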