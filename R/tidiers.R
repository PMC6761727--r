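#' Tidy a bump-hunting result
#'
#' @param x A `bumphunt` object.
#' @param ... Unused.
#' @return The candidate-region tibble, ordered by FWER then area.
#' @export
tidy.bumphunt <- function(x, ...) {
  r <- x$regions
  r[order(r$fwer, -r$area), , drop = FALSE]
}

#' @rdname tidy.bumphunt
#' @return For `glance()`: a one-row tibble with the run parameters, the
#'   candidate and significant region counts, and the permutation maximum
#'   area quantiles.
#' @export
glance.bumphunt <- function(x, ...) {
  tibble::tibble(
    design = x$design, coef = x$coef, cutoff = x$cutoff,
    max_gap = x$max_gap, n_perms = x$n_perms, n_sites = x$n_sites,
    n_candidates = nrow(x$regions),
    n_significant = sum(x$regions$fwer < 0.05),
    perm_max_median = stats::median(x$perm_max),
    perm_max_q95 = stats::quantile(x$perm_max, 0.95)[[1L]]
  )
}

#' Tidy a trajectory clustering
#'
#' @param x A `traj_clusters` object.
#' @param ... Unused.
#' @return Per-region assignments with the semantic group label.
#' @export
tidy.traj_clusters <- function(x, ...) {
  a <- x$assignments
  a$group_label <- x$labels[a$group]
  a
}

#' @rdname tidy.traj_clusters
#' @export
glance.traj_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_regions = nrow(x$assignments),
    total_within_ss = x$wss,
    largest_group = max(tabulate(x$assignments$group, x$k)),
    smallest_group = min(tabulate(x$assignments$group, x$k))
  )
}

#' @export
print.traj_clusters <- function(x, ...) {
  cat("Trajectory clustering: k = ", x$k, ", ",
      nrow(x$assignments), " regions\n", sep = "")
  counts <- tabulate(x$assignments$group, x$k)
  for (g in seq_len(x$k)) {
    cat(sprintf("  %d. %-42s %4d regions\n", g, x$labels[g], counts[g]))
  }
  invisible(x)
}
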