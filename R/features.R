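# Structural characterisation: per-group length and exon-number summaries
# and two-group t statistics. The same operations serve lncRNAs and mRNAs
# (biotype == "coding"); there is no separate mRNA code path.

#' Summarise the structure of a transcript group
#'
#' @param ts a `transcript_set` (nonempty).
#' @param label group label carried into the output.
#' @param breaks histogram bin breaks for spliced length (nt); the last
#'   bin is open-ended.
#' @return list of class `group_stats`: `label`, `n`, `median_length`,
#'   `mean_exon_count`, `single_exon_pct` (half-up, 2 decimals), and a
#'   `length_hist` data.frame of bin counts.
#' @export
summarize_group <- function(ts, label = "group",
                            breaks = c(200, 500, 1000, 2000, 5000, Inf)) {
  tx <- ts$transcripts
  if (nrow(tx) == 0) stop("empty transcript group: ", label)
  h <- hist(tx$length, breaks = c(0, breaks), plot = FALSE)
  structure(list(
    label = label,
    n = nrow(tx),
    median_length = stats::median(tx$length),
    mean_exon_count = mean(tx$exon_count),
    single_exon_pct = pct(sum(tx$exon_count == 1L), nrow(tx)),
    length_hist = data.frame(bin_low = utils::head(c(0, breaks), -1),
                             bin_high = breaks,
                             count = h$counts)
  ), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf(
    "group_stats '%s': n = %d, median length = %g nt, mean exons = %.2f, single-exon = %.2f%%\n",
    x$label, x$n, x$median_length, x$mean_exon_count, x$single_exon_pct))
  invisible(x)
}

#' Two-group comparison by t statistics
#'
#' Welch's unequal-variance t test by default (group variances of
#' transcript features plainly differ between genomes); `student = TRUE`
#' switches to the pooled-variance Student test. Two identical degenerate
#' groups (both zero variance, equal means) return p = 1 rather than an
#' error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param labels length-2 character vector naming the groups.
#' @param student use pooled-variance Student's t instead of Welch.
#' @return data.frame (class `group_comparison`) with `group_a`,
#'   `group_b`, `t`, `df`, `p_value`, `significance` (`"n.s."`, `"*"` for
#'   p < 0.05, `"**"` for p < 0.01).
#' @export
compare_groups <- function(a, b, labels = c("A", "B"), student = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                 parameter = length(a) + length(b) - 2, p.value = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = student)
  }
  p <- tt$p.value
  out <- data.frame(group_a = labels[1], group_b = labels[2],
                    t = unname(tt$statistic), df = unname(tt$parameter),
                    p_value = p,
                    significance = if (p < 0.01) "**"
                                   else if (p < 0.05) "*" else "n.s.",
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Structural comparison table across genomes
#'
#' Runs [summarize_group()] per genome and [compare_groups()] on spliced
#' length and exon count for every genome pair, for one biotype class.
#'
#' @param sets named list (by genome) of `transcript_set`s.
#' @param student passed to [compare_groups()].
#' @return list with `stats` (one row per genome) and `comparisons`
#'   (one row per genome pair and feature).
#' @export
summarize_features <- function(sets, student = FALSE) {
  g <- names(sets)
  st <- lapply(g, function(x) summarize_group(sets[[x]], label = x))
  stats_df <- data.frame(
    genome = g,
    n = vapply(st, `[[`, numeric(1), "n"),
    median_length = vapply(st, `[[`, numeric(1), "median_length"),
    mean_exon_count = vapply(st, `[[`, numeric(1), "mean_exon_count"),
    single_exon_pct = vapply(st, `[[`, numeric(1), "single_exon_pct"),
    stringsAsFactors = FALSE)
  cmp <- list()
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i >= j) next
    for (feat in c("length", "exon_count")) {
      va <- sets[[g[i]]]$transcripts[[feat]]
      vb <- sets[[g[j]]]$transcripts[[feat]]
      row <- compare_groups(va, vb, labels = c(g[i], g[j]),
                            student = student)
      row$feature <- feat
      cmp[[length(cmp) + 1L]] <- row
    }
  }
  list(stats = stats_df, comparisons = do.call(rbind, cmp))
}
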