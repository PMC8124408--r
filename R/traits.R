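# Mutant-vs-wild-type agronomic trait statistics, summarised in the
# conventional "mean +/- SD(mark arrow)" table format.

#' Compare a mutant trait sample against its wild type
#'
#' Two-sided pooled-variance Student's t test (the test conventionally
#' named for such trait tables); `welch = TRUE` switches to the
#' unequal-variance form. Significance marks: `**` for p < 0.01, `*` for
#' 0.01 <= p < 0.05, `n.s.` otherwise; the arrow gives the direction of
#' the mutant mean relative to wild type and is shown only with a
#' significant mark.
#'
#' @param wildtype,mutant numeric vectors of per-plant measurements for
#'   the same trait (each n >= 2).
#' @param trait trait name (must agree between the two samples when
#'   supplied via [trait_sample()] objects).
#' @param welch use Welch's t instead of the pooled-variance test.
#' @return data.frame (class `trait_summary`): `trait`, per-group `n`,
#'   `mean`, `sd` (2 decimals), `t`, `df`, `p_value`, `mark`, `arrow`.
#' @export
compare_trait <- function(wildtype, mutant, trait = "trait",
                          welch = FALSE) {
  wt_name <- mt_name <- trait
  if (is.list(wildtype) && !is.null(wildtype$trait)) {
    wt_name <- wildtype$trait; wildtype <- wildtype$values
  }
  if (is.list(mutant) && !is.null(mutant$trait)) {
    mt_name <- mutant$trait; mutant <- mutant$values
  }
  if (!identical(wt_name, mt_name))
    stop("mismatched trait names: '", wt_name, "' vs '", mt_name, "'")
  stopifnot(length(wildtype) >= 2, length(mutant) >= 2)
  if (stats::var(wildtype) == 0 && stats::var(mutant) == 0 &&
      mean(wildtype) == mean(mutant)) {
    tt <- list(statistic = 0,
               parameter = length(wildtype) + length(mutant) - 2,
               p.value = 1)
  } else {
    tt <- stats::t.test(mutant, wildtype, var.equal = !welch)
  }
  p <- tt$p.value
  mark <- if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
  arrow <- if (mark == "n.s.") "none"
           else if (mean(mutant) > mean(wildtype)) "up" else "down"
  out <- data.frame(
    trait = wt_name,
    n_wt = length(wildtype), mean_wt = round_half_up(mean(wildtype), 2),
    sd_wt = round_half_up(stats::sd(wildtype), 2),
    n_mut = length(mutant), mean_mut = round_half_up(mean(mutant), 2),
    sd_mut = round_half_up(stats::sd(mutant), 2),
    t = unname(tt$statistic), df = unname(tt$parameter), p_value = p,
    mark = mark, arrow = arrow, stringsAsFactors = FALSE)
  class(out) <- c("trait_summary", "data.frame")
  out
}

#' A labelled trait sample
#'
#' @param values numeric vector of per-plant measurements.
#' @param trait trait name.
#' @param units units string (recorded, not checked).
#' @param line line identifier.
#' @return list of class `trait_sample`.
#' @export
trait_sample <- function(values, trait, units = "", line = "") {
  stopifnot(is.numeric(values))
  structure(list(values = values, trait = trait, units = units,
                 line = line), class = "trait_sample")
}

.arrow_glyph <- c(up = "↑", down = "↓", none = "")

#' Render trait summaries as a publication-style table
#'
#' Cell text is `"mean ± SD"` for the wild type and
#' `"mean ± SD(mark arrow)"` for each mutant line, e.g.
#' `"16.62 ± 2.04(n.s.)"` or `"51.38 ± 3.87(**↓)"`.
#' Columns are traits, rows are lines.
#'
#' @param summaries data.frame of [compare_trait()] rows with an added
#'   `line` column naming each mutant line.
#' @param wildtype_label row label for the wild-type entries.
#' @return data.frame: first column `line`, one column per trait.
#' @export
render_trait_table <- function(summaries, wildtype_label = "wild-type") {
  traits <- unique(summaries$trait)
  lines <- unique(summaries$line)
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  out <- data.frame(line = c(wildtype_label, lines),
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    sub <- summaries[summaries$trait == tr, , drop = FALSE]
    wt_cell <- fmt(sub$mean_wt[1], sub$sd_wt[1])
    cells <- vapply(lines, function(l) {
      r <- sub[sub$line == l, , drop = FALSE]
      if (nrow(r) == 0) return(NA_character_)
      suffix <- if (r$mark == "n.s.") "(n.s.)"
                else paste0("(", r$mark, .arrow_glyph[[r$arrow]], ")")
      paste0(fmt(r$mean_mut, r$sd_mut), suffix)
    }, character(1))
    out[[tr]] <- c(wt_cell, unname(cells))
  }
  out
}

#' Parse a rendered trait cell back into its components
#'
#' Inverse of the [render_trait_table()] cell format, for round-trip
#' checks and downstream reuse.
#'
#' @param cell character cell like `"51.38 ± 3.87(**↓)"`.
#' @return list with `mean`, `sd`, `mark` (`NA` for a wild-type cell),
#'   `arrow`.
#' @export
parse_trait_cell <- function(cell) {
  m <- regmatches(cell,
                  regexec("^([0-9.]+) ± ([0-9.]+)(\\((.*)\\))?$", cell))[[1]]
  if (!length(m)) stop("unparseable trait cell: ", cell)
  mark <- NA_character_; arrow <- "none"
  if (nzchar(m[4])) {
    inner <- m[5]
    if (inner == "n.s.") {
      mark <- "n.s."
    } else {
      mark <- gsub("[^*]", "", inner)
      arrow <- if (grepl("↑", inner)) "up"
               else if (grepl("↓", inner)) "down" else "none"
    }
  }
  list(mean = as.numeric(m[2]), sd = as.numeric(m[3]), mark = mark,
       arrow = arrow)
}

#' Summarise a long-format trait table against a wild-type line
#'
#' @param df data.frame with columns `line`, `trait`, `value`.
#' @param wildtype label of the wild-type line in `line`.
#' @param welch passed to [compare_trait()].
#' @return data.frame of [compare_trait()] rows, one per (line, trait),
#'   with a `line` column.
#' @export
summarize_traits <- function(df, wildtype, welch = FALSE) {
  stopifnot(all(c("line", "trait", "value") %in% names(df)),
            wildtype %in% df$line)
  rows <- list()
  for (tr in unique(df$trait)) {
    wt <- df$value[df$line == wildtype & df$trait == tr]
    for (l in setdiff(unique(df$line[df$trait == tr]), wildtype)) {
      s <- compare_trait(wt, df$value[df$line == l & df$trait == tr],
                         trait = tr, welch = welch)
      s$line <- l
      rows[[length(rows) + 1L]] <- s
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
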