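#' Round half away from zero to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; published percentage tables are
#' conventionally rounded half-up (52.555 -> 52.56). Used for all reported
#' percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(100 * 1099 / 2091, 2) # 52.56
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a part in a whole, rounded half-up to two decimals
#'
#' @param part,whole numeric; `whole` may be zero, giving `NA`.
#' @param digits decimal places (default 2).
#' @return numeric percentage.
#' @export
#' @examples
#' pct(628, 4072) # 15.42
pct <- function(part, whole, digits = 2) {
  ifelse(whole == 0, NA_real_, round_half_up(100 * part / whole, digits))
}

# Derive a per-stage seed from a global seed so stages can be rerun in
# isolation. Kept strictly below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, discover = 2L, features = 3L, de = 4L,
              homology = 5L, synteny = 6L, traits = 7L)
  k <- stages[[stage]]
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483587)
}

msg <- function(...) message("[oryzalnc] ", ...)

.datatable.aware <- TRUE

utils::globalVariables(c(".", ".N", "kmer", "qid", "sid", "N"))

`%||%` <- function(a, b) if (is.null(a)) b else a
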