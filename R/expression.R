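# FPKM quantification and panicle-vs-seedling differential expression.
#
# The study design has one library per (genome, tissue), so replicate-based
# tests are unavailable. Differential expression uses an exact binomial
# contrast of the two counts (Audic-Claverie style): conditional on the
# total count, the panicle count is Binomial(c_p + c_s, N_p / (N_p + N_s))
# under the null of equal concentration. A Fisher-exact variant against the
# remainder of each library is available behind a flag. Both are documented
# stand-ins for the unreplicated design.

#' Compute an FPKM expression table
#'
#' FPKM_{i,s} = count_{i,s} * 1e9 / (length_i * library_size_s).
#'
#' @param counts numeric matrix of fragment counts, rows named by
#'   transcript id, columns by sample.
#' @param lengths named vector of effective (spliced) lengths in nt; every
#'   counted transcript must be present.
#' @param lib_sizes named vector of library sizes (total mapped fragments
#'   per sample); defaults to the column sums of `counts`.
#' @return list of class `expression_table`: `counts`, `fpkm` (same
#'   dimnames), `lengths`, `lib_sizes`.
#' @export
compute_fpkm <- function(counts, lengths, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have transcript rownames")
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("missing effective length for transcript(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  L <- lengths[rownames(counts)]
  stopifnot(all(L >= 1), all(lib_sizes >= 1))
  fpkm <- sweep(counts * 1e9 / L, 2, lib_sizes, "/")
  structure(list(counts = counts, fpkm = fpkm, lengths = L,
                 lib_sizes = lib_sizes),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table: ", nrow(x$counts), " transcripts x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' log10(FPKM + 1) matrix
#'
#' The heatmap-ready transform: elementwise log10(FPKM + 1), so FPKM 0
#' maps to 0 and FPKM 9 to 1.
#'
#' @param expr an `expression_table` (or bare FPKM matrix).
#' @return numeric matrix.
#' @export
log_matrix <- function(expr) {
  fpkm <- if (inherits(expr, "expression_table")) expr$fpkm else expr
  log10(fpkm + 1)
}

# Two-sided exact binomial p-value, the "sum of all outcomes at most as
# probable as the observed one" definition used by stats::binom.test,
# vectorised over transcripts.
.binom_p2 <- function(x, n, p0) {
  mapply(function(xi, ni) {
    d <- stats::dbinom(0:ni, ni, p0)
    # 1 + 1e-7 relative tolerance, matching stats::binom.test
    sum(d[d <= d[xi + 1L] * (1 + 1e-7)])
  }, x, n)
}

#' Differential expression between two unreplicated samples
#'
#' @param expr an `expression_table`.
#' @param sample_a,sample_b column names of the contrasted samples
#'   (conventionally panicle and seedling). Fold change is a-over-b.
#' @param epsilon FPKM pseudocount for fold changes (default 0.01).
#' @param fc_threshold fold-change cutoff; a transcript passes when
#'   FC > fc_threshold or FC < 1/fc_threshold (default 2).
#' @param alpha FDR cutoff on the Benjamini-Hochberg adjusted p (default
#'   0.05).
#' @param method `"binomial"` (exact binomial contrast, default) or
#'   `"fisher"` (Fisher's exact test on the 2x2 count/remainder table).
#' @return data.frame (class `de_result`) with one row per transcript:
#'   `transcript_id`, counts, FPKMs, `fc`, `log2_fc`, `p_value`, `q_value`
#'   (BH), `tested`, `de` (verdict: both fold-change and FDR criteria),
#'   `direction`. Transcripts with zero counts in both samples are
#'   reported untested (`tested = FALSE`, NA p).
#' @export
differential_expression <- function(expr, sample_a, sample_b,
                                    epsilon = 0.01, fc_threshold = 2,
                                    alpha = 0.05, method = c("binomial",
                                                             "fisher")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "expression_table"),
            all(c(sample_a, sample_b) %in% colnames(expr$counts)))
  ca <- expr$counts[, sample_a]
  cb <- expr$counts[, sample_b]
  Na <- expr$lib_sizes[[sample_a]]
  Nb <- expr$lib_sizes[[sample_b]]
  fa <- expr$fpkm[, sample_a]
  fb <- expr$fpkm[, sample_b]
  tested <- (ca + cb) > 0
  p <- rep(NA_real_, length(ca))
  if (method == "binomial") {
    p0 <- Na / (Na + Nb)
    p[tested] <- .binom_p2(ca[tested], ca[tested] + cb[tested], p0)
  } else {
    p[tested] <- mapply(function(xa, xb) {
      stats::fisher.test(matrix(c(xa, Na - xa, xb, Nb - xb), 2))$p.value
    }, ca[tested], cb[tested])
  }
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  fc <- (fa + epsilon) / (fb + epsilon)
  de <- tested & (fc > fc_threshold | fc < 1 / fc_threshold) & q < alpha
  out <- data.frame(
    transcript_id = rownames(expr$counts),
    count_a = unname(ca), count_b = unname(cb),
    fpkm_a = unname(fa), fpkm_b = unname(fb),
    fc = unname(fc), log2_fc = unname(log2(fc)),
    p_value = unname(p), q_value = unname(q),
    tested = unname(tested),
    de = unname(ifelse(is.na(de), FALSE, de)),
    direction = ifelse(tested & !is.na(de) & de,
                       ifelse(fc > 1, "up", "down"), "none"),
    stringsAsFactors = FALSE)
  attr(out, "samples") <- c(a = sample_a, b = sample_b)
  attr(out, "thresholds") <- c(fc = fc_threshold, alpha = alpha,
                               epsilon = epsilon)
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  s <- attr(x, "samples")
  cat("de_result ", s[["a"]], " vs ", s[["b"]], ": ", sum(x$de), " DE of ",
      sum(x$tested), " tested (", nrow(x), " transcripts)\n", sep = "")
  invisible(x)
}
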