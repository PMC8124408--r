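#' Alignment parameters for the homology screen
#'
#' Scoring defaults are chosen near megablast's (+1 match, -2 mismatch)
#' with affine gaps: a gap of length L costs `gap_open + L * gap_extend`.
#' The screen thresholds are strict: a segment passes only if its aligned
#' length exceeds `min_segment_length` columns AND its percent identity
#' exceeds `min_identity`.
#'
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -2). `N` scores as a mismatch
#'   against every base and never counts as an identity.
#' @param gap_open gap opening penalty (default -4).
#' @param gap_extend gap extension penalty (default -1).
#' @param min_segment_length strict lower bound on alignment columns
#'   (default 100, i.e. a segment must be > 100 columns).
#' @param min_identity strict lower bound on percent identity (default 90).
#' @param both_strands also search the reverse complement of the subject
#'   (default TRUE).
#' @param seed_k k-mer length for the seeding prefilter in set-vs-set
#'   screens (default 11).
#' @param min_seed_kmers minimum number of shared k-mers for a pair to be
#'   aligned in set-vs-set screens (default 3); set to 0 to align all pairs.
#' @return list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = -4,
                         gap_extend = -1, min_segment_length = 100,
                         min_identity = 90, both_strands = TRUE,
                         seed_k = 11L, min_seed_kmers = 3L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            min_identity > 0, min_identity <= 100)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 min_segment_length = min_segment_length,
                 min_identity = min_identity, both_strands = both_strands,
                 seed_k = as.integer(seed_k),
                 min_seed_kmers = as.integer(min_seed_kmers)),
            class = "align_params")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman with affine gaps (Gotoh). When `both_strands` is enabled
#' the reverse complement of the subject is also searched and the
#' higher-scoring hit kept (forward preferred on ties); reverse-strand hits
#' report subject coordinates on the forward strand with `strand = "-"`.
#' Percent identity uses the BLAST convention: identities divided by total
#' alignment columns, gap columns included.
#'
#' @param a query sequence (character, over A/C/G/T/N).
#' @param b subject sequence.
#' @param params an [align_params()] object.
#' @return A one-row data.frame (class `homology_segment`) with `score`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `strand`,
#'   `aligned_length` (columns), `identities`, `identity_pct`; or `NULL`
#'   when no positive-scoring local alignment exists (e.g. an empty
#'   sequence).
#' @export
local_align <- function(a, b, params = align_params()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0 || nchar(b) == 0) return(NULL)
  hit <- .sw_align_cpp(a, b, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  best <- NULL
  if (!is.null(hit$aligned_length)) {
    hit$strand <- "+"
    best <- hit
  }
  if (isTRUE(params$both_strands)) {
    brc <- revcomp(b)
    hit2 <- .sw_align_cpp(a, brc, params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
    if (!is.null(hit2$aligned_length) &&
        (is.null(best) || hit2$score > best$score)) {
      m <- nchar(b)
      ss <- m - hit2$subject_end + 1L
      se <- m - hit2$subject_start + 1L
      hit2$subject_start <- ss
      hit2$subject_end <- se
      hit2$strand <- "-"
      best <- hit2
    }
  }
  if (is.null(best)) return(NULL)
  out <- data.frame(score = best$score,
                    query_start = best$query_start,
                    query_end = best$query_end,
                    subject_start = best$subject_start,
                    subject_end = best$subject_end,
                    strand = best$strand,
                    aligned_length = best$aligned_length,
                    identities = best$identities,
                    identity_pct = 100 * best$identities / best$aligned_length,
                    stringsAsFactors = FALSE)
  class(out) <- c("homology_segment", "data.frame")
  out
}
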