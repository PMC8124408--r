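# The lncRNA identification cascade: candidate transcripts pass, in order,
# a biotype gate (not annotated protein-coding), a length gate (> 200 nt),
# an expression gate (FPKM >= 0.1 in at least one sample) and a
# coding-potential gate (both scorers < 0). Each candidate receives an
# audit row recording the first gate it failed.

#' Filter thresholds for lncRNA identification
#'
#' Defaults encode the conventional screen: spliced length strictly greater
#' than 200 nt, maximum FPKM across samples at least 0.1, and both
#' coding-potential scores strictly below 0.
#'
#' @param min_length minimum spliced length in nt, inclusive (default 201,
#'   i.e. strictly longer than 200 nt).
#' @param min_fpkm minimum FPKM, inclusive (default 0.1); the gate uses the
#'   maximum over the transcript's samples.
#' @param max_coding_score exclusive ceiling applied to each coding score
#'   (default 0: both scores must be < 0).
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_length = 201, min_fpkm = 0.1,
                              max_coding_score = 0) {
  stopifnot(min_length >= 1, min_fpkm >= 0)
  structure(list(min_length = min_length, min_fpkm = min_fpkm,
                 max_coding_score = max_coding_score),
            class = "filter_thresholds")
}

#' Identify lncRNAs by the filter cascade
#'
#' @param candidates a [transcript_set()] of candidate transcripts.
#' @param fpkm numeric matrix of FPKM values, rows named by transcript id
#'   (e.g. from [compute_fpkm()]), columns are samples.
#' @param scores data.frame with columns `transcript_id`, `cpc_score`,
#'   `cnci_score` (any two coding-potential scorers; negative means
#'   noncoding).
#' @param th a [filter_thresholds()] object.
#' @return list of class `discovery_result`: `retained` (a
#'   `transcript_set` of lncRNAs, biotype set to `"lncRNA"`) and `audit`
#'   (data.frame with one row per candidate: `transcript_id`, `verdict`,
#'   `first_failed_filter`, and the value observed at each gate).
#' @export
filter_lncrnas <- function(candidates, fpkm, scores,
                           th = filter_thresholds()) {
  tx <- candidates$transcripts
  m <- match(tx$transcript_id, rownames(fpkm))
  if (anyNA(m))
    stop("candidate(s) missing an expression row: ",
         paste(utils::head(tx$transcript_id[is.na(m)], 5), collapse = ", "))
  ms <- match(tx$transcript_id, scores$transcript_id)
  if (anyNA(ms) || anyNA(scores$cpc_score[ms]) || anyNA(scores$cnci_score[ms]))
    stop("candidate(s) missing a coding-score row: ",
         paste(utils::head(tx$transcript_id[is.na(ms)], 5), collapse = ", "))

  max_fpkm <- apply(fpkm[m, , drop = FALSE], 1, max)
  cpc <- scores$cpc_score[ms]
  cnci <- scores$cnci_score[ms]

  pass_biotype <- tx$biotype != "coding"
  pass_length <- tx$length >= th$min_length
  pass_expr <- max_fpkm >= th$min_fpkm
  pass_coding <- cpc < th$max_coding_score & cnci < th$max_coding_score

  first_failed <- rep("none", nrow(tx))
  first_failed[!pass_coding] <- "coding_potential"
  first_failed[!pass_expr] <- "expression"
  first_failed[!pass_length] <- "length"
  first_failed[!pass_biotype] <- "biotype"

  audit <- data.frame(
    transcript_id = tx$transcript_id,
    verdict = ifelse(first_failed == "none", "retained", "rejected"),
    first_failed_filter = first_failed,
    biotype = tx$biotype,
    length = tx$length,
    max_fpkm = unname(max_fpkm),
    cpc_score = cpc,
    cnci_score = cnci,
    stringsAsFactors = FALSE
  )
  retained <- subset_transcripts(candidates,
                                 tx$transcript_id[first_failed == "none"])
  retained$transcripts$biotype <- "lncRNA"
  structure(list(retained = retained, audit = audit),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("discovery_result: ", sum(x$audit$verdict == "retained"),
      " lncRNAs retained of ", nrow(x$audit), " candidates\n", sep = "")
  print(table(x$audit$first_failed_filter))
  invisible(x)
}

#' Classify retained lncRNAs as known or novel
#'
#' A lncRNA is known when it has same-strand exonic overlap of at least
#' `min_overlap` nt with any transcript of the reference lncRNA
#' annotation. Genomes without a reference annotation (`reference = NULL`)
#' have all lncRNAs novel; a reference on a disjoint chromosome namespace
#' triggers a warning and an all-novel call.
#'
#' @param lncrnas a `transcript_set` of retained lncRNAs.
#' @param reference a `transcript_set` of reference lncRNAs on the same
#'   assembly, or NULL.
#' @param min_overlap minimum exonic overlap in nt (default 1).
#' @return named logical vector, TRUE = known.
#' @export
classify_known <- function(lncrnas, reference = NULL, min_overlap = 1L) {
  ids <- lncrnas$transcripts$transcript_id
  known <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (is.null(reference)) return(known)
  if (!any(unique(lncrnas$exons$chrom) %in% unique(reference$exons$chrom))) {
    warning("reference annotation shares no chromosome names with the ",
            "lncRNA set; all lncRNAs called novel")
    return(known)
  }
  gr_q <- GenomicRanges::GRanges(lncrnas$exons$chrom,
                                 IRanges::IRanges(lncrnas$exons$start,
                                                  lncrnas$exons$end),
                                 strand = lncrnas$exons$strand)
  gr_r <- GenomicRanges::GRanges(reference$exons$chrom,
                                 IRanges::IRanges(reference$exons$start,
                                                  reference$exons$end),
                                 strand = reference$exons$strand)
  ov <- GenomicRanges::findOverlaps(gr_q, gr_r, minoverlap = min_overlap,
                                    ignore.strand = FALSE)
  hit_tx <- unique(lncrnas$exons$transcript_id[S4Vectors::queryHits(ov)])
  known[hit_tx] <- TRUE
  known
}

#' Summarise discovery per genome
#'
#' @param retained named list (by genome) of retained `transcript_set`s.
#' @param known named list (by genome) of logical known-vectors, as from
#'   [classify_known()].
#' @return data.frame with per-genome lncRNA counts, known/novel counts
#'   and percentages (half-up, two decimals).
#' @export
summarize_discovery <- function(retained, known) {
  g <- names(retained)
  n <- vapply(retained, length, integer(1))
  nk <- vapply(g, function(x) sum(known[[x]]), integer(1))
  data.frame(genome = g,
             n_lncrna = unname(n),
             n_known = unname(nk),
             n_novel = unname(n - nk),
             pct_known = pct(unname(nk), unname(n)),
             pct_novel = pct(unname(n - nk), unname(n)),
             stringsAsFactors = FALSE)
}

#' Fallback coding-potential scorer (not CPC/CNCI)
#'
#' The cascade consumes coding-potential scores from external tools. This
#' built-in fallback exists only so self-contained runs need no external
#' scorer: it scores a transcript by the fraction of its length covered by
#' the longest ATG-initiated open reading frame (any frame, either
#' strand), minus an offset, so ORF-poor transcripts score below zero and
#' ORF-rich ones above. The default offset of 0.5 sits above the typical
#' longest-ORF fraction of random nucleotide sequence at lncRNA lengths
#' (median about 0.36 over six frames). It is a crude proxy and is clearly
#' not a substitute measure of coding potential for real data.
#'
#' @param seqs named character vector of transcript sequences.
#' @param offset ORF-fraction offset subtracted from every score.
#' @return data.frame with `transcript_id`, `cpc_score`, `cnci_score`
#'   (the same fallback value supplied to both scorer slots).
#' @export
orf_fraction_scores <- function(seqs, offset = 0.5) {
  longest_orf <- function(s) {
    best <- 0L
    for (frame_seq in c(s, revcomp(s))) {
      n <- nchar(frame_seq)
      for (off in 0:2) {
        if (n - off < 3) next
        starts <- seq(1 + off, n - 2, by = 3)
        codons <- substring(frame_seq, starts, starts + 2)
        stops <- c(0L, which(codons %in% c("TAA", "TAG", "TGA")),
                   length(codons) + 1L)
        atg <- which(codons == "ATG")
        for (k in seq_len(length(stops) - 1L)) {
          lo <- stops[k] + 1L; hi <- stops[k + 1L] - 1L
          if (hi < lo) next
          first_atg <- atg[atg >= lo & atg <= hi]
          if (!length(first_atg)) next
          best <- max(best, 3L * (hi - first_atg[1L] + 1L))
        }
      }
    }
    best
  }
  frac <- vapply(seqs, function(s) longest_orf(s) / nchar(s), numeric(1))
  score <- frac - offset
  data.frame(transcript_id = names(seqs),
             cpc_score = unname(score), cnci_score = unname(score),
             stringsAsFactors = FALSE)
}
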