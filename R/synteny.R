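# Positional-conservation calling: each lncRNA is anchored by its five
# nearest protein-coding genes; a cross-genome lncRNA pair is positionally
# conserved when at least 4 of the 5 anchors have orthologs lying in (or
# within a rank window of) the partner lncRNA's neighbourhood.

#' Flanking-gene contexts for lncRNAs
#'
#' For every lncRNA, the 5 nearest protein-coding genes on its chromosome
#' by absolute midpoint distance (ties broken by lower start coordinate),
#' each labelled upstream/downstream. Chromosomes holding fewer than 5
#' coding genes yield incomplete contexts, which are excluded from calling
#' and listed separately.
#'
#' @param lncrnas a `transcript_set` of lncRNAs.
#' @param annotation a `transcript_set` holding the genome's coding genes
#'   (biotype `"coding"`); one transcript per gene is assumed
#'   representative.
#' @param n_genes context size (default 5).
#' @return list of class `flank_contexts`: `contexts` (data.frame
#'   `lnc_id`, `chrom`, `gene_id`, `side`, `rank`, `distance`),
#'   `gene_ranks` (data.frame `gene_id`, `chrom`, `rank`, `midpoint` —
#'   coding-gene order along each chromosome), `incomplete` (lncRNA ids
#'   excluded).
#' @export
flank_context <- function(lncrnas, annotation, n_genes = 5L) {
  code <- annotation$transcripts[annotation$transcripts$biotype == "coding", ,
                                 drop = FALSE]
  if (nrow(code) == 0) stop("annotation contains no coding genes")
  span <- function(ts, ids) {
    s <- tapply(ts$exons$start, ts$exons$transcript_id, min)[ids]
    e <- tapply(ts$exons$end, ts$exons$transcript_id, max)[ids]
    cbind(s, e)
  }
  gsp <- span(annotation, code$transcript_id)
  genes <- data.frame(gene_id = code$gene_id, chrom = code$chrom,
                      start = as.integer(gsp[, 1]),
                      mid = (gsp[, 1] + gsp[, 2]) / 2,
                      stringsAsFactors = FALSE)
  genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  genes <- genes[order(genes$chrom, genes$mid, genes$start), , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                           FUN = seq_along)

  ltx <- lncrnas$transcripts
  lsp <- span(lncrnas, ltx$transcript_id)
  lmid <- (lsp[, 1] + lsp[, 2]) / 2

  ctx <- vector("list", nrow(ltx))
  incomplete <- character(0)
  by_chr <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(nrow(ltx))) {
    gi <- by_chr[[ltx$chrom[i]]]
    if (is.null(gi) || length(gi) < n_genes) {
      incomplete <- c(incomplete, ltx$transcript_id[i])
      next
    }
    d <- abs(genes$mid[gi] - lmid[i])
    ord <- order(d, genes$start[gi])[seq_len(n_genes)]
    pick <- gi[ord]
    ctx[[i]] <- data.frame(
      lnc_id = ltx$transcript_id[i],
      chrom = ltx$chrom[i],
      gene_id = genes$gene_id[pick],
      side = ifelse(genes$mid[pick] < lmid[i], "upstream", "downstream"),
      rank = seq_len(n_genes),
      distance = d[ord],
      stringsAsFactors = FALSE)
  }
  ctx <- ctx[!vapply(ctx, is.null, logical(1))]
  contexts <- if (length(ctx)) do.call(rbind, ctx)
              else data.frame(lnc_id = character(0), chrom = character(0),
                              gene_id = character(0), side = character(0),
                              rank = integer(0), distance = numeric(0))
  if (length(incomplete))
    msg(length(incomplete), " lncRNA(s) excluded: fewer than ", n_genes,
        " coding genes on their chromosome")
  structure(list(contexts = contexts,
                 gene_ranks = genes[, c("gene_id", "chrom", "rank", "mid")],
                 incomplete = incomplete),
            class = "flank_contexts")
}

#' Reciprocal-best-hit orthologs between two coding gene sets
#'
#' Both directions are screened with the package's local aligner (k-mer
#' seeded); a pair is retained when each gene is the other's unique
#' top-scoring partner. Genes with tied best partners are excluded as
#' ambiguous. A user-supplied ortholog table can be used instead of this
#' step throughout the synteny workflow.
#'
#' @param seqsA,seqsB named character vectors of coding sequences.
#' @param params an [align_params()] object (thresholding fields are
#'   ignored; only scoring and seeding are used).
#' @return data.frame `gene_a`, `gene_b`, `score`, one-to-one.
#' @export
rbh_orthologs <- function(seqsA, seqsB, params = align_params()) {
  stopifnot(length(seqsA) > 0, length(seqsB) > 0)
  if (params$min_seed_kmers > 0L) {
    cand <- .kmer_candidates(seqsA, seqsB, params$seed_k,
                             params$min_seed_kmers, params$both_strands)
  } else {
    cand <- expand.grid(qid = seq_along(seqsA), sid = seq_along(seqsB))
  }
  if (nrow(cand) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  sc <- numeric(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    seg <- local_align(seqsA[[cand$qid[r]]], seqsB[[cand$sid[r]]], params)
    sc[r] <- if (is.null(seg)) 0 else seg$score
  }
  cand$score <- sc
  cand <- cand[cand$score > 0, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  best_unique <- function(df, by) {
    top <- stats::ave(df$score, df[[by]], FUN = max)
    at_top <- df[df$score == top, , drop = FALSE]
    dup <- at_top[[by]][duplicated(at_top[[by]])]
    at_top[!(at_top[[by]] %in% dup), , drop = FALSE] # ties excluded
  }
  bestA <- best_unique(cand, "qid")
  bestB <- best_unique(cand, "sid")
  key <- paste(bestA$qid, bestA$sid)
  rec <- bestA[key %in% paste(bestB$qid, bestB$sid), , drop = FALSE]
  out <- data.frame(gene_a = names(seqsA)[rec$qid],
                    gene_b = names(seqsB)[rec$sid],
                    score = rec$score, stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Call positionally conserved lncRNA pairs (4-of-5 rule)
#'
#' For a pair (a, b) across two genomes, each of a's 5 context genes is
#' "close" when its ortholog is among b's context genes, or lies on b's
#' chromosome within `window` coding-gene ranks of b's nearest coding
#' gene. The pair is conserved when `min_close` (default 4) of the 5 are
#' close. Candidate partners are lncRNAs in B sharing at least one
#' ortholog-linked context gene; missing ortholog rows count as not-close.
#'
#' @param ctxA,ctxB `flank_contexts` for the two genomes (direction A to
#'   B).
#' @param orthologs data.frame with columns `gene_a` (genome A ids) and
#'   `gene_b` (genome B ids), one-to-one.
#' @param window rank window W (default 10 coding-gene ranks).
#' @param min_close conserved threshold (default 4 of 5).
#' @param reciprocal also require the call in the B-to-A direction.
#' @return data.frame (class `positional_calls`): `lnc_a`, `lnc_b`,
#'   `close_count`, `conserved`.
#' @export
call_positional <- function(ctxA, ctxB, orthologs, window = 10L,
                            min_close = 4L, reciprocal = FALSE) {
  calls <- .call_positional_dir(ctxA, ctxB, orthologs, window, min_close)
  if (reciprocal) {
    back <- .call_positional_dir(
      ctxB, ctxA,
      data.frame(gene_a = orthologs$gene_b, gene_b = orthologs$gene_a),
      window, min_close)
    keep <- paste(calls$lnc_a, calls$lnc_b) %in%
      paste(back$lnc_b[back$conserved], back$lnc_a[back$conserved])
    calls$conserved <- calls$conserved & keep
  }
  attr(calls, "window") <- window
  attr(calls, "min_close") <- min_close
  class(calls) <- c("positional_calls", "data.frame")
  calls
}

.call_positional_dir <- function(ctxA, ctxB, orthologs, window, min_close) {
  empty <- data.frame(lnc_a = character(0), lnc_b = character(0),
                      close_count = integer(0), conserved = logical(0))
  if (nrow(ctxA$contexts) == 0 || nrow(ctxB$contexts) == 0) return(empty)
  orth <- stats::setNames(orthologs$gene_b, orthologs$gene_a)
  cB <- ctxB$contexts
  ranksB <- ctxB$gene_ranks
  rankB <- stats::setNames(ranksB$rank, ranksB$gene_id)
  chromB <- stats::setNames(ranksB$chrom, ranksB$gene_id)
  # b's own anchor: its nearest coding gene (context rank 1)
  anchorB <- cB[cB$rank == 1L, c("lnc_id", "gene_id", "chrom")]
  ctx_genes_B <- split(cB$gene_id, cB$lnc_id)
  # lncRNAs in B indexed by context gene for candidate lookup
  b_by_gene <- split(cB$lnc_id, cB$gene_id)

  rows <- list()
  for (a_id in unique(ctxA$contexts$lnc_id)) {
    genes_a <- ctxA$contexts$gene_id[ctxA$contexts$lnc_id == a_id]
    ortho_a <- unname(orth[genes_a]) # NA where unmapped
    cand_b <- unique(unlist(b_by_gene[stats::na.omit(ortho_a)],
                            use.names = FALSE))
    for (b_id in cand_b) {
      anchor <- anchorB[anchorB$lnc_id == b_id, , drop = FALSE]
      b_rank <- rankB[[anchor$gene_id[1]]]
      b_chrom <- anchor$chrom[1]
      in_ctx <- ortho_a %in% ctx_genes_B[[b_id]]
      in_win <- !is.na(ortho_a) &
        chromB[ortho_a] == b_chrom &
        abs(rankB[ortho_a] - b_rank) <= window
      in_win[is.na(in_win)] <- FALSE
      cc <- sum(in_ctx | in_win)
      rows[[length(rows) + 1L]] <- data.frame(
        lnc_a = a_id, lnc_b = b_id, close_count = cc,
        conserved = cc >= min_close, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$lnc_a, out$lnc_b), , drop = FALSE]
}

#' Intersect pairwise positional calls into triple-conserved matches
#'
#' A triple (w, a, b) is emitted when all three pairwise calls among its
#' members are conserved: w-a, w-b and a-b.
#'
#' @param calls_wa,calls_wb,calls_ab `positional_calls` for the three
#'   genome pairs, oriented as the argument names indicate.
#' @return data.frame `lnc_w`, `lnc_a`, `lnc_b`, one row per conserved
#'   triple.
#' @export
intersect_triples <- function(calls_wa, calls_wb, calls_ab) {
  wa <- calls_wa[calls_wa$conserved, , drop = FALSE]
  wb <- calls_wb[calls_wb$conserved, , drop = FALSE]
  ab <- calls_ab[calls_ab$conserved, , drop = FALSE]
  if (!nrow(wa) || !nrow(wb) || !nrow(ab))
    return(data.frame(lnc_w = character(0), lnc_a = character(0),
                      lnc_b = character(0)))
  m1 <- merge(data.frame(lnc_w = wa$lnc_a, lnc_a = wa$lnc_b),
              data.frame(lnc_w = wb$lnc_a, lnc_b = wb$lnc_b), by = "lnc_w")
  if (!nrow(m1))
    return(data.frame(lnc_w = character(0), lnc_a = character(0),
                      lnc_b = character(0)))
  key_ab <- paste(ab$lnc_a, ab$lnc_b)
  out <- m1[paste(m1$lnc_a, m1$lnc_b) %in% key_ab, , drop = FALSE]
  out <- out[order(out$lnc_w, out$lnc_a, out$lnc_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shuffle coding-gene order on each chromosome (negative control)
#'
#' Permutes the genomic positions of the coding genes within each
#' chromosome while leaving lncRNAs in place, destroying collinearity.
#' Used as the negative control for positional-conservation calling.
#'
#' @param annotation a `transcript_set`.
#' @return a `transcript_set` with coding-gene spans permuted.
#' @export
shuffle_gene_order <- function(annotation) {
  tx <- annotation$transcripts
  ex <- annotation$exons
  code_ids <- tx$transcript_id[tx$biotype == "coding"]
  for (chr in unique(tx$chrom[tx$transcript_id %in% code_ids])) {
    ids <- tx$transcript_id[tx$biotype == "coding" & tx$chrom == chr]
    if (length(ids) < 2) next
    perm <- sample(ids)
    starts <- vapply(ids, function(i) min(ex$start[ex$transcript_id == i]),
                     numeric(1))
    new_start <- stats::setNames(starts[match(perm, ids)], ids)
    for (i in ids) {
      sel <- ex$transcript_id == i
      off <- as.integer(new_start[[i]] - min(ex$start[sel]))
      ex$start[sel] <- ex$start[sel] + off
      ex$end[sel] <- ex$end[sel] + off
    }
  }
  transcript_set(ex, meta = tx[, c("transcript_id", "gene_id", "biotype")],
                 genome = tx$genome[1])
}
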