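# Sequence-conservation screen between lncRNA sets: all-vs-all local
# alignment with a k-mer seeding prefilter, strict length/identity
# filtering, conserved-family construction and TE-like multi-copy flagging.

# k-mer seeding: candidate pairs are those sharing at least `min_seed_kmers`
# distinct k-mers (either strand). Homologs above the 90% identity screen
# retain many exact 11-mers, while unrelated transcript pairs rarely share
# three, so seeding prunes the quadratic alignment burden without touching
# pairs the screen could pass.
.kmer_candidates <- function(seqsA, seqsB, k, min_hits, both_strands) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  dtA <- data.table::rbindlist(lapply(seq_along(seqsA), function(i) {
    data.table::data.table(kmer = kmers(seqsA[[i]]), qid = i)
  }))
  seqsB2 <- seqsB
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqsB)))
    seqsB2 <- paste0(seqsB, "N", rc) # N separator blocks chimeric k-mers
  }
  dtB <- data.table::rbindlist(lapply(seq_along(seqsB2), function(j) {
    data.table::data.table(kmer = kmers(seqsB2[[j]]), sid = j)
  }))
  if (nrow(dtA) == 0 || nrow(dtB) == 0)
    return(data.frame(qid = integer(0), sid = integer(0)))
  dtA <- dtA[!grepl("N", kmer, fixed = TRUE)]
  dtB <- dtB[!grepl("N", kmer, fixed = TRUE)]
  hits <- merge(dtA, dtB, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(qid = integer(0), sid = integer(0)))
  counts <- hits[, .N, by = .(qid, sid)]
  as.data.frame(counts[N >= min_hits, .(qid, sid)])
}

#' Screen two lncRNA sets for homologous segments
#'
#' Every candidate pair (after k-mer seeding, see [align_params()]) is
#' locally aligned on both strands; segments are retained only when their
#' aligned length strictly exceeds `min_segment_length` columns and their
#' percent identity strictly exceeds `min_identity` (defaults: > 100
#' columns, > 90%).
#'
#' @param seqsA,seqsB named character vectors of transcript sequences.
#' @param params an [align_params()] object.
#' @param genomeA,genomeB genome labels recorded on each segment.
#' @return data.frame with one row per retained segment: `query_id`,
#'   `query_genome`, `subject_id`, `subject_genome`, plus all
#'   [local_align()] columns.
#' @export
screen_homologs <- function(seqsA, seqsB, params = align_params(),
                            genomeA = "A", genomeB = "B") {
  stopifnot(length(seqsA) > 0, length(seqsB) > 0,
            !is.null(names(seqsA)), !is.null(names(seqsB)))
  if (params$min_seed_kmers > 0L) {
    cand <- .kmer_candidates(seqsA, seqsB, params$seed_k,
                             params$min_seed_kmers, params$both_strands)
  } else {
    cand <- expand.grid(qid = seq_along(seqsA), sid = seq_along(seqsB))
  }
  cand <- cand[order(cand$qid, cand$sid), , drop = FALSE]
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$qid[r]; j <- cand$sid[r]
    seg <- local_align(seqsA[[i]], seqsB[[j]], params)
    if (is.null(seg)) next
    if (seg$aligned_length > params$min_segment_length &&
        seg$identity_pct > params$min_identity) {
      seg$query_id <- names(seqsA)[i]
      seg$query_genome <- genomeA
      seg$subject_id <- names(seqsB)[j]
      seg$subject_genome <- genomeB
      rows[[r]] <- seg
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  front <- c("query_id", "query_genome", "subject_id", "subject_genome")
  if (!length(rows)) {
    out <- data.frame(query_id = character(0), query_genome = character(0),
                      subject_id = character(0), subject_genome = character(0),
                      score = numeric(0), query_start = integer(0),
                      query_end = integer(0), subject_start = integer(0),
                      subject_end = integer(0), strand = character(0),
                      aligned_length = integer(0), identities = integer(0),
                      identity_pct = numeric(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c(front, setdiff(names(out), front))]
}

#' Build conserved lncRNA families from pairwise homology segments
#'
#' Transcripts are nodes; every retained segment is an undirected link.
#' Families are the connected components of this graph. A family is
#' `three_way` when it has at least one member in each of the supplied
#' genomes; the sequence-conserved output of the trio workflow keeps only
#' three-way families.
#'
#' @param segments data.frame of segments from [screen_homologs()]
#'   (typically the three pairwise screens row-bound together).
#' @param genomes character vector of all genome labels in the analysis
#'   (order fixes the copy-profile column order).
#' @return list of class `conserved_families`: `families` data.frame
#'   (`family_id`, `n_members`, one `copies_<genome>` column per genome,
#'   `three_way`), and `members` data.frame (`family_id`, `transcript_id`,
#'   `genome`).
#' @export
build_families <- function(segments, genomes) {
  if (nrow(segments) == 0) {
    fam <- data.frame(family_id = character(0), n_members = integer(0))
    for (g in genomes) fam[[paste0("copies_", g)]] <- integer(0)
    fam$three_way <- logical(0)
    return(structure(list(families = fam,
                          members = data.frame(family_id = character(0),
                                               transcript_id = character(0),
                                               genome = character(0))),
                     class = "conserved_families"))
  }
  nodes <- unique(data.frame(
    transcript_id = c(segments$query_id, segments$subject_id),
    genome = c(segments$query_genome, segments$subject_genome),
    stringsAsFactors = FALSE))
  key <- paste(nodes$genome, nodes$transcript_id, sep = "\r")
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste(segments$query_genome, segments$query_id, sep = "\r"),
               to = paste(segments$subject_genome, segments$subject_id, sep = "\r")),
    directed = FALSE,
    vertices = data.frame(name = key))
  comp <- igraph::components(g)$membership
  members <- data.frame(
    family_id = sprintf("FAM%04d", comp[key]),
    transcript_id = nodes$transcript_id,
    genome = nodes$genome,
    stringsAsFactors = FALSE)
  members <- members[order(members$family_id, members$genome,
                           members$transcript_id), , drop = FALSE]
  rownames(members) <- NULL
  ids <- sort(unique(members$family_id))
  fam <- data.frame(family_id = ids,
                    n_members = as.integer(table(members$family_id)[ids]))
  for (gname in genomes) {
    cnt <- table(members$family_id[members$genome == gname])
    fam[[paste0("copies_", gname)]] <- as.integer(ifelse(
      ids %in% names(cnt), cnt[ids], 0L))
  }
  prof <- as.matrix(fam[, paste0("copies_", genomes), drop = FALSE])
  fam$three_way <- rowSums(prof > 0) == length(genomes)
  rownames(fam) <- NULL
  structure(list(families = fam, members = members),
            class = "conserved_families")
}

#' @export
print.conserved_families <- function(x, ...) {
  cat("conserved_families: ", nrow(x$families), " families, ",
      nrow(x$members), " member transcripts (",
      sum(x$families$three_way), " three-way)\n", sep = "")
  invisible(x)
}

#' Flag transposable-element-like multi-copy families
#'
#' A family is flagged TE-like when any single genome contributes at least
#' `threshold` member copies — the signature of a multi-copy repeat family
#' that is widely present in one genome but contracted in the others. The
#' contraction ratio relates the first (wild/progenitor) genome's copy
#' count to the best cultivar copy count.
#'
#' @param families a `conserved_families` object.
#' @param genomes genome labels (first label treated as the progenitor for
#'   the contraction ratio).
#' @param threshold minimum per-genome copy count to flag (default 5).
#' @return the `families` data.frame with `te_like` and
#'   `contraction_ratio` columns added.
#' @export
flag_multicopy <- function(families, genomes, threshold = 5) {
  fam <- families$families
  prof <- as.matrix(fam[, paste0("copies_", genomes), drop = FALSE])
  fam$te_like <- apply(prof, 1, function(p) any(p >= threshold))
  if (length(genomes) >= 2) {
    cultivar_max <- apply(prof[, -1, drop = FALSE], 1, max)
    fam$contraction_ratio <- ifelse(cultivar_max > 0,
                                    prof[, 1] / cultivar_max, NA_real_)
  }
  fam
}
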