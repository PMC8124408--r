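#' Construct a set of transcript models
#'
#' The central container of the pipeline: a stranded, exon-structured
#' transcript on a named chromosome of a named genome. Coordinates are
#' 1-based inclusive throughout (GFF3 convention), so a single-exon
#' transcript spanning 3,117,854..3,119,120 has spliced length 1267 nt.
#' Transcript length always means spliced length (sum of exon lengths),
#' never genomic span.
#'
#' Exons arriving unsorted or overlapping within a transcript are repaired
#' by sorting and merging, with a warning. Invalid coordinates (start > end,
#' non-positive) and unknown strands are hard errors.
#'
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand` (one row per exon).
#' @param meta optional data.frame keyed by `transcript_id` with any of
#'   `gene_id`, `biotype` (one of `"coding"`, `"lnc_candidate"`,
#'   `"lncRNA"`).
#' @param genome genome label (short string), recorded on every transcript.
#' @return An object of class `transcript_set`: a list with a `transcripts`
#'   data.frame (`transcript_id`, `gene_id`, `genome`, `chrom`, `strand`,
#'   `biotype`, `length`, `exon_count`) and an `exons` data.frame.
#' @export
transcript_set <- function(exons, meta = NULL, genome = "genome") {
  stopifnot(is.data.frame(exons),
            all(c("transcript_id", "chrom", "start", "end", "strand")
                %in% names(exons)))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  bad <- which(is.na(exons$start) | is.na(exons$end) |
                 exons$start < 1L | exons$end < exons$start)
  if (length(bad))
    stop("invalid exon coordinates (start > end or non-positive) for ",
         "transcript(s): ",
         paste(unique(exons$transcript_id[bad]), collapse = ", "))
  if (!all(exons$strand %in% c("+", "-")))
    stop("unknown strand value(s): ",
         paste(unique(setdiff(exons$strand, c("+", "-"))), collapse = ", "))

  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ,
                 drop = FALSE]
  # merge overlapping/touching exons within a transcript
  repaired <- FALSE
  ex_split <- split(seq_len(nrow(exons)), exons$transcript_id)
  keep <- logical(nrow(exons))
  for (idx in ex_split) {
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    s <- exons$start[idx]; e <- exons$end[idx]
    cur <- 1L; keep[idx[1L]] <- TRUE
    for (k in 2L:length(idx)) {
      if (s[k] <= exons$end[idx[cur]]) { # overlap: extend current
        exons$end[idx[cur]] <- max(exons$end[idx[cur]], e[k])
        repaired <- TRUE
      } else {
        cur <- k; keep[idx[k]] <- TRUE
      }
    }
  }
  if (repaired)
    warning("overlapping exons merged during import")
  exons <- exons[keep, , drop = FALSE]
  rownames(exons) <- NULL

  len <- tapply(exons$end - exons$start + 1L, exons$transcript_id, sum)
  nex <- tapply(exons$transcript_id, exons$transcript_id, length)
  ids <- names(len)
  tx <- data.frame(
    transcript_id = ids,
    gene_id = ids,
    genome = genome,
    chrom = exons$chrom[match(ids, exons$transcript_id)],
    strand = exons$strand[match(ids, exons$transcript_id)],
    biotype = "lnc_candidate",
    length = as.integer(len),
    exon_count = as.integer(nex),
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) {
    m <- match(tx$transcript_id, meta$transcript_id)
    if ("gene_id" %in% names(meta)) {
      hit <- !is.na(m) & !is.na(meta$gene_id[m])
      tx$gene_id[hit] <- meta$gene_id[m[hit]]
    }
    if ("biotype" %in% names(meta)) {
      hit <- !is.na(m) & !is.na(meta$biotype[m])
      tx$biotype[hit] <- meta$biotype[m[hit]]
    }
  }
  rownames(tx) <- NULL
  structure(list(transcripts = tx, exons = exons),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  tx <- x$transcripts
  cat("transcript_set: ", nrow(tx), " transcripts (",
      sum(tx$biotype == "coding"), " coding) on genome '",
      tx$genome[1] %||% "?", "'\n", sep = "")
  invisible(x)
}

#' @export
length.transcript_set <- function(x) nrow(x$transcripts)

#' Subset a transcript set by transcript identifier
#'
#' @param ts a `transcript_set`.
#' @param ids character vector of transcript identifiers to keep.
#' @return a `transcript_set` restricted to `ids`.
#' @export
subset_transcripts <- function(ts, ids) {
  structure(list(
    transcripts = ts$transcripts[ts$transcripts$transcript_id %in% ids, ,
                                 drop = FALSE],
    exons = ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE]
  ), class = "transcript_set")
}

#' Spliced transcript lengths
#'
#' @param ts a `transcript_set`.
#' @return named integer vector of spliced lengths (nt), one per transcript.
#' @export
transcript_length <- function(ts) {
  stats::setNames(ts$transcripts$length, ts$transcripts$transcript_id)
}

#' Read a transcript annotation (GFF3 or GTF)
#'
#' Parses with \pkg{rtracklayer}; exon features are grouped into transcripts
#' by `transcript_id` (GTF) or `Parent`/`ID` (GFF3). Transcript biotype is
#' taken from a `biotype`, `transcript_biotype` or `gene_biotype` attribute
#' when present (`protein_coding`/`mRNA` map to `"coding"`, values
#' containing `lnc` to `"lncRNA"`); otherwise transcripts are imported as
#' `"lnc_candidate"`. Malformed coordinates or strands are hard errors that
#' name the offending line.
#'
#' @param path GFF3 or GTF file.
#' @param genome genome label recorded on every transcript.
#' @return a [transcript_set()].
#' @export
read_annotation <- function(path, genome = "genome") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  # pre-scan: name the offending line for malformed records, which the
  # general-purpose importer would report less helpfully
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  lineno <- which(body)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 8L) next
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s < 1L || e < s)
      stop("malformed coordinates at line ", lineno[k], " of ", path,
           " (start=", f[4], ", end=", f[5], ")")
    if (!f[7] %in% c("+", "-"))
      stop("unknown strand '", f[7], "' at line ", lineno[k], " of ", path)
  }
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  is_exon <- !is.na(md$type) & tolower(as.character(md$type)) == "exon"
  if (!any(is_exon)) stop("no exon features found in ", path)
  ex <- gr[is_exon]
  exmd <- S4Vectors::mcols(ex)
  txid <- if (!is.null(exmd$transcript_id)) as.character(exmd$transcript_id)
          else if (!is.null(exmd$Parent)) as.character(unlist(exmd$Parent))
          else as.character(exmd$ID)
  if (anyNA(txid)) stop("exon features without a transcript identifier in ", path)
  exons <- data.frame(
    transcript_id = txid,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE
  )

  # transcript-level metadata
  meta <- NULL
  is_tx <- !is.na(md$type) &
    tolower(as.character(md$type)) %in% c("transcript", "mrna", "lnc_rna", "lncrna")
  if (any(is_tx)) {
    txmd <- S4Vectors::mcols(gr[is_tx])
    tid <- if (!is.null(txmd$ID) && !all(is.na(txmd$ID))) as.character(txmd$ID)
           else as.character(txmd$transcript_id)
    gid <- if (!is.null(txmd$Parent) && length(txmd$Parent))
             vapply(as.list(txmd$Parent),
                    function(p) if (length(p)) as.character(p[1]) else NA_character_,
                    character(1))
           else if (!is.null(txmd$gene_id)) as.character(txmd$gene_id)
           else NA_character_
    bt <- rep(NA_character_, length(tid))
    for (attr in c("biotype", "transcript_biotype", "gene_biotype")) {
      if (!is.null(txmd[[attr]])) {
        v <- as.character(txmd[[attr]])
        bt[is.na(bt) & !is.na(v)] <- v[is.na(bt) & !is.na(v)]
      }
    }
    bt_norm <- ifelse(is.na(bt), NA_character_,
                      ifelse(bt %in% c("protein_coding", "mRNA", "coding"), "coding",
                             ifelse(grepl("lnc", bt, ignore.case = TRUE), "lncRNA",
                                    "lnc_candidate")))
    meta <- data.frame(transcript_id = tid, gene_id = gid, biotype = bt_norm,
                       stringsAsFactors = FALSE)
  }
  transcript_set(exons, meta = meta, genome = genome)
}

#' Write a transcript set as GFF3
#'
#' @param ts a `transcript_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ts, path) {
  tx <- ts$transcripts
  esc <- function(x) gsub("[;=,\t]", "_", x)
  span_s <- tapply(ts$exons$start, ts$exons$transcript_id, min)[tx$transcript_id]
  span_e <- tapply(ts$exons$end, ts$exons$transcript_id, max)[tx$transcript_id]
  tx_lines <- sprintf("%s\toryzalnc\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;biotype=%s",
                      tx$chrom, as.integer(span_s), as.integer(span_e),
                      tx$strand, esc(tx$transcript_id), esc(tx$gene_id),
                      tx$biotype)
  ex <- ts$exons
  ex_lines <- sprintf("%s\toryzalnc\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                      ex$chrom, ex$start, ex$end, ex$strand,
                      esc(ex$transcript_id))
  ord <- order(c(tx$chrom, ex$chrom),
               c(as.integer(span_s), ex$start),
               c(rep(0L, nrow(tx)), rep(1L, nrow(ex))))
  writeLines(c("##gff-version 3", c(tx_lines, ex_lines)[ord]), path)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over \pkg{Biostrings} that uppercase-normalise sequences
#' (N allowed) and reject duplicate identifiers.
#'
#' @param path FASTA file.
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ds <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ds))
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(ds)), ids)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifiers")
  ds <- Biostrings::DNAStringSet(toupper(seqs))
  names(ds) <- names(seqs)
  Biostrings::writeXStringSet(ds, path, width = 70L)
  invisible(path)
}

#' Read / write a TSV table with header
#'
#' @param path TSV file.
#' @return `read_table`: a data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_table
#' @param x data.frame.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export transcript spans as BED6
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention at this boundary.
#'
#' @param ts a `transcript_set`.
#' @param path output file.
#' @export
write_bed <- function(ts, path) {
  tx <- ts$transcripts
  span_s <- tapply(ts$exons$start, ts$exons$transcript_id, min)[tx$transcript_id]
  span_e <- tapply(ts$exons$end, ts$exons$transcript_id, max)[tx$transcript_id]
  bed <- data.frame(chrom = tx$chrom,
                    start = as.integer(span_s) - 1L,
                    end = as.integer(span_e),
                    name = tx$transcript_id,
                    score = 0L,
                    strand = tx$strand)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export conserved matches as a Circos-style link file
#'
#' One record per match, giving the two genomic intervals it connects.
#' An empty match set yields a header-only file; n matches yield exactly n
#' link records.
#'
#' @param matches data.frame with columns `genome_a`, `chrom_a`, `start_a`,
#'   `end_a`, `genome_b`, `chrom_b`, `start_b`, `end_b` (extra columns are
#'   carried through).
#' @param path output file.
#' @export
write_links <- function(matches, path) {
  cols <- c("genome_a", "chrom_a", "start_a", "end_a",
            "genome_b", "chrom_b", "start_b", "end_b")
  if (nrow(matches) == 0) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  stopifnot(all(cols %in% names(matches)))
  extra <- setdiff(names(matches), cols)
  utils::write.table(matches[, c(cols, extra), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a link file written by [write_links()]
#' @param path link file.
#' @return data.frame of link records (possibly zero rows).
#' @export
read_links <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Extract spliced transcript sequences from genome sequences
#'
#' Exon sequences are concatenated in genomic order and reverse-complemented
#' for minus-strand transcripts.
#'
#' @param genome_seqs named character vector of chromosome sequences (as
#'   from [read_fasta()]).
#' @param ts a `transcript_set`.
#' @return named character vector of spliced transcript sequences.
#' @export
extract_transcript_seqs <- function(genome_seqs, ts) {
  ex <- ts$exons
  missing_chr <- setdiff(unique(ex$chrom), names(genome_seqs))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome FASTA: ",
         paste(missing_chr, collapse = ", "))
  pieces <- substring(genome_seqs[ex$chrom], ex$start, ex$end)
  spliced <- vapply(split(pieces, ex$transcript_id), paste0, character(1),
                    collapse = "")
  # splits are alphabetical; exons were sorted by start within transcript
  tx <- ts$transcripts
  out <- spliced[tx$transcript_id]
  neg <- tx$strand == "-"
  if (any(neg))
    out[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[neg])))
  stats::setNames(out, tx$transcript_id)
}
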