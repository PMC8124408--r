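test_that("spliced length uses 1-based inclusive coordinates", {
  ts <- transcript_set(data.frame(
    transcript_id = "MSTRG.19480", chrom = "chr8",
    start = 3117854, end = 3119120, strand = "+"))
  expect_equal(unname(transcript_length(ts)), 1267)
  expect_equal(ts$transcripts$exon_count, 1L)

  one <- transcript_set(data.frame(transcript_id = "t", chrom = "c",
                                   start = 5, end = 5, strand = "+"))
  expect_equal(unname(transcript_length(one)), 1)

  two <- transcript_set(data.frame(transcript_id = rep("t", 2), chrom = "c",
                                   start = c(1, 21), end = c(10, 30),
                                   strand = "+"))
  expect_equal(unname(transcript_length(two)), 20)
  expect_equal(two$transcripts$exon_count, 2L)
})

test_that("spliced length matches per-base enumeration on random exon sets", {
  set.seed(41)
  for (k in 1:25) {
    n_ex <- sample(1:6, 1)
    starts <- sort(sample(1:5000, n_ex)) * 100
    ends <- starts + sample(1:90, n_ex, replace = TRUE)
    ts <- transcript_set(data.frame(transcript_id = "t", chrom = "c",
                                    start = starts, end = ends,
                                    strand = "-"))
    expect_equal(unname(transcript_length(ts)),
                 length_by_enumeration(starts, ends))
  }
})

test_that("constructor repairs exon order/overlap and rejects bad records", {
  expect_warning(
    ts <- transcript_set(data.frame(transcript_id = rep("t", 3), chrom = "c",
                                    start = c(100, 1, 50), end = c(200, 60, 120),
                                    strand = "+")),
    "merged")
  expect_equal(ts$transcripts$exon_count, 1L)
  expect_equal(unname(transcript_length(ts)), 200)

  expect_error(transcript_set(data.frame(transcript_id = "t", chrom = "c",
                                         start = 10, end = 5, strand = "+")),
               "invalid exon")
  expect_error(transcript_set(data.frame(transcript_id = "t", chrom = "c",
                                         start = 1, end = 5, strand = ".")),
               "strand")
})

test_that("annotation reader handles GFF3 and GTF and names bad lines", {
  d <- withr::local_tempdir()
  gff <- file.path(d, "x.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr8\tsrc\ttranscript\t3117854\t3119120\t.\t+\t.\tID=tx1;Parent=g1;biotype=lncRNA",
    "chr8\tsrc\texon\t3117854\t3119120\t.\t+\t.\tParent=tx1"), gff)
  ts <- read_annotation(gff, genome = "g")
  expect_equal(unname(transcript_length(ts)), 1267)
  expect_equal(ts$transcripts$biotype, "lncRNA")
  expect_equal(ts$transcripts$gene_id, "g1")

  gtf <- file.path(d, "x.gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t1\t10\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tsrc\texon\t21\t30\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";')), gtf)
  ts2 <- read_annotation(gtf, genome = "g")
  expect_equal(unname(transcript_length(ts2)), 20)
  expect_equal(ts2$transcripts$exon_count, 2L)

  bad <- file.path(d, "bad.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\texon\t50\t10\t.\t+\t.\tParent=t1"), bad)
  expect_error(read_annotation(bad), "line 2")
  bad2 <- file.path(d, "bad2.gff3")
  writeLines(c("chr1\tsrc\texon\t5\t10\t.\t?\t.\tParent=t1"), bad2)
  expect_error(read_annotation(bad2), "strand")
})

test_that("GFF3 writer round-trips a transcript set", {
  b <- std_trio()
  ts <- b$annotations[[1]]
  d <- withr::local_tempdir()
  p <- write_gff3(ts, file.path(d, "rt.gff3"))
  back <- read_annotation(p, genome = ts$transcripts$genome[1])
  expect_setequal(back$transcripts$transcript_id,
                  ts$transcripts$transcript_id)
  m <- match(ts$transcripts$transcript_id, back$transcripts$transcript_id)
  expect_equal(back$transcripts$length[m], ts$transcripts$length)
  expect_equal(back$transcripts$exon_count[m], ts$transcripts$exon_count)
  expect_equal(back$transcripts$biotype[m] == "coding",
               ts$transcripts$biotype == "coding")
})

test_that("FASTA and TSV round-trip; duplicate FASTA ids rejected", {
  d <- withr::local_tempdir()
  set.seed(7)
  seqs <- setNames(vapply(c(80, 200, 35), rand_dna, character(1)),
                   c("s1", "s2", "s3"))
  p <- write_fasta(seqs, file.path(d, "x.fa"))
  expect_identical(read_fasta(p), seqs)
  expect_error(write_fasta(setNames(seqs, c("a", "a", "b")), file.path(d, "y.fa")),
               "duplicate")

  df <- data.frame(id = c("a", "b"), x = c(1.5, -2), s = c("u", "v"),
                   stringsAsFactors = FALSE)
  p2 <- write_table(df, file.path(d, "x.tsv"))
  expect_equal(read_table(p2), df)
})

test_that("link export writes one record per match and a header-only empty file", {
  d <- withr::local_tempdir()
  empty <- data.frame()
  p <- write_links(empty, file.path(d, "empty.links"))
  expect_length(readLines(p), 1L)
  expect_equal(nrow(read_links(p)), 0L)

  set.seed(8)
  n <- 633
  m <- data.frame(genome_a = "w", chrom_a = "chr1",
                  start_a = 1:n, end_a = 1:n + 99,
                  genome_b = "j", chrom_b = "chr2",
                  start_b = 1:n + 5, end_b = 1:n + 104)
  p2 <- write_links(m, file.path(d, "m.links"))
  back <- read_links(p2)
  expect_equal(nrow(back), n)
  expect_equal(back, m)
})

test_that("BED export converts to 0-based half-open", {
  ts <- transcript_set(data.frame(transcript_id = "t", chrom = "c",
                                  start = 101, end = 200, strand = "-"))
  d <- withr::local_tempdir()
  p <- write_bed(ts, file.path(d, "x.bed"))
  bed <- utils::read.delim(p, header = FALSE)
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 200)
  expect_equal(bed$V3 - bed$V2, 100) # interval width preserved
  expect_equal(bed$V6, "-")
})

test_that("transcript sequence extraction splices and reverse-complements", {
  chrom <- "AAACCCGGGTTTACGTACGT"
  # plus strand, two exons 4..6 and 10..12 -> CCC + TTT
  ts <- transcript_set(data.frame(transcript_id = rep("p", 2), chrom = "c1",
                                  start = c(4, 10), end = c(6, 12),
                                  strand = "+"))
  expect_equal(unname(extract_transcript_seqs(c(c1 = chrom), ts)), "CCCTTT")
  # minus strand single exon 1..6 = AAACCC -> revcomp GGGTTT
  tsm <- transcript_set(data.frame(transcript_id = "m", chrom = "c1",
                                   start = 1, end = 6, strand = "-"))
  expect_equal(unname(extract_transcript_seqs(c(c1 = chrom), tsm)), "GGGTTT")
  expect_error(extract_transcript_seqs(c(other = chrom), tsm), "absent")
})
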