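test_that("flank context picks the 5 nearest coding genes, mixed sides", {
  ann <- toy_genome("g", n_genes = 30, lnc_after = 10)
  lnc <- subset_transcripts(ann, "g_lnc")
  ctx <- flank_context(lnc, ann)
  cc <- ctx$contexts
  expect_equal(nrow(cc), 5)
  # lncRNA sits between genes 10 and 11: nearest five are 9..13-ish
  expect_setequal(cc$gene_id, sprintf("g_g%02d", c(9, 10, 11, 12, 8)))
  expect_equal(sort(table(cc$side), decreasing = TRUE)[[1]] +
                 sort(table(cc$side))[[1]], 5)
})

test_that("chromosome-end contexts take the nearest five from one side", {
  ann <- toy_genome("g", n_genes = 12, lnc_after = 2)
  lnc <- subset_transcripts(ann, "g_lnc")
  cc <- flank_context(lnc, ann)$contexts
  expect_equal(sum(cc$side == "upstream"), 2)
  expect_equal(sum(cc$side == "downstream"), 3)
})

test_that("contexts equal a brute-force distance sort on random layouts", {
  set.seed(71)
  for (k in 1:8) {
    n <- sample(8:40, 1)
    starts <- sort(sample(seq(1, 1e6, by = 100), n))
    ex <- data.frame(transcript_id = sprintf("g%03d", 1:n), chrom = "c",
                     start = starts, end = starts + 500, strand = "+")
    lpos <- sample(1e6, 1)
    ex <- rbind(ex, data.frame(transcript_id = "lnc", chrom = "c",
                               start = lpos, end = lpos + 300, strand = "+"))
    ann <- transcript_set(ex, meta = data.frame(
      transcript_id = ex$transcript_id,
      biotype = c(rep("coding", n), "lnc_candidate")), genome = "g")
    cc <- flank_context(subset_transcripts(ann, "lnc"), ann)$contexts
    mids <- starts + 250
    lmid <- lpos + 150
    want <- sprintf("g%03d", order(abs(mids - lmid), starts)[1:5])
    expect_setequal(cc$gene_id, want)
  }
})

test_that("incomplete contexts (fewer than 5 coding genes) are excluded", {
  ann <- toy_genome("g", n_genes = 4, lnc_after = 2)
  lnc <- subset_transcripts(ann, "g_lnc")
  expect_message(ctx <- flank_context(lnc, ann), "excluded")
  expect_equal(nrow(ctx$contexts), 0)
  expect_equal(ctx$incomplete, "g_lnc")
})

test_that("the 4-of-5 boundary decides positional conservation", {
  # two toy genomes with identical gene order and a 1:1 ortholog map
  annA <- toy_genome("A", n_genes = 30, lnc_after = 10)
  annB <- toy_genome("B", n_genes = 30, lnc_after = 10)
  ctxA <- flank_context(subset_transcripts(annA, "A_lnc"), annA)
  ctxB <- flank_context(subset_transcripts(annB, "B_lnc"), annB)
  orth_full <- data.frame(gene_a = sprintf("A_g%02d", 1:30),
                          gene_b = sprintf("B_g%02d", 1:30))
  # all 5 orthologs in context: close_count 5
  calls <- call_positional(ctxA, ctxB, orth_full)
  expect_equal(calls$close_count, 5)
  expect_true(calls$conserved)

  drop_k <- function(k) {
    # remove ortholog rows for k of A's context genes AND displace them
    # beyond any rank window by pointing them at a fake far gene
    ctx_genes <- ctxA$contexts$gene_id[1:k]
    orth_full[!(orth_full$gene_a %in% ctx_genes), ]
  }
  c4 <- call_positional(ctxA, ctxB, drop_k(1))
  expect_equal(c4$close_count, 4)
  expect_true(c4$conserved)
  c3 <- call_positional(ctxA, ctxB, drop_k(2))
  expect_equal(c3$close_count, 3)
  expect_false(c3$conserved)
})

test_that("close_count is monotone nonincreasing as the window shrinks", {
  b <- std_trio()
  pos <- trio_positional(b)
  g <- b$config$genomes
  orth <- b$truth$orthologs
  o <- orth[orth$genome_a == g[1] & orth$genome_b == g[2], ]
  prev <- NULL
  for (W in c(20, 10, 5, 2, 0)) {
    cl <- call_positional(pos$ctx[[g[1]]], pos$ctx[[g[2]]], o, window = W)
    key <- paste(cl$lnc_a, cl$lnc_b)
    if (!is.null(prev)) {
      common <- intersect(key, prev$key)
      expect_true(all(cl$close_count[match(common, key)] <=
                        prev$cc[match(common, prev$key)]))
    }
    prev <- list(key = key, cc = cl$close_count)
  }
})

test_that("RBH orthologs: identity map on identical sets, ties excluded", {
  set.seed(72)
  genes <- setNames(vapply(rep(600, 8), rand_dna, character(1)),
                    sprintf("G%02d", 1:8))
  m <- rbh_orthologs(genes, genes)
  expect_equal(nrow(m), 8)
  expect_equal(m$gene_a, m$gene_b)

  # a duplicated subject sequence makes its best hit ambiguous
  dup <- c(genes, setNames(genes["G01"], "G01copy"))
  m2 <- rbh_orthologs(genes, dup)
  expect_false("G01" %in% m2$gene_a)
  expect_equal(nrow(m2), 7)
})

test_that("RBH recovers planted ortholog truth from mutated sequences", {
  set.seed(73)
  anc <- vapply(rep(800, 10), rand_dna, character(1))
  a <- setNames(vapply(anc, function(s) oryzalnc:::.mutate_seq(s, 0.025),
                       character(1)), sprintf("A%02d", 1:10))
  b <- setNames(vapply(anc, function(s) oryzalnc:::.mutate_seq(s, 0.025),
                       character(1)), sprintf("B%02d", 1:10))
  m <- rbh_orthologs(a, b)
  expect_equal(nrow(m), 10)
  expect_equal(sub("A", "", m$gene_a), sub("B", "", m$gene_b))
})

test_that("triple intersection requires all three pairwise calls", {
  mk <- function(a, b, cons = TRUE)
    structure(data.frame(lnc_a = a, lnc_b = b, close_count = 5,
                         conserved = cons),
              class = c("positional_calls", "data.frame"))
  wa <- mk("w1", "a1"); wb <- mk("w1", "b1"); ab <- mk("a1", "b1")
  tr <- intersect_triples(wa, wb, ab)
  expect_equal(nrow(tr), 1)
  expect_equal(unlist(tr[1, ], use.names = FALSE), c("w1", "a1", "b1"))
  # missing a-b edge: no triple
  expect_equal(nrow(intersect_triples(wa, wb, mk("a9", "b9"))), 0)
  # empty input
  expect_equal(nrow(intersect_triples(mk("w", "a", FALSE), wb, ab)), 0)
})

test_that("planted pairwise counts preserve the wild-B > wild-A excess", {
  b <- std_trio()
  pos <- trio_positional(b)
  expect_gt(sum(pos$wb$conserved), sum(pos$wa$conserved))
  # triple count bounded by the smallest pairwise count
  tr <- intersect_triples(pos$wa, pos$wb, pos$ab)
  expect_lte(nrow(tr), min(sum(pos$wa$conserved), sum(pos$wb$conserved),
                           sum(pos$ab$conserved)))
})
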