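# helper: build a candidate set + expression/scores with full control
make_candidates <- function(n, seed = 1) {
  set.seed(seed)
  lens <- sample(c(50:300, 500, 1267, 5000), n, replace = TRUE)
  ex <- data.frame(transcript_id = sprintf("c%04d", 1:n), chrom = "chr1",
                   start = cumsum(rep(10000, n)),
                   end = cumsum(rep(10000, n)) + lens - 1,
                   strand = sample(c("+", "-"), n, TRUE))
  meta <- data.frame(transcript_id = ex$transcript_id,
                     biotype = sample(c("coding", "lnc_candidate"), n, TRUE,
                                      prob = c(0.3, 0.7)))
  ts <- transcript_set(ex, meta = meta, genome = "g")
  fpkm <- cbind(panicle = round(stats::rexp(n, 1 / 2), 3),
                seedling = round(stats::rexp(n, 1 / 2), 3))
  fpkm[sample(n, n %/% 5), ] <- 0.01 # some below the 0.1 gate
  rownames(fpkm) <- ex$transcript_id
  scores <- data.frame(transcript_id = ex$transcript_id,
                       cpc_score = round(stats::rnorm(n, -0.5, 1.5), 3),
                       cnci_score = round(stats::rnorm(n, -0.5, 1.5), 3))
  list(ts = ts, fpkm = fpkm, scores = scores)
}

test_that("each gate rejects exactly as specified", {
  ex <- data.frame(transcript_id = c("short", "good", "codingish", "weak"),
                   chrom = "chr1", start = c(1, 1000, 9000, 20000),
                   end = c(150, 2266, 9900, 20400), strand = "+")
  ts <- transcript_set(ex, genome = "g")
  fpkm <- matrix(c(5, 5, 5.2, 0.05, 2, 2, 2, 0.02), ncol = 2,
                 dimnames = list(c("short", "good", "codingish", "weak"),
                                 c("p", "s")))
  scores <- data.frame(transcript_id = rownames(fpkm),
                       cpc_score = c(-1, -1.2, 0.4, -1),
                       cnci_score = c(-1, -0.5, -0.2, -1))
  res <- filter_lncrnas(ts, fpkm, scores)
  aud <- res$audit
  expect_equal(aud$first_failed_filter[aud$transcript_id == "short"], "length")
  expect_equal(aud$first_failed_filter[aud$transcript_id == "good"], "none")
  expect_equal(aud$first_failed_filter[aud$transcript_id == "codingish"],
               "coding_potential")
  expect_equal(aud$first_failed_filter[aud$transcript_id == "weak"],
               "expression")
  expect_setequal(res$retained$transcripts$transcript_id, "good")
  expect_equal(res$retained$transcripts$biotype, "lncRNA")
})

test_that("missing score or expression rows are hard errors naming the id", {
  cc <- make_candidates(5)
  expect_error(filter_lncrnas(cc$ts, cc$fpkm[-2, , drop = FALSE], cc$scores),
               "c0002")
  expect_error(filter_lncrnas(cc$ts, cc$fpkm, cc$scores[-3, ]), "c0003")
})

test_that("cascade equals the unordered predicate oracle on 1000 candidates", {
  cc <- make_candidates(1000, seed = 17)
  th <- filter_thresholds()
  res <- filter_lncrnas(cc$ts, cc$fpkm, cc$scores, th)
  want <- filter_oracle(cc$ts$transcripts,
                        apply(cc$fpkm, 1, max),
                        cc$scores$cpc_score, cc$scores$cnci_score, th)
  expect_setequal(res$retained$transcripts$transcript_id, want)
  # audit completeness: every candidate exactly once
  expect_equal(sort(res$audit$transcript_id),
               sort(cc$ts$transcripts$transcript_id))
  expect_equal(sum(res$audit$verdict == "retained") +
                 sum(res$audit$verdict == "rejected"), 1000L)
})

test_that("relaxing any threshold never shrinks the retained set", {
  cc <- make_candidates(400, seed = 23)
  base <- filter_lncrnas(cc$ts, cc$fpkm, cc$scores, filter_thresholds())
  base_ids <- base$retained$transcripts$transcript_id
  relaxed <- list(filter_thresholds(min_length = 100),
                  filter_thresholds(min_fpkm = 0),
                  filter_thresholds(max_coding_score = 1))
  for (th in relaxed) {
    ids <- filter_lncrnas(cc$ts, cc$fpkm, cc$scores,
                          th)$retained$transcripts$transcript_id
    expect_true(all(base_ids %in% ids))
  }
})

test_that("known/novel classification follows same-strand exonic overlap", {
  lnc <- transcript_set(data.frame(
    transcript_id = c("L1", "L2", "L3"), chrom = "chr1",
    start = c(1000, 5000, 9000), end = c(1500, 5500, 9500),
    strand = c("+", "+", "-")), genome = "g")
  ref <- transcript_set(data.frame(
    transcript_id = c("R1", "R3"), chrom = "chr1",
    start = c(1451, 9100), end = c(2000, 9400),
    strand = c("+", "+")), genome = "g")
  known <- classify_known(lnc, ref)
  expect_true(known[["L1"]])   # 50 nt same-strand overlap
  expect_false(known[["L2"]])  # no overlap
  expect_false(known[["L3"]])  # full overlap but opposite strand

  expect_equal(sum(classify_known(lnc, NULL)), 0L)
  ref_other <- transcript_set(data.frame(
    transcript_id = "R", chrom = "scaffold_99",
    start = 1000, end = 2000, strand = "+"), genome = "g")
  expect_warning(k2 <- classify_known(lnc, ref_other), "chromosome")
  expect_equal(sum(k2), 0L)
})

test_that("summary percentages reproduce half-up two-decimal rounding", {
  expect_equal(pct(1099, 2091), 52.56)
  expect_equal(pct(628, 4072), 15.42)
  expect_equal(pct(0, 17), 0)
  b <- std_trio()
  lnc <- trio_lnc_sets(b)
  known <- lapply(names(lnc), function(g) {
    tk <- b$truth$known[b$truth$known$genome == g, ]
    setNames(tk$known, tk$transcript_id)[
      lnc[[g]]$transcripts$transcript_id]
  })
  names(known) <- names(lnc)
  s <- summarize_discovery(lnc, known)
  expect_equal(s$n_known + s$n_novel, s$n_lncrna)
  expect_equal(s$pct_known,
               round_half_up(100 * s$n_known / s$n_lncrna, 2))
})

test_that("fallback ORF scorer separates coding-like from random sequence", {
  set.seed(31)
  # ORF-rich: long ATG...stop-free stretch
  orf <- paste0("ATG", paste(rep("GCT", 150), collapse = ""), "TAA")
  coding_like <- paste0(rand_dna(20), orf, rand_dna(20))
  random_seqs <- vapply(rep(400, 10), rand_dna, character(1))
  sc <- orf_fraction_scores(c(setNames(coding_like, "cod"),
                              setNames(random_seqs, sprintf("r%02d", 1:10))))
  expect_gt(sc$cpc_score[sc$transcript_id == "cod"], 0)
  expect_gte(mean(sc$cpc_score[sc$transcript_id != "cod"] < 0), 0.7)
})
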