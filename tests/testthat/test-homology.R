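test_that("screen thresholds are strict at 100 columns and 90% identity", {
  p0 <- align_params(min_seed_kmers = 0L, both_strands = FALSE)
  set.seed(11)
  s100 <- rand_dna(100)
  # exactly 100 perfect columns: rejected by the > 100 rule
  expect_equal(nrow(screen_homologs(c(q = s100), c(s = s100), p0)), 0L)
  s101 <- rand_dna(101)
  expect_equal(nrow(screen_homologs(c(q = s101), c(s = s101), p0)), 1L)

  # 150 columns at exactly 90.0%: rejected by the > 90 rule.
  # 15 mismatches spread so clipping any flank loses score.
  base <- rand_dna(150)
  v <- strsplit(base, "")[[1]]
  pos <- seq(5, 145, by = 10)
  v[pos] <- vapply(v[pos], function(x) setdiff(c("A", "C", "G", "T"), x)[1],
                   character(1))
  mut <- paste0(v, collapse = "")
  seg <- local_align(base, mut, p0)
  expect_equal(seg$aligned_length, 150)
  expect_equal(seg$identity_pct, 90)
  expect_equal(nrow(screen_homologs(c(q = base), c(s = mut), p0)), 0L)

  # 14 mismatches (90.67%) passes
  v2 <- strsplit(base, "")[[1]]
  v2[pos[1:14]] <- vapply(v2[pos[1:14]],
                          function(x) setdiff(c("A", "C", "G", "T"), x)[1],
                          character(1))
  expect_equal(nrow(screen_homologs(c(q = base),
                                    c(s = paste0(v2, collapse = "")), p0)), 1L)
})

test_that("screen is symmetric up to role swap", {
  b <- std_trio()
  fam <- b$truth$families
  ids_w <- fam$transcript_id[fam$genome == "wild"][1:6]
  ids_a <- fam$transcript_id[fam$genome == "cultivarA"]
  sW <- b$lnc_seqs$wild[ids_w]
  sA <- b$lnc_seqs$cultivarA[ids_a]
  fwd <- screen_homologs(sW, sA, genomeA = "w", genomeB = "a")
  rev <- screen_homologs(sA, sW, genomeA = "a", genomeB = "w")
  expect_setequal(paste(fwd$query_id, fwd$subject_id),
                  paste(rev$subject_id, rev$query_id))
})

test_that("family construction equals a union-find oracle on random graphs", {
  set.seed(12)
  for (k in 1:10) {
    n <- sample(10:40, 1)
    nodes <- sprintf("t%02d", 1:n)
    genome_of <- sample(c("w", "a", "b"), n, replace = TRUE)
    n_edges <- sample(5:50, 1)
    ei <- sample(n, n_edges, replace = TRUE)
    ej <- sample(n, n_edges, replace = TRUE)
    keep <- genome_of[ei] != genome_of[ej] # cross-genome links only
    if (!any(keep)) next
    segs <- data.frame(query_id = nodes[ei[keep]],
                       query_genome = genome_of[ei[keep]],
                       subject_id = nodes[ej[keep]],
                       subject_genome = genome_of[ej[keep]])
    fams <- build_families(segs, c("w", "a", "b"))
    got <- split(fams$members$transcript_id, fams$members$family_id)
    want <- union_find_components(segs$query_id, segs$subject_id)
    expect_setequal(lapply(unname(got), sort), lapply(unname(want), sort))
    # copy profile sums equal member counts
    prof <- as.matrix(fams$families[, c("copies_w", "copies_a", "copies_b")])
    expect_equal(unname(rowSums(prof)), fams$families$n_members)
  }
})

test_that("three-way flag requires membership in every genome", {
  segs <- data.frame(query_id = c("w1", "w2"), query_genome = c("w", "w"),
                     subject_id = c("a1", "b1"), subject_genome = c("a", "b"))
  fams <- build_families(segs[1, ], c("w", "a", "b"))
  expect_false(any(fams$families$three_way))
  fams2 <- build_families(segs, c("w", "a", "b"))
  expect_false(any(fams2$families$three_way)) # two separate families
  segs3 <- rbind(segs, data.frame(query_id = "w1", query_genome = "w",
                                  subject_id = "b1", subject_genome = "b"))
  fams3 <- build_families(segs3, c("w", "a", "b"))
  expect_true(any(fams3$families$three_way))
})

test_that("TE-like flagging is monotone in the copy threshold", {
  b <- std_trio()
  sc <- std_screens()
  fams <- build_families(rbind(sc$wa, sc$wb, sc$ab), b$config$genomes)
  prev <- rep(TRUE, nrow(fams$families))
  for (thr in c(2, 5, 10, 25, 50)) {
    flags <- flag_multicopy(fams, b$config$genomes, threshold = thr)$te_like
    expect_true(all(flags <= prev))
    prev <- flags
  }
  flagged <- flag_multicopy(fams, b$config$genomes, threshold = 5)
  expect_true(all(flagged$te_like[flagged$copies_wild >= 5]))
  expect_false(any(flagged$te_like[flagged$copies_wild < 5 &
                                     flagged$copies_cultivarA < 5 &
                                     flagged$copies_cultivarB < 5]))
})

test_that("empty segment set yields an empty family table", {
  fams <- build_families(
    data.frame(query_id = character(0), query_genome = character(0),
               subject_id = character(0), subject_genome = character(0)),
    c("w", "a", "b"))
  expect_equal(nrow(fams$families), 0L)
  expect_equal(nrow(fams$members), 0L)
})
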