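# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive affine-gap local-alignment DP (score only, no heuristics).
# Gap of length L costs open + L * ext; N scores as a mismatch always.
sw_score_oracle <- function(a, b, match = 1, mismatch = -2,
                            open = -4, ext = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] + open + ext, E[i, j - 1] + ext)
    F[i, j] <- max(H[i - 1, j] + open + ext, F[i - 1, j] + ext)
    s <- if (A[i - 1] == B[j - 1] && A[i - 1] %in% c("A", "C", "G", "T"))
      match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Per-base interval length by explicit enumeration.
length_by_enumeration <- function(starts, ends) {
  sum(vapply(seq_along(starts),
             function(i) length(seq(starts[i], ends[i])), numeric(1)))
}

# Connected components by plain union-find over transcript link edges.
union_find_components <- function(edges_from, edges_to) {
  nodes <- unique(c(edges_from, edges_to))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_from)) {
    ra <- find(edges_from[k]); rb <- find(edges_to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# Unordered filter-cascade oracle: re-checks all four predicates per
# transcript with no gate ordering.
filter_oracle <- function(tx, max_fpkm, cpc, cnci, th) {
  tx$transcript_id[tx$biotype != "coding" &
                     tx$length >= th$min_length &
                     max_fpkm >= th$min_fpkm &
                     cpc < th$max_coding_score &
                     cnci < th$max_coding_score]
}

# Benjamini-Hochberg step-up from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Two-sided permutation test for a difference in means.
permutation_p <- function(a, b, n_perm = 10000) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
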