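# Shared fixtures, built once per test run and cached. The "standard trio"
# is the seed-1 synthetic dataset used for all planted-truth recovery
# checks; the "large trio" (n = 2000 lncRNAs per genome) is used for
# distributional calibration.

.fixture_cache <- new.env(parent = emptyenv())

std_trio_config <- function() {
  trio_config(seed = 1, n_lnc = c(300L, 300L, 300L), coding_per_chrom = 40L)
}

std_trio <- function() {
  if (is.null(.fixture_cache$std))
    .fixture_cache$std <- generate_trio(std_trio_config())
  .fixture_cache$std
}

large_trio <- function() {
  if (is.null(.fixture_cache$large))
    .fixture_cache$large <- generate_trio(
      trio_config(seed = 1, n_lnc = c(2000L, 2000L, 2000L),
                  chrom_length = 2500000L))
  .fixture_cache$large
}

# the three pairwise homology screens over the standard trio's lncRNAs
std_screens <- function() {
  if (is.null(.fixture_cache$screens)) {
    b <- std_trio()
    g <- b$config$genomes
    .fixture_cache$screens <- list(
      wa = screen_homologs(b$lnc_seqs[[g[1]]], b$lnc_seqs[[g[2]]],
                           genomeA = g[1], genomeB = g[2]),
      wb = screen_homologs(b$lnc_seqs[[g[1]]], b$lnc_seqs[[g[3]]],
                           genomeA = g[1], genomeB = g[3]),
      ab = screen_homologs(b$lnc_seqs[[g[2]]], b$lnc_seqs[[g[3]]],
                           genomeA = g[2], genomeB = g[3]))
  }
  .fixture_cache$screens
}

# lncRNA-only transcript sets per genome of a bundle
trio_lnc_sets <- function(b) {
  lapply(b$annotations, function(a)
    subset_transcripts(a, a$transcripts$transcript_id[
      a$transcripts$biotype != "coding"]))
}

# flank contexts + pairwise positional calls over a bundle's truth
trio_positional <- function(b) {
  key <- paste0("pos_", b$config$seed)
  if (is.null(.fixture_cache[[key]])) {
    ann <- b$annotations
    lnc <- trio_lnc_sets(b)
    g <- b$config$genomes
    ctx <- lapply(g, function(x) flank_context(lnc[[x]], ann[[x]]))
    names(ctx) <- g
    orth <- b$truth$orthologs
    pair_calls <- function(a, bb) {
      o <- orth[orth$genome_a == a & orth$genome_b == bb, , drop = FALSE]
      call_positional(ctx[[a]], ctx[[bb]], o)
    }
    .fixture_cache[[key]] <- list(
      ctx = ctx,
      wa = pair_calls(g[1], g[2]),
      wb = pair_calls(g[1], g[3]),
      ab = pair_calls(g[2], g[3]))
  }
  .fixture_cache[[key]]
}

# a small hand-made two-genome layout for deterministic synteny tests:
# one chromosome per genome, `n_genes` coding genes at regular spacing,
# plus one lncRNA between genes `lnc_after` and `lnc_after + 1`.
toy_genome <- function(genome, n_genes = 30, lnc_after = 10,
                       gene_order = seq_len(n_genes)) {
  gene_w <- 1000; gap <- 1000
  starts <- 1 + (seq_len(n_genes) - 1) * (gene_w + gap)
  ex <- data.frame(
    transcript_id = sprintf("%s_g%02d", genome, gene_order),
    chrom = "chr1", start = starts, end = starts + gene_w - 1,
    strand = "+", stringsAsFactors = FALSE)
  lnc_start <- starts[lnc_after] + gene_w + 300
  ex <- rbind(ex, data.frame(transcript_id = paste0(genome, "_lnc"),
                             chrom = "chr1", start = lnc_start,
                             end = lnc_start + 399, strand = "+"))
  meta <- data.frame(transcript_id = ex$transcript_id,
                     biotype = c(rep("coding", n_genes), "lnc_candidate"))
  transcript_set(ex, meta = meta, genome = genome)
}
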