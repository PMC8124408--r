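# Deterministic synthetic trio-genome generator with planted ground truth.
#
# The generator emulates the study design the pipeline targets: a wild
# progenitor genome and two cultivar genomes, each with its own lncRNA
# length/exon-structure spectrum, panicle- and seedling-tissue expression
# with a panicle bias, planted multi-copy homolog families (TE-like),
# planted decoy families designed to fail the homology screen, planted
# collinear coding-gene blocks carrying positionally conserved lncRNAs,
# and per-plant trait measurements. Every planted element is recorded in
# a truth table so downstream stages can be scored exactly.

.BASES <- c("A", "C", "G", "T")

.rand_seq <- function(n) paste0(sample(.BASES, n, replace = TRUE),
                                collapse = "")

# substitute `round(rate * L)` positions to a different base
.mutate_seq <- function(s, rate) {
  L <- nchar(s)
  m <- round(rate * L)
  if (m == 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample.int(L, m)
  v[pos] <- vapply(v[pos],
                   function(b) sample(setdiff(.BASES, b), 1), character(1))
  paste0(v, collapse = "")
}

# truncated log-normal spliced lengths. The meanlog is solved so that the
# TRUNCATED distribution has the configured median (plain log-normal
# parameterisation would shift the realised median upward where the lower
# truncation bound bites, e.g. a 370-nt median over [201, 10000]).
.draw_lengths <- function(n, median, sdlog, range) {
  a <- range[1]; b <- range[2]
  f <- function(mu) {
    stats::plnorm(median, mu, sdlog) -
      (stats::plnorm(a, mu, sdlog) + stats::plnorm(b, mu, sdlog)) / 2
  }
  mu <- stats::uniroot(f, interval = log(median) + c(-4, 4))$root
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog = mu, sdlog = sdlog)
    out <- c(out, x[x >= a & x <= b])
  }
  as.integer(round(out[seq_len(n)]))
}

# exon count: 1 with prob p_single, else 2 + Poisson(lambda) where lambda
# reproduces the configured mean exon count
.draw_exon_counts <- function(n, p_single, mean_exons) {
  lambda <- max(0, (mean_exons - p_single - 2 * (1 - p_single)) /
                  (1 - p_single))
  k <- ifelse(stats::runif(n) < p_single, 1L,
              2L + stats::rpois(n, lambda))
  as.integer(k)
}

#' Configuration of the synthetic genome trio
#'
#' Defaults encode the study conditions the generator emulates, at desk
#' scale: three genomes (wild progenitor first), genome-specific lncRNA
#' length medians 370/670/508 nt and single-exon fractions
#' 65.83%/50.39%/61.96% with mean exon counts 1.61/2.37/1.76; mRNA medians
#' 1178/1425/912 nt with mean exon counts 5.85/4.55/4.18; two planted
#' TE-like homolog families with copy profiles (41,1,3) and (21,1,2) at
#' 96% pairwise identity over 150-nt segments; two decoy families designed
#' to fail the >100 nt / >90% screen (85% identity, and 90-nt segment);
#' planted collinear blocks giving 10 wild-cultivarA pairs, 12
#' wild-cultivarB pairs (the wild-B excess mirrors the stronger wild-indica
#' synteny), 8 cultivarA-cultivarB pairs and exactly 8 triple-conserved
#' lncRNAs; negative-binomial expression with a panicle multiplier; and a
#' reference lncRNA annotation for the second genome covering ~52.6% of
#' its lncRNAs.
#'
#' @param seed integer seed; a fixed seed makes [generate_trio()] output
#'   byte-identical across runs.
#' @param genomes ordered genome labels (first = wild progenitor).
#' @param n_chrom,chrom_length chromosomes per genome and their length
#'   cap (nt).
#' @param n_lnc lncRNA count per genome (planted members included).
#' @param median_length,sdlog,length_range log-normal spliced-length model
#'   per genome (nt), truncated to `length_range`.
#' @param single_exon_prob,mean_exons lncRNA exon-structure model per
#'   genome.
#' @param coding_per_chrom background protein-coding genes per chromosome.
#' @param block_bg_genes background (non-orthologous) coding genes on the
#'   dedicated block chromosome; they dilute gene ranks around the planted
#'   blocks so the rank-window rule is exercised against a realistic gene
#'   density.
#' @param mrna_median_length,mrna_mean_exons mRNA structure per genome.
#' @param families planted homolog families: list of
#'   `list(copies = <int per genome>, segment_length, identity)` where
#'   `identity` is the target pairwise percent identity among members.
#' @param decoys planted families expected to fail the homology screen
#'   (same shape).
#' @param blocks planted collinear blocks: list of
#'   `list(genomes = <indices>, n_genes, lnc = TRUE/FALSE)`.
#' @param expression negative-binomial model: `mean`, `mean_sdlog`
#'   (spread of per-transcript base means), `dispersion`, `multiplier`
#'   (panicle over seedling for differentially expressed lncRNAs),
#'   `frac_null` (fraction of non-DE lncRNAs), `frac_silent` (fraction
#'   with near-zero expression, exercising the FPKM gate), `lib_size`
#'   (total mapped fragments per library).
#' @param known_fraction per genome, fraction of lncRNAs covered by an
#'   emitted reference lncRNA annotation (0 = no reference emitted).
#' @param traits data.frame of trait-sampling parameters: `line`, `trait`,
#'   `mean`, `sd`, `n`.
#' @return list of class `trio_config`.
#' @export
trio_config <- function(
    seed = 1L,
    genomes = c("wild", "cultivarA", "cultivarB"),
    n_chrom = 4L,
    chrom_length = 800000L,
    n_lnc = c(500L, 500L, 500L),
    median_length = c(370, 670, 508),
    sdlog = 0.6,
    length_range = c(201L, 10000L),
    single_exon_prob = c(0.6583, 0.5039, 0.6196),
    mean_exons = c(1.61, 2.37, 1.76),
    coding_per_chrom = 60L,
    block_bg_genes = 120L,
    mrna_median_length = c(1178, 1425, 912),
    mrna_mean_exons = c(5.85, 4.55, 4.18),
    families = list(
      list(copies = c(41L, 1L, 3L), segment_length = 150L, identity = 96),
      list(copies = c(21L, 1L, 2L), segment_length = 150L, identity = 96)),
    decoys = list(
      list(copies = c(2L, 1L, 1L), segment_length = 150L, identity = 85),
      list(copies = c(2L, 1L, 1L), segment_length = 90L, identity = 96)),
    blocks = c(
      rep(list(list(genomes = c(1L, 2L, 3L), n_genes = 10L, lnc = TRUE)), 8),
      rep(list(list(genomes = c(1L, 3L), n_genes = 10L, lnc = TRUE)), 4),
      rep(list(list(genomes = c(1L, 2L), n_genes = 10L, lnc = TRUE)), 2),
      list(list(genomes = c(1L, 2L, 3L), n_genes = 10L, lnc = FALSE))),
    expression = list(mean = 50, mean_sdlog = 1, dispersion = 0.1,
                      multiplier = 10, frac_null = 0.35,
                      frac_silent = 0.05, lib_size = 5e7),
    known_fraction = c(0, 0.5256, 0),
    traits = NULL) {
  if (is.null(traits)) {
    traits <- data.frame(
      line = rep(c("WT", "mut1"), each = 4),
      trait = rep(c("plant_height_cm", "panicle_length_cm",
                    "grain_length_mm", "grain_width_mm"), 2),
      mean = c(64.38, 16.80, 7.64, 3.49, 51.38, 16.62, 6.93, 2.72),
      sd = c(3.56, 0.56, 0.33, 0.14, 3.87, 2.04, 0.27, 0.17),
      n = c(12L, 12L, 31L, 31L, 12L, 12L, 31L, 31L),
      stringsAsFactors = FALSE)
  }
  G <- length(genomes)
  stopifnot(G >= 2, !anyDuplicated(genomes), length(n_lnc) == G,
            length(median_length) == G, length(single_exon_prob) == G)
  for (f in c(families, decoys)) {
    if (f$identity <= 50 || f$identity > 100)
      stop("family identity must be in (50, 100]: got ", f$identity)
    stopifnot(length(f$copies) == G, all(f$copies >= 0))
  }
  cfg <- list(seed = as.integer(seed), genomes = genomes,
              n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              n_lnc = as.integer(n_lnc), median_length = median_length,
              sdlog = sdlog, length_range = as.integer(length_range),
              single_exon_prob = single_exon_prob, mean_exons = mean_exons,
              coding_per_chrom = as.integer(coding_per_chrom),
              block_bg_genes = as.integer(block_bg_genes),
              mrna_median_length = mrna_median_length,
              mrna_mean_exons = mrna_mean_exons,
              families = families, decoys = decoys, blocks = blocks,
              expression = expression, known_fraction = known_fraction,
              traits = traits)
  class(cfg) <- "trio_config"
  cfg
}

#' Plant one multi-copy homolog family
#'
#' All copies derive from one random consensus segment; each copy is
#' point-mutated at half the configured pairwise divergence, so the
#' expected pairwise identity among members is the configured `identity`.
#' Copies are flanked with random sequence to reach lncRNA length
#' (minimum 201 nt of transcript, at least 30 nt per flank).
#'
#' @param copies integer vector, copy number per genome.
#' @param segment_length consensus segment length (nt).
#' @param identity target pairwise percent identity, in (50, 100].
#' @param genomes genome labels.
#' @return list: `consensus` and `members` (data.frame `genome`,
#'   `member`, `seq`, `segment_start`, `segment_end`).
#' @export
plant_te_family <- function(copies, segment_length, identity, genomes) {
  if (identity <= 50 || identity > 100)
    stop("identity must be in (50, 100]: got ", identity)
  stopifnot(all(copies >= 0), length(copies) == length(genomes))
  if (sum(copies) == 0)
    return(list(consensus = NULL,
                members = data.frame(genome = character(0),
                                     member = integer(0), seq = character(0),
                                     segment_start = integer(0),
                                     segment_end = integer(0))))
  consensus <- .rand_seq(segment_length)
  rate <- (100 - identity) / 200
  flank <- max(30L, as.integer(ceiling((201 - segment_length) / 2)))
  rows <- list()
  for (gi in seq_along(genomes)) {
    for (k in seq_len(copies[gi])) {
      seg <- .mutate_seq(consensus, rate)
      rows[[length(rows) + 1L]] <- data.frame(
        genome = genomes[gi], member = k,
        seq = paste0(.rand_seq(flank), seg, .rand_seq(flank)),
        segment_start = flank + 1L,
        segment_end = flank + segment_length,
        stringsAsFactors = FALSE)
    }
  }
  list(consensus = consensus, members = do.call(rbind, rows))
}

#' Simulate panicle/seedling fragment counts for one genome
#'
#' Negative-binomial counts for two unreplicated libraries, generated as
#' a Poisson-gamma mixture: each transcript draws one gamma-distributed
#' true concentration (shape 1/dispersion, mean 1, shared between the two
#' libraries) and each library samples Poisson counts from it, so the
#' marginal count distribution is NB(mean, dispersion) while a null
#' transcript genuinely has one concentration in both tissues. Each
#' transcript is silent (near-zero mean), null (shared concentration) or
#' differentially expressed (panicle concentration = multiplier x
#' seedling; the bias is panicle-ward, matching the tissue contrast the
#' design emulates).
#'
#' @param ids transcript identifiers.
#' @param model expression model list (see [trio_config()]).
#' @param never_silent ids exempt from silent status (planted truth
#'   members, which must stay detectable downstream).
#' @return list: `counts` (matrix, columns `panicle`, `seedling`),
#'   `status` (character: `"silent"`, `"null"`, `"de"`).
#' @export
simulate_counts <- function(ids, model = trio_config()$expression,
                            never_silent = character(0)) {
  n <- length(ids)
  stopifnot(model$mean > 0, model$dispersion > 0)
  u <- stats::runif(n)
  status <- ifelse(u < model$frac_silent, "silent",
                   ifelse(u < model$frac_silent + model$frac_null,
                          "null", "de"))
  status[ids %in% never_silent & status == "silent"] <- "null"
  if (model$multiplier == 1) status[status == "de"] <- "null"
  base <- stats::rlnorm(n, log(model$mean), model$mean_sdlog %||% 1)
  mix <- stats::rgamma(n, shape = 1 / model$dispersion,
                       rate = 1 / model$dispersion)
  mu <- base * mix
  mu[status == "silent"] <- 0.02
  mu_p <- ifelse(status == "de", mu * model$multiplier, mu)
  counts <- cbind(panicle = stats::rpois(n, mu_p),
                  seedling = stats::rpois(n, mu))
  rownames(counts) <- ids
  list(counts = counts, status = status)
}

# one genome's element layout: returns exon table, metadata, sequences
.build_genome <- function(cfg, gi, fam_members, block_defs) {
  g <- cfg$genomes[gi]
  nchr <- cfg$n_chrom
  # planted collinear blocks live on a dedicated extra chromosome, mixed
  # with non-orthologous background coding genes but no background
  # lncRNAs, so the planted positional truth is exact
  involved <- any(vapply(block_defs, function(b) gi %in% b$genomes,
                         logical(1)))
  block_chrom <- nchr + 1L
  nchr_total <- nchr + as.integer(involved)
  elements <- list() # each: id, class, origin, strand, spliced_len,
                     # exon_count, seq (or NA), chrom

  # background coding genes
  ncode <- cfg$coding_per_chrom * nchr
  clen <- .draw_lengths(ncode, cfg$mrna_median_length[gi], cfg$sdlog,
                        c(300L, 15000L))
  cex <- .draw_exon_counts(ncode, 0.1, cfg$mrna_mean_exons[gi])
  for (k in seq_len(ncode)) {
    elements[[length(elements) + 1L]] <- list(
      id = sprintf("%s_G%04d", g, k), class = "coding",
      origin = "background", strand = sample(c("+", "-"), 1),
      spliced_len = clen[k], exon_count = cex[k], seq = NA_character_,
      chrom = ((k - 1L) %% nchr) + 1L, unit = NA_integer_)
  }

  # planted family/decoy members (single-exon, dispersed across chroms)
  n_planted_lnc <- nrow(fam_members)
  if (n_planted_lnc) {
    for (k in seq_len(n_planted_lnc)) {
      elements[[length(elements) + 1L]] <- list(
        id = fam_members$id[k], class = "lnc",
        origin = fam_members$origin[k], strand = sample(c("+", "-"), 1),
        spliced_len = nchar(fam_members$seq[k]), exon_count = 1L,
        seq = fam_members$seq[k], chrom = ((k - 1L) %% nchr) + 1L,
        unit = NA_integer_)
    }
  }

  # background coding genes on the block chromosome
  if (involved && cfg$block_bg_genes > 0) {
    blen <- .draw_lengths(cfg$block_bg_genes, cfg$mrna_median_length[gi],
                          cfg$sdlog, c(300L, 15000L))
    bex <- .draw_exon_counts(cfg$block_bg_genes, 0.1,
                             cfg$mrna_mean_exons[gi])
    for (k in seq_len(cfg$block_bg_genes)) {
      elements[[length(elements) + 1L]] <- list(
        id = sprintf("%s_BG%04d", g, k), class = "coding",
        origin = "background", strand = sample(c("+", "-"), 1),
        spliced_len = blen[k], exon_count = bex[k], seq = NA_character_,
        chrom = block_chrom, unit = NA_integer_)
    }
  }

  # planted collinear blocks: contiguous units
  n_block_lnc <- 0L
  for (b in seq_along(block_defs)) {
    bd <- block_defs[[b]]
    if (!(gi %in% bd$genomes)) next
    chrom <- block_chrom
    half <- bd$n_genes %/% 2L
    for (k in seq_len(bd$n_genes)) {
      elements[[length(elements) + 1L]] <- list(
        id = sprintf("%s_BLK%02d_G%02d", g, b, k), class = "coding",
        origin = "block", strand = "+",
        spliced_len = nchar(bd$gene_seqs[[gi]][k]), exon_count = 1L,
        seq = bd$gene_seqs[[gi]][k], chrom = chrom, unit = b)
      if (bd$lnc && k == half) { # lncRNA at the block midpoint
        n_block_lnc <- n_block_lnc + 1L
        elements[[length(elements) + 1L]] <- list(
          id = sprintf("%s_BLK%02d_LNC", g, b), class = "lnc",
          origin = "block_lnc", strand = "+",
          spliced_len = 400L, exon_count = 1L, seq = .rand_seq(400L),
          chrom = chrom, unit = b)
      }
    }
  }

  # background lncRNAs fill up to the configured count
  n_bg <- cfg$n_lnc[gi] - n_planted_lnc - n_block_lnc
  if (n_bg < 0)
    stop("infeasible config: planted lncRNAs (", n_planted_lnc + n_block_lnc,
         ") exceed n_lnc for genome ", g)
  if (n_bg) {
    llen <- .draw_lengths(n_bg, cfg$median_length[gi], cfg$sdlog,
                          cfg$length_range)
    lex <- .draw_exon_counts(n_bg, cfg$single_exon_prob[gi],
                             cfg$mean_exons[gi])
    for (k in seq_len(n_bg)) {
      elements[[length(elements) + 1L]] <- list(
        id = sprintf("%s_LNC%04d", g, k), class = "lnc",
        origin = "background", strand = sample(c("+", "-"), 1),
        spliced_len = llen[k], exon_count = lex[k], seq = NA_character_,
        chrom = ((k - 1L) %% nchr) + 1L, unit = NA_integer_)
    }
  }

  # layout per chromosome: shuffle standalone elements, keep block units
  # contiguous, then place left to right with random intergenic gaps
  exon_rows <- list()
  chrom_seqs <- stats::setNames(vector("list", nchr_total),
                                sprintf("chr%d", seq_len(nchr_total)))
  el_chrom <- vapply(elements, `[[`, integer(1), "chrom")
  el_unit <- vapply(elements, `[[`, integer(1), "unit")
  for (ch in seq_len(nchr_total)) {
    idx <- which(el_chrom == ch)
    units <- split(idx, ifelse(is.na(el_unit[idx]),
                               paste0("s", idx), paste0("u", el_unit[idx])))
    units <- units[sample(length(units))]
    chrom_vec <- sample(.BASES, cfg$chrom_length, replace = TRUE)
    cursor <- 1L
    for (u in units) {
      for (ei in u) {
        el <- elements[[ei]]
        cursor <- cursor + sample(200:1500, 1)
        k <- el$exon_count
        S <- el$spliced_len
        if (S < 60L * k) k <- max(1L, S %/% 60L)
        cuts <- if (k > 1) sort(sample(seq(30L, S - 30L), k - 1L)) else integer(0)
        ex_len <- diff(c(0L, cuts, S))
        introns <- if (k > 1) sample(60:400, k - 1L, replace = TRUE)
                   else integer(0)
        starts <- cursor + cumsum(c(0L, ex_len[-k] + introns))
        ends <- starts + ex_len - 1L
        if (ends[k] > cfg$chrom_length)
          stop("infeasible config: chromosome ", ch, " of genome ", g,
               " overflows its length cap (", cfg$chrom_length, " nt)")
        if (!is.na(el$seq)) { # write planted sequence into the genome
          genomic <- if (el$strand == "+") el$seq else revcomp(el$seq)
          off <- 0L
          for (e in seq_len(k)) {
            piece <- substr(genomic, off + 1L, off + ex_len[e])
            chrom_vec[starts[e]:ends[e]] <- strsplit(piece, "")[[1]]
            off <- off + ex_len[e]
          }
        }
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          transcript_id = el$id, chrom = sprintf("chr%d", ch),
          start = starts, end = ends, strand = el$strand,
          stringsAsFactors = FALSE)
        cursor <- ends[k] + 1L
      }
    }
    chrom_seqs[[ch]] <- paste0(chrom_vec, collapse = "")
  }

  exons <- do.call(rbind, exon_rows)
  meta <- data.frame(
    transcript_id = vapply(elements, `[[`, character(1), "id"),
    gene_id = vapply(elements, `[[`, character(1), "id"),
    biotype = ifelse(vapply(elements, `[[`, character(1), "class") ==
                       "coding", "coding", "lnc_candidate"),
    origin = vapply(elements, `[[`, character(1), "origin"),
    stringsAsFactors = FALSE)
  ts <- transcript_set(exons, meta = meta, genome = g)
  list(annotation = ts, genome_seqs = unlist(chrom_seqs), meta = meta)
}

#' Generate the full synthetic trio dataset
#'
#' Deterministic given `config$seed`: two runs with the same config are
#' byte-identical on disk. Writes, per genome, a genome FASTA, a GFF3
#' annotation, a counts TSV (panicle + seedling), a library-size TSV and a
#' coding-score TSV; plus a reference lncRNA GFF3 for genomes with
#' `known_fraction > 0`, a long-format trait TSV, truth tables
#' (families, positional blocks, DE status, known status, orthologs) and
#' a MANIFEST with md5 checksums of every emitted file.
#'
#' @param config a [trio_config()].
#' @param dir output directory (created); `NULL` keeps everything
#'   in memory only.
#' @return list of class `trio_bundle`: `config`, `annotations`,
#'   `genome_seqs`, `lnc_seqs`, `counts`, `lib_sizes`, `scores`,
#'   `reference`, `traits`, `truth`, `files`.
#' @export
generate_trio <- function(config = trio_config(), dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  G <- length(cfg$genomes)

  # --- plant families and decoys -------------------------------------
  fam_rows <- list()       # truth rows
  fam_members <- stats::setNames(
    rep(list(data.frame(id = character(0), seq = character(0),
                        origin = character(0))), G), cfg$genomes)
  plant_set <- function(defs, origin, prefix) {
    for (f in seq_along(defs)) {
      d <- defs[[f]]
      fam <- plant_te_family(d$copies, d$segment_length, d$identity,
                             cfg$genomes)
      fid <- sprintf("%s%02d", prefix, f)
      if (!nrow(fam$members)) next
      for (r in seq_len(nrow(fam$members))) {
        gm <- fam$members$genome[r]
        id <- sprintf("%s_%s_M%02d", gm, fid, fam$members$member[r])
        fam_members[[gm]] <<- rbind(
          fam_members[[gm]],
          data.frame(id = id, seq = fam$members$seq[r], origin = origin,
                     stringsAsFactors = FALSE))
        fam_rows[[length(fam_rows) + 1L]] <<- data.frame(
          family_id = fid, type = origin, genome = gm, transcript_id = id,
          segment_length = d$segment_length, identity = d$identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  plant_set(cfg$families, "family", "FAMT")
  plant_set(cfg$decoys, "decoy", "DECY")
  truth_families <- if (length(fam_rows)) do.call(rbind, fam_rows)
                    else data.frame(family_id = character(0))

  # --- block gene sequences (shared ancestry, ~95% pairwise identity) --
  block_defs <- cfg$blocks
  truth_orth <- list()
  for (b in seq_along(block_defs)) {
    bd <- block_defs[[b]]
    anc <- vapply(seq_len(bd$n_genes),
                  function(i) .rand_seq(sample(900:1800, 1)), character(1))
    bd$gene_seqs <- lapply(seq_len(G), function(gi) {
      if (gi %in% bd$genomes)
        vapply(anc, .mutate_seq, character(1), rate = 0.025)
      else character(0)
    })
    block_defs[[b]] <- bd
    for (gi in bd$genomes) for (gj in bd$genomes) {
      if (gi >= gj) next
      truth_orth[[length(truth_orth) + 1L]] <- data.frame(
        genome_a = cfg$genomes[gi], genome_b = cfg$genomes[gj],
        gene_a = sprintf("%s_BLK%02d_G%02d", cfg$genomes[gi], b,
                         seq_len(bd$n_genes)),
        gene_b = sprintf("%s_BLK%02d_G%02d", cfg$genomes[gj], b,
                         seq_len(bd$n_genes)),
        stringsAsFactors = FALSE)
    }
  }
  truth_orth <- if (length(truth_orth)) do.call(rbind, truth_orth)
                else data.frame(genome_a = character(0))

  truth_pos <- list()
  for (b in seq_along(block_defs)) {
    bd <- block_defs[[b]]
    if (!bd$lnc) next
    row <- data.frame(block_id = sprintf("BLK%02d", b),
                      stringsAsFactors = FALSE)
    for (gi in seq_len(G))
      row[[paste0("lnc_", cfg$genomes[gi])]] <-
        if (gi %in% bd$genomes)
          sprintf("%s_BLK%02d_LNC", cfg$genomes[gi], b)
        else NA_character_
    row$triple <- length(bd$genomes) >= 3
    truth_pos[[length(truth_pos) + 1L]] <- row
  }
  truth_pos <- if (length(truth_pos)) do.call(rbind, truth_pos)
               else data.frame(block_id = character(0))

  # --- per-genome genomes, annotations, expression, scores ------------
  annotations <- list(); genome_seqs <- list(); lnc_seqs <- list()
  counts <- list(); scores <- list(); reference <- list()
  truth_de <- list(); truth_known <- list()
  for (gi in seq_len(G)) {
    g <- cfg$genomes[gi]
    built <- .build_genome(cfg, gi, fam_members[[g]], block_defs)
    annotations[[g]] <- built$annotation
    genome_seqs[[g]] <- built$genome_seqs
    tx <- built$annotation$transcripts
    all_seqs <- extract_transcript_seqs(built$genome_seqs,
                                        built$annotation)
    lnc_ids <- tx$transcript_id[tx$biotype != "coding"]
    code_ids <- tx$transcript_id[tx$biotype == "coding"]
    lnc_seqs[[g]] <- all_seqs[lnc_ids]

    planted_ids <- c(fam_members[[g]]$id,
                     sprintf("%s_BLK%02d_LNC", g, seq_along(block_defs)))
    sim <- simulate_counts(lnc_ids, cfg$expression,
                           never_silent = planted_ids)
    code_counts <- cbind(
      panicle = stats::rnbinom(length(code_ids), mu = 500,
                               size = 1 / cfg$expression$dispersion),
      seedling = stats::rnbinom(length(code_ids), mu = 500,
                                size = 1 / cfg$expression$dispersion))
    rownames(code_counts) <- code_ids
    cts <- rbind(sim$counts, code_counts)
    cts <- cts[tx$transcript_id, , drop = FALSE]
    colnames(cts) <- paste0(g, "_", colnames(cts))
    counts[[g]] <- cts
    truth_de[[g]] <- data.frame(genome = g, transcript_id = lnc_ids,
                                status = sim$status,
                                multiplier = ifelse(sim$status == "de",
                                                    cfg$expression$multiplier,
                                                    1),
                                stringsAsFactors = FALSE)

    # coding scores: two normals separated by biotype; planted lncRNAs
    # truncated below zero so planted truth survives the cascade
    is_code <- tx$biotype == "coding"
    sc <- ifelse(is_code, stats::rnorm(nrow(tx), 2, 0.7),
                 stats::rnorm(nrow(tx), -2, 0.7))
    sc2 <- ifelse(is_code, stats::rnorm(nrow(tx), 2, 0.7),
                  stats::rnorm(nrow(tx), -2, 0.7))
    planted <- tx$transcript_id %in%
      c(fam_members[[g]]$id,
        sprintf("%s_BLK%02d_LNC", g, seq_along(block_defs)))
    sc[planted] <- pmin(sc[planted], -0.1)
    sc2[planted] <- pmin(sc2[planted], -0.1)
    scores[[g]] <- data.frame(transcript_id = tx$transcript_id,
                              cpc_score = sc, cnci_score = sc2,
                              stringsAsFactors = FALSE)

    # reference lncRNA annotation: a fraction of this genome's lncRNAs
    kf <- cfg$known_fraction[gi]
    if (kf > 0) {
      n_known <- round(kf * length(lnc_ids))
      known_ids <- sample(lnc_ids, n_known)
      ref <- subset_transcripts(built$annotation, known_ids)
      ref$transcripts$transcript_id <- paste0("REF.", ref$transcripts$transcript_id)
      ref$transcripts$gene_id <- ref$transcripts$transcript_id
      ref$exons$transcript_id <- paste0("REF.", ref$exons$transcript_id)
      ref$transcripts$biotype <- "lncRNA"
      reference[[g]] <- ref
      truth_known[[g]] <- data.frame(genome = g, transcript_id = lnc_ids,
                                     known = lnc_ids %in% known_ids,
                                     stringsAsFactors = FALSE)
    } else {
      reference[g] <- list(NULL)
      truth_known[[g]] <- data.frame(genome = g, transcript_id = lnc_ids,
                                     known = FALSE,
                                     stringsAsFactors = FALSE)
    }
  }

  # --- traits ---------------------------------------------------------
  tr <- cfg$traits
  trait_rows <- list()
  for (r in seq_len(nrow(tr))) {
    trait_rows[[r]] <- data.frame(
      line = tr$line[r], trait = tr$trait[r],
      value = round(stats::rnorm(tr$n[r], tr$mean[r], tr$sd[r]), 3),
      stringsAsFactors = FALSE)
  }
  traits_df <- do.call(rbind, trait_rows)

  truth <- list(families = truth_families, positional = truth_pos,
                de = do.call(rbind, truth_de),
                known = do.call(rbind, truth_known),
                orthologs = truth_orth)

  bundle <- structure(list(config = cfg, annotations = annotations,
                           genome_seqs = genome_seqs, lnc_seqs = lnc_seqs,
                           counts = counts, scores = scores,
                           reference = reference, traits = traits_df,
                           truth = truth, files = character(0)),
                      class = "trio_bundle")
  if (!is.null(dir)) bundle$files <- write_trio(bundle, dir)
  bundle
}

#' @export
print.trio_bundle <- function(x, ...) {
  cat("trio_bundle: genomes ", paste(x$config$genomes, collapse = ", "),
      "; ", sum(x$truth$de$status != ""), " lncRNAs; ",
      nrow(x$truth$families), " planted family members\n", sep = "")
  invisible(x)
}

#' Write a trio bundle to disk with a checksummed MANIFEST
#'
#' @param bundle a `trio_bundle`.
#' @param dir output directory.
#' @return named character vector of emitted file paths (including the
#'   MANIFEST), invisibly.
#' @export
write_trio <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  paths <- character(0)
  emit <- function(name) { p <- file.path(dir, name); paths <<- c(paths, p); p }
  for (g in cfg$genomes) {
    write_fasta(bundle$genome_seqs[[g]], emit(paste0(g, "_genome.fa")))
    write_gff3(bundle$annotations[[g]], emit(paste0(g, ".gff3")))
    cts <- data.frame(transcript_id = rownames(bundle$counts[[g]]),
                      bundle$counts[[g]], check.names = FALSE)
    write_table(cts, emit(paste0(g, "_counts.tsv")))
    write_table(data.frame(sample = colnames(bundle$counts[[g]]),
                           lib_size = cfg$expression$lib_size),
                emit(paste0(g, "_lib_sizes.tsv")))
    write_table(bundle$scores[[g]], emit(paste0(g, "_scores.tsv")))
    if (!is.null(bundle$reference[[g]]))
      write_gff3(bundle$reference[[g]], emit(paste0(g, "_reference_lncrna.gff3")))
  }
  write_table(bundle$traits, emit("traits.tsv"))
  write_table(bundle$truth$families, emit("truth_families.tsv"))
  write_table(bundle$truth$positional, emit("truth_positional.tsv"))
  write_table(bundle$truth$de, emit("truth_de.tsv"))
  write_table(bundle$truth$known, emit("truth_known.tsv"))
  write_table(bundle$truth$orthologs, emit("truth_orthologs.tsv"))
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  write_table(manifest, file.path(dir, "MANIFEST.tsv"))
  invisible(c(paths, file.path(dir, "MANIFEST.tsv")))
}
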