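# End-to-end runner: simulate? -> discover -> features -> de -> homology
# -> synteny -> traits, with a single config, per-stage seeds derived from
# one global seed, and a checksummed MANIFEST of every output.

#' Read and validate a pipeline run configuration
#'
#' YAML with fields: `seed`, `outdir`, `simulate` (generate the synthetic
#' trio in `outdir/data` and analyse it), or a `genomes` list (entries
#' `name`, `annotation`, `genome`, `counts`, `lib_sizes`, `scores`,
#' optional `reference`), optional `orthologs` TSV, `traits` TSV with a
#' `wildtype` line label, and a `thresholds` block (defaults: min_length
#' 201, min_fpkm 0.1, coding scores < 0, fold change > 2, FDR < 0.05,
#' segment > 100 columns, identity > 90%, 4 of 5 context genes close,
#' rank window 10).
#'
#' @param path YAML file, or a list with the same structure.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$simulate <- isTRUE(cfg$simulate)
  if (is.null(cfg$outdir)) stop("config: 'outdir' is required")
  th <- cfg$thresholds %||% list()
  defaults <- list(min_length = 201, min_fpkm = 0.1, max_coding_score = 0,
                   fc = 2, fdr = 0.05, min_segment = 100, min_identity = 90,
                   window = 10, min_close = 4, te_copies = 5)
  for (k in names(defaults)) th[[k]] <- th[[k]] %||% defaults[[k]]
  cfg$thresholds <- th
  if (!cfg$simulate) {
    if (is.null(cfg$genomes) || length(cfg$genomes) < 1)
      stop("config: 'genomes' entries required unless 'simulate: true'")
    for (g in cfg$genomes) {
      for (f in c("name", "annotation", "genome", "counts", "scores")) {
        if (is.null(g[[f]]))
          stop("config: genome entry missing required field '", f, "'")
      }
      for (f in c("annotation", "genome", "counts", "scores")) {
        if (!file.exists(g[[f]]))
          stop("config: file not found for genome ", g$name, ": ", g[[f]])
      }
    }
    if (length(cfg$genomes) < 2)
      stop("config: at least two 'genomes' entries required")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full trio pipeline
#'
#' Stage order: simulate (optional), discover, features, differential
#' expression, homology, synteny, traits. Every output file is written
#' under `outdir` and checksummed into `MANIFEST.tsv`; a rerun with the
#' same config and seed is byte-identical. Any stage failure aborts with
#' the stage name.
#'
#' @param config a [read_run_config()] result, a path to a YAML config,
#'   or a list.
#' @return invisible list of stage results (`discovery`, `features`,
#'   `de`, `homology`, `synteny`, `traits`, `manifest`).
#' @export
run_trio_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  th <- cfg$thresholds
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(x, name) {
    p <- file.path(cfg$outdir, name)
    write_table(x, p)
    outputs <<- c(outputs, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------
  if (cfg$simulate) {
    bundle <- stage("simulate", {
      tc_args <- cfg$trio %||% list()
      tc_args$seed <- stage_seed(cfg$seed, "simulate")
      generate_trio(do.call(trio_config, tc_args),
                    dir = file.path(cfg$outdir, "data"))
    })
    genomes <- bundle$config$genomes
    annotations <- bundle$annotations
    counts <- bundle$counts
    lib_sizes <- lapply(counts, function(m)
      stats::setNames(rep(bundle$config$expression$lib_size, ncol(m)),
                      colnames(m)))
    scores <- bundle$scores
    reference <- bundle$reference
    lnc_seqs_all <- bundle$lnc_seqs
    orthologs <- bundle$truth$orthologs
    traits_df <- bundle$traits
    wildtype <- "WT"
  } else {
    genomes <- vapply(cfg$genomes, `[[`, character(1), "name")
    annotations <- list(); counts <- list(); lib_sizes <- list()
    scores <- list(); reference <- list(); lnc_seqs_all <- list()
    for (g in cfg$genomes) {
      annotations[[g$name]] <- stage("read", read_annotation(g$annotation,
                                                             g$name))
      ctab <- read_table(g$counts)
      m <- as.matrix(ctab[, -1, drop = FALSE])
      rownames(m) <- ctab[[1]]
      counts[[g$name]] <- m
      lib_sizes[[g$name]] <- if (!is.null(g$lib_sizes)) {
        lt <- read_table(g$lib_sizes)
        stats::setNames(lt$lib_size, lt$sample)[colnames(m)]
      } else colSums(m)
      scores[[g$name]] <- read_table(g$scores)
      reference[[g$name]] <- if (!is.null(g$reference))
        read_annotation(g$reference, g$name) else NULL
      gseq <- read_fasta(g$genome)
      lnc_seqs_all[[g$name]] <- extract_transcript_seqs(
        gseq, annotations[[g$name]])
    }
    orthologs <- if (!is.null(cfg$orthologs)) read_table(cfg$orthologs)
                 else NULL
    traits_df <- if (!is.null(cfg$traits)) read_table(cfg$traits) else NULL
    wildtype <- cfg$wildtype %||% "WT"
  }

  # --- discover -------------------------------------------------------
  fth <- filter_thresholds(th$min_length, th$min_fpkm, th$max_coding_score)
  discovery <- stage("discover", {
    res <- list()
    for (g in genomes) {
      expr <- compute_fpkm(counts[[g]],
                           transcript_length(annotations[[g]]),
                           lib_sizes[[g]])
      d <- filter_lncrnas(annotations[[g]], expr$fpkm, scores[[g]], fth)
      d$known <- classify_known(d$retained, reference[[g]])
      d$expr <- expr
      emit(d$audit, paste0(g, "_audit.tsv"))
      res[[g]] <- d
    }
    res
  })
  retained <- lapply(discovery, `[[`, "retained")
  summary_tab <- summarize_discovery(retained,
                                     lapply(discovery, `[[`, "known"))
  emit(summary_tab, "discovery_summary.tsv")

  # --- features -------------------------------------------------------
  feats <- stage("features", summarize_features(retained))
  emit(feats$stats, "lncrna_features.tsv")
  emit(feats$comparisons, "lncrna_feature_tests.tsv")

  # --- differential expression ---------------------------------------
  de <- stage("de", {
    res <- list()
    for (g in genomes) {
      lnc_ids <- retained[[g]]$transcripts$transcript_id
      expr <- discovery[[g]]$expr
      sub <- compute_fpkm(expr$counts[lnc_ids, , drop = FALSE],
                          expr$lengths[lnc_ids], expr$lib_sizes)
      r <- differential_expression(sub, paste0(g, "_panicle"),
                                   paste0(g, "_seedling"),
                                   fc_threshold = th$fc, alpha = th$fdr)
      emit(r, paste0(g, "_de.tsv"))
      res[[g]] <- r
    }
    res
  })

  # --- homology -------------------------------------------------------
  ap <- align_params(min_segment_length = th$min_segment,
                     min_identity = th$min_identity)
  homology <- stage("homology", {
    segs <- list()
    for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
      if (i >= j) next
      gi <- genomes[i]; gj <- genomes[j]
      seqs_i <- lnc_seqs_all[[gi]][retained[[gi]]$transcripts$transcript_id]
      seqs_j <- lnc_seqs_all[[gj]][retained[[gj]]$transcripts$transcript_id]
      segs[[paste(gi, gj, sep = "-")]] <-
        screen_homologs(seqs_i, seqs_j, ap, gi, gj)
    }
    all_segs <- do.call(rbind, c(segs, make.row.names = FALSE))
    emit(all_segs, "homology_segments.tsv")
    fams <- build_families(all_segs, genomes)
    fam_tab <- flag_multicopy(fams, genomes, threshold = th$te_copies)
    emit(fam_tab, "conserved_families.tsv")
    emit(fams$members, "family_members.tsv")
    list(segments = all_segs, families = fams, family_table = fam_tab)
  })

  # --- synteny --------------------------------------------------------
  synteny <- stage("synteny", {
    ctx <- lapply(genomes, function(g)
      flank_context(retained[[g]], annotations[[g]]))
    names(ctx) <- genomes
    calls <- list()
    for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
      if (i >= j) next
      gi <- genomes[i]; gj <- genomes[j]
      orth <- orthologs[orthologs$genome_a == gi &
                          orthologs$genome_b == gj, , drop = FALSE]
      cl <- call_positional(ctx[[gi]], ctx[[gj]], orth,
                            window = th$window, min_close = th$min_close)
      emit(cl, paste0("positional_", gi, "-", gj, ".tsv"))
      calls[[paste(gi, gj, sep = "-")]] <- cl
    }
    triples <- if (length(genomes) >= 3)
      intersect_triples(calls[[paste(genomes[1], genomes[2], sep = "-")]],
                        calls[[paste(genomes[1], genomes[3], sep = "-")]],
                        calls[[paste(genomes[2], genomes[3], sep = "-")]])
      else NULL
    if (!is.null(triples)) emit(triples, "positional_triples.tsv")
    list(contexts = ctx, calls = calls, triples = triples)
  })

  # --- traits ---------------------------------------------------------
  traits <- NULL
  if (!is.null(traits_df)) {
    traits <- stage("traits", {
      s <- summarize_traits(traits_df, wildtype)
      emit(s, "trait_tests.tsv")
      emit(render_trait_table(s, wildtype), "trait_table.tsv")
      s
    })
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  write_table(manifest, file.path(cfg$outdir, "MANIFEST.tsv"))

  invisible(list(discovery = discovery, summary = summary_tab,
                 features = feats, de = de, homology = homology,
                 synteny = synteny, traits = traits, manifest = manifest))
}
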