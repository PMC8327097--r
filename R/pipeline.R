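## End-to-end driver: configuration, provenance-stamped TSV artifacts, and
## stage chaining on simulated or file-based inputs.

.writeTsv <- function(df, path, stage, params) {
  hdr <- sprintf("# ovisweep %s | stage=%s | %s",
                 as.character(utils::packageVersion("ovisweep")), stage,
                 paste(names(params), unname(params), sep = "=",
                       collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.asComparisons <- function(x, pops) {
  if (is.null(x)) {
    if (length(pops) < 2L) stop("need >= 2 populations for comparisons")
    cmb <- utils::combn(sort(pops), 2L)
    x <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  for (cmp in x)
    if (!all(cmp %in% pops))
      stop("comparison names unknown population: ",
           paste(setdiff(cmp, pops), collapse = ", "))
  x
}

#' Run the full analysis pipeline
#'
#' Chains the stages — input (simulation or PED/MAP + phased VCF), sample
#' and variant QC, relatedness pruning, diversity, ROH/F_ROH/islands, LD
#' pruning + PCA/NJ, LD decay + N_E, windowed F_ST scan, XP-EHH scan, and
#' consensus candidate calling — writing one provenance-stamped TSV per
#' stage under `out_dir`.  Deterministic given `seed`.
#'
#' @param config a named list or path to a YAML file.  Keys: either
#'   `simulate` (arguments of [simConfig()], plus optional `sweep` spec for
#'   [injectSweep()]) or `ped`/`map` (and optionally `vcf` for haplotype
#'   stages); optional `comparisons` (list of label pairs; default all
#'   pairs), `qc`, `roh`, `scan` parameter blocks, `gene_bed`.
#' @param seed integer seed driving every stochastic stage
#' @param out_dir output directory (created)
#' @param stages subset of stages to run (default all)
#' @return invisibly, a manifest list of stage outputs and parameters
#' @export
runPipeline <- function(config, seed = 1L, out_dir,
                        stages = c("qc", "diversity", "roh", "ldne",
                                   "structure", "fst", "xpehh",
                                   "consensus")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, config = config,
                   version = as.character(utils::packageVersion("ovisweep")))

  ## ---- input ---------------------------------------------------------------
  hs <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$sweep <- NULL
    sim_args$rng_seed <- seed
    cfg <- do.call(simConfig, sim_args)
    sim <- simulateDivergentPops(cfg)
    ds <- sim$genotypes; hs <- sim$haplotypes
    if (!is.null(config$simulate$sweep)) {
      hs <- injectSweep(hs, config$simulate$sweep, seed = seed + 1L)
      ds <- genotypesFromHaps(hs)
    }
  } else if (!is.null(config$ped) && !is.null(config$map)) {
    ds <- readPlinkText(config$ped, config$map)
    if (!is.null(config$vcf)) hs <- readVcfPhased(config$vcf)
    manifest$input_md5 <- tools::md5sum(c(config$ped, config$map,
                                          unlist(config$vcf)))
  } else stop("config must name either 'simulate' or 'ped'/'map' inputs")
  pops <- unique(unname(popLabels(ds)))
  comparisons <- .asComparisons(config$comparisons, pops)

  ## ---- qc ------------------------------------------------------------------
  thr <- do.call(qcThresholds, if (is.null(config$qc)) list() else config$qc)
  if ("qc" %in% stages) {
    fs <- filterSamples(ds, thr)
    fv <- filterVariants(fs$dataset, thr)
    ds <- fv$dataset
    rel <- pihatMatrix(ds)
    pr <- relatednessPrune(rel, thr$pihat_cutoff,
                           .missingFraction(genotypes(ds), 2L))
    ds <- ds[, match(pr$kept, sampleIds(ds))]
    if (!is.null(hs)) hs <- hs[, colData(hs)$sample_id %in% pr$kept]
    .writeTsv(pihatReport(rel, thr$pihat_window),
              file.path(out_dir, "qc_pihat.tsv"), "qc",
              list(cutoff = thr$pihat_cutoff))
    .writeTsv(data.frame(rule = c("samples_removed", "variants_call_rate",
                                  "variants_maf", "variants_hwe",
                                  "samples_related_removed"),
                         n = c(length(fs$report$removed_ids),
                               fv$report$removed_call_rate,
                               fv$report$removed_maf,
                               fv$report$removed_hwe,
                               length(pr$removed))),
              file.path(out_dir, "qc_report.tsv"), "qc",
              thr[c("max_sample_missing", "min_snp_call_rate",
                    "hwe_p_min", "maf_min")])
    manifest$qc <- list(n_samples = nSamples(ds), n_variants = nVariants(ds))
  }

  ## ---- diversity -----------------------------------------------------------
  if ("diversity" %in% stages) {
    div <- hetStats(ds)
    .writeTsv(div$per_population, file.path(out_dir, "diversity.tsv"),
              "diversity", list(he_sd_axis = attr(div$per_population,
                                                  "he_sd_axis")))
    manifest$diversity <- div$per_population
  }

  ## ---- roh -----------------------------------------------------------------
  roh_regions <- genomicIntervals(character(0), integer(0), integer(0))
  if ("roh" %in% stages) {
    rp <- do.call(rohParams,
                  if (is.null(config$roh)) list() else config$roh)
    segs <- detectRoh(ds, rp)
    .writeTsv(segs, file.path(out_dir, "roh_segments.tsv"), "roh",
              rp[c("min_length_bp", "min_consecutive_snps")])
    .writeTsv(froh(segs, sampleIds(ds)),
              file.path(out_dir, "roh_froh.tsv"), "roh",
              list(autosome_length_bp = 2.45e9))
    pls <- popLabels(ds)
    island_list <- list()
    for (p in pops) {
      grp <- names(pls)[pls == p]
      if (length(grp) < 2L) next
      island_list[[p]] <- rohIslands(segs, grp, ds, group_name = p)
    }
    for (p in names(island_list)) {
      others <- suppressWarnings(
        do.call(c, unname(island_list[setdiff(names(island_list), p)])))
      priv <- if (length(others)) privateIslands(island_list[[p]], others)
              else island_list[[p]]
      if (length(priv)) {
        mcols(priv)$comparison <- p
        roh_regions <- suppressWarnings(
          c(roh_regions, priv[, c("method", "comparison")]))
      }
    }
    writeBed(roh_regions, file.path(out_dir, "roh_private_islands.bed"))
    manifest$roh <- list(n_segments = nrow(segs),
                         n_private_islands = length(roh_regions))
  }

  ## ---- ld / ne -------------------------------------------------------------
  if ("ldne" %in% stages) {
    pairs <- pairwiseR2(ds, thin_to = 200000L, seed = seed)
    decay <- ldDecay(pairs, seq(0, 5e6, by = 2.5e5))
    .writeTsv(decay, file.path(out_dir, "ld_decay.tsv"), "ldne",
              list(max_dist_bp = 5e6))
    ne <- neTrajectory(pairs)
    .writeTsv(ne, file.path(out_dir, "ne_trajectory.tsv"), "ldne",
              list(tolerance = 0.1))
    manifest$ldne <- list(n_pairs = nrow(pairs))
  }

  ## ---- structure -----------------------------------------------------------
  if ("structure" %in% stages) {
    pruned <- ldPrune(ds, thr$ld_window_kb, thr$ld_step_kb, thr$ld_r2_max)
    pca <- pcaGenotypes(pruned$dataset, k = min(10L, nSamples(ds) - 1L))
    .writeTsv(data.frame(sample_id = rownames(pca$coords),
                         population = pca$population, pca$coords),
              file.path(out_dir, "pca_coords.tsv"), "structure",
              list(scaling = "patterson"))
    if (length(pops) >= 3L) {
      fstm <- pairwiseFstMatrix(pruned$dataset)
      njNewick(njTree(fstm$theta), file.path(out_dir, "nj_fst.nwk"))
    }
    manifest$structure <- list(var_frac = pca$var_frac,
                               n_pruned = length(pruned$removed))
  }

  ## ---- selection scans -----------------------------------------------------
  scan_regions <- roh_regions
  scan_par <- config$scan
  if ("fst" %in% stages) {
    for (cmp in comparisons) {
      tag <- paste(cmp, collapse = "_vs_")
      sc <- windowFstScan(ds, cmp[1L], cmp[2L])
      .writeTsv(sc$windows,
                file.path(out_dir, sprintf("fst_windows_%s.tsv", tag)),
                "fst", list(window_bp = 2e5, step_bp = 6e4,
                            comparison = tag))
      scan_regions <- suppressWarnings(
        c(scan_regions, fstCandidateRegions(sc, tag)))
    }
  }
  if ("xpehh" %in% stages && !is.null(hs)) {
    for (cmp in comparisons) {
      tag <- paste(cmp, collapse = "_vs_")
      rec <- xpehhScan(subsetPop(hs, cmp[1L]), subsetPop(hs, cmp[2L]))
      .writeTsv(rec, file.path(out_dir, sprintf("xpehh_%s.tsv", tag)),
                "xpehh", list(p_threshold = 0.001, comparison = tag))
      sig <- significantRegions(rec, comparison = tag)
      if (length(sig)) scan_regions <- suppressWarnings(
        c(scan_regions, sig[, c("method", "comparison")]))
    }
  }

  ## ---- consensus -----------------------------------------------------------
  if ("consensus" %in% stages && length(scan_regions)) {
    cons <- consensusCandidates(scan_regions)
    if (!is.null(config$gene_bed)) {
      kept <- cons[cons$retained, , drop = FALSE]
      if (nrow(kept)) {
        ann <- annotateRegions(genomicIntervals(kept$chrom, kept$start_bp,
                                                kept$stop_bp),
                               config$gene_bed)
        cons <- merge(cons, ann, by = c("chrom", "start_bp", "stop_bp"),
                      all.x = TRUE)
      }
    }
    .writeTsv(cons, file.path(out_dir, "consensus_candidates.tsv"),
              "consensus", list(min_methods = 2, min_comparisons = 2,
                                mode = "or"))
    manifest$consensus <- cons
  }

  yaml::write_yaml(manifest[setdiff(names(manifest),
                                    c("diversity", "consensus"))],
                   file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
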