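#' Default pipeline configuration
#'
#' Assembles the configuration list consumed by \code{\link{runPipeline}}:
#' stage toggles, analysis thresholds and demonstration-scale synthetic
#' problem sizes. All randomness derives from \code{seed}.
#'
#' @param seed master integer seed.
#' @param out_dir output directory (created if absent).
#' @param stages character vector of stages to run, a subset of
#'   \code{c("synth", "survival", "de", "setcompare", "funcenrich",
#'   "motif", "motifenrich", "phenotype")}.
#' @return a named configuration list.
#' @export
pipelineConfig <- function(seed, out_dir,
                           stages = c("synth", "survival", "de",
                                      "setcompare", "funcenrich",
                                      "motif", "motifenrich",
                                      "phenotype")) {
  list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
       thresholds = list(fdr = 0.05, up = 1.50, down = 0.67,
                         min_frac = 0.80, alpha = 0.05, quantile = 0.90,
                         floor = log2(64)),
       sizes = list(
         cohort = list(
           list(label = "KO", n = 97, shape = 0.0055, rate = 2e-5),
           list(label = "Ct", n = 108, shape = 0.0080, rate = 2e-5)),
         n_genes = 2000L, n_sibling_probes = 200L, n_unexpressed = 500L,
         samples_per_group = 3L, planted_up = 50L, planted_down = 50L,
         effect_log2fc = 2, residual_sd = 0.25,
         n_experiments = 13L, concordance = 0.8,
         n_terms = 25L,
         n_promoter_genes = 150L, n_target_promoters = 40L,
         region_length = 500L, masked_fraction = 0.2,
         instances_per_gene = 2L, n_decoy_motifs = 4L))
}

configHash <- function(config) {
  config$out_dir <- NULL   # identity of the run, not its location
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  unname(tools::md5sum(tf))
}

stampLines <- function(config) {
  c(paste0("seed=", config$seed), paste0("config=", configHash(config)))
}

needStage <- function(config, stage, needed_by) {
  if (!stage %in% config$stages)
    stop("stage '", needed_by, "' requires upstream stage '", stage,
         "', which is disabled", call. = FALSE)
}

# a small fixed decoy PFM generator for the pipeline's motif dictionary
decoyPWMs <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    L <- sample(6:10, 1)
    pfm <- matrix(rpois(4 * L, 5), nrow = 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pfm[cbind(sample(1:4, L, replace = TRUE), 1:L)] <- 30
    buildPWM(pfm, id = sprintf("DECOY%02d", i), source_db = "custom")
  })
}

#' Run the integrated analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order — synthetic-data
#' generation, lifespan statistics, differential expression,
#' cross-experiment concordance, term overrepresentation, motif scanning,
#' motif enrichment, phenotype calculators — writing every artifact into
#' \code{config$out_dir} stamped with the seed and a configuration hash.
#' Reruns with the same configuration are byte-identical.
#'
#' @param config list from \code{\link{pipelineConfig}}.
#' @return invisibly, a named list of in-memory stage results.
#' @export
runPipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds; sz <- config$sizes
  stamp <- stampLines(config)
  out <- list()
  path <- function(f) file.path(config$out_dir, f)

  if ("synth" %in% config$stages) {
    out$survival_table <- genSurvivalCohort(sz$cohort, seed = config$seed)
    writeSurvivalTable(out$survival_table, path("survival.tsv"), stamp)
    es <- genExpressionStudy(
      n_genes = sz$n_genes, n_sibling_probes = sz$n_sibling_probes,
      n_unexpressed = sz$n_unexpressed,
      samples_per_group = sz$samples_per_group,
      planted_up = sz$planted_up, planted_down = sz$planted_down,
      effect_log2fc = sz$effect_log2fc, residual_sd = sz$residual_sd,
      floor = th$floor, seed = config$seed + 1L)
    out$study <- es$study; out$truth <- es$truth
    writeExpressionStudy(es$study, path("expression.tsv"),
                         path("design.tsv"), stamp)
  }

  if ("survival" %in% config$stages) {
    needStage(config, "synth", "survival")
    st <- out$survival_table
    grp <- survivalGroups(st)
    curves <- lapply(grp, function(g) kmEstimate(st, g))
    names(curves) <- grp
    for (g in grp)
      writeTsv(kmCoordinates(curves[[g]]), path(paste0("km_", g, ".tsv")),
               stamp)
    med <- vapply(curves, medianSurvival, numeric(1))
    lr <- logrankTest(st, grp[1], grp[2])
    ml <- maxlifeQuantileTest(st, grp[1], grp[2], quantile = th$quantile)
    out$survival_stats <- list(
      medians = as.list(med),
      percent_change = percentChange(med[[1]], med[[2]])$percent,
      logrank = list(chi2 = lr$chi2, df = lr$df, p = lr$p),
      maxlife = list(threshold_age = ml$threshold_age, p = ml$p,
                     percent_change_q90 = ml$percent_change_q90))
    jsonlite::write_json(c(list(seed = config$seed), out$survival_stats),
                         path("survival_stats.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  if ("de" %in% config$stages) {
    needStage(config, "synth", "de")
    de <- runDE(out$study, "A", "B", floor = th$floor, fdr = th$fdr,
                up = th$up, down = th$down)
    out$de <- de
    writeTsv(de$per_gene[, c("gene", "chosen_probe", "log2fc",
                             "fold_change", "t_mod", "p", "q", "class")],
             path("de_genes.tsv"), stamp)
    writeGMT(list(increased = de$increased, decreased = de$decreased),
             path("de_sets.gmt"))
  }

  if ("setcompare" %in% config$stages) {
    needStage(config, "de", "setcompare")
    universe <- out$de$per_gene$gene
    exps <- lapply(seq_len(sz$n_experiments), function(i)
      genRankedExperiment(universe, out$de$increased,
                          concordance = sz$concordance, direction = 1,
                          experiment_id = sprintf("CR%02d", i),
                          seed = config$seed + 100L + i))
    names(exps) <- sprintf("CR%02d", seq_len(sz$n_experiments))
    scr <- concordanceScreen(list(increased = out$de$increased,
                                  decreased = out$de$decreased),
                             exps, alpha = th$alpha,
                             directions = c(increased = 1, decreased = -1))
    out$concordance <- scr
    writeTsv(scr$results, path("concordance.tsv"), stamp)
    jsonlite::write_json(c(list(seed = config$seed),
                           split(scr$tally$n_significant_concordant,
                                 scr$tally$set)),
                         path("concordance_tally.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("funcenrich" %in% config$stages) {
    needStage(config, "de", "funcenrich")
    bg <- setBackground(out$de)
    onto <- genToyOntology(sz$n_terms, seed = config$seed + 200L,
                           genes = out$de$per_gene$gene)
    out$terms <- conditionalWalk(onto$dag, out$de$increased,
                                 c(bg, out$de$increased),
                                 alpha = th$alpha)
    writeTsv(out$terms, path("term_results.tsv"), stamp)
  }

  if ("motif" %in% config$stages) {
    needStage(config, "de", "motif")
    planted_pwm <- buildPWM(
      matrix(c(20, 0, 0, 0,  0, 0, 0, 20,  0, 0, 0, 20,  20, 0, 0, 0,
               20, 0, 0, 0,  0, 0, 0, 20), nrow = 4,
             dimnames = list(c("A", "C", "G", "T"), NULL)),
      id = "PLANTED", source_db = "custom")
    out$dictionary <- c(list(planted_pwm),
                        decoyPWMs(sz$n_decoy_motifs, config$seed + 300L))
    names(out$dictionary) <-
      vapply(out$dictionary, function(p) p@id, character(1))
    genes_prom <- head(out$de$per_gene$gene, sz$n_promoter_genes)
    prom <- genPromoterSet(planted_pwm, n_genes = sz$n_promoter_genes,
                           n_target = sz$n_target_promoters,
                           region_length = sz$region_length,
                           masked_fraction = sz$masked_fraction,
                           instances_per_gene = sz$instances_per_gene,
                           seed = config$seed + 301L)
    names(prom$sequences) <- genes_prom
    prom$truth$gene <- genes_prom
    out$promoters <- prom
    writeMaskedFasta(prom$sequences, path("promoters.fa"))
    writePFMs(out$dictionary, path("motifs.pfm"))
    out$counts <- countTable(prom$sequences, out$dictionary,
                             min_frac = th$min_frac)
    writeTsv(out$counts, path("motif_counts.tsv"), stamp)
  }

  if ("motifenrich" %in% config$stages) {
    needStage(config, "motif", "motifenrich")
    target <- prom_target <- out$promoters$truth$gene[out$promoters$truth$is_target]
    bg <- setdiff(out$promoters$truth$gene, target)
    out$motif_enrichment <- screenDictionary(out$counts, target, bg,
                                             min_per_class = 20L)
    writeTsv(out$motif_enrichment, path("motif_enrichment.tsv"), stamp)
  }

  if ("phenotype" %in% config$stages) {
    plate <- genQpcrPlate(c("Sult2a2", "Igf1"), log2fc = c(10, -3),
                          seed = config$seed + 400L)
    writeQpcrTable(plate, path("qpcr.tsv"))
    out$phenotype <- list(
      fold_induction = foldInduction(plate),
      homa_ir_example = homaIR(100, 10),
      rq_example = respiratoryQuotient(0.7, 1.0))
    writeTsv(out$phenotype$fold_induction, path("fold_induction.tsv"),
             stamp)
  }

  invisible(out)
}
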