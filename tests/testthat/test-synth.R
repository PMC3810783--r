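test_that("survival cohorts honour censoring flags and seeds", {
  spec <- list(list(label = "A", n = 50, shape = 0.005, rate = 1e-4),
               list(label = "B", n = 50, shape = 0.005, rate = 1e-4,
                    censor_fraction = 0.2))
  st1 <- genSurvivalCohort(spec, seed = 7)
  st2 <- genSurvivalCohort(spec, seed = 7)
  expect_identical(survivalData(st1), survivalData(st2))
  d <- survivalData(st1)
  expect_true(all(d$event[d$group == "A"] == 1L))
  expect_equal(sum(d$event[d$group == "B"] == 0L), 10)
  # censoring times precede the (unobserved) death times by construction
  expect_true(all(d$time > 0))
  expect_error(genSurvivalCohort(list(list(label = "A", n = 5,
                                           shape = 0.01, rate = -1)),
                                 seed = 1), "rate")
})

test_that("identical group specs give exchangeable lifespan distributions", {
  rejections <- 0L
  for (r in 1:100) {
    st <- genSurvivalCohort(list(
      list(label = "A", n = 40, shape = 0.006, rate = 5e-5),
      list(label = "B", n = 40, shape = 0.006, rate = 5e-5)),
      seed = 5000 + r)
    d <- survivalData(st)
    p <- wilcox.test(d$time[d$group == "A"], d$time[d$group == "B"])$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  # nominal rejection rate 1%; allow ordinary binomial variation
  expect_lte(rejections, 4L)
})

test_that("the zero-shape limit of the lifespan law is exponential", {
  st <- genSurvivalCohort(list(list(label = "A", n = 5000, shape = 0,
                                    rate = 1 / 300)), seed = 9)
  tm <- survivalData(st)$time
  expect_gt(ks.test(tm, "pexp", rate = 1 / 300)$p.value, 0.01)
})

test_that("null expression studies carry no planted truth", {
  es <- genExpressionStudy(n_genes = 300, planted_up = 0, planted_down = 0,
                           effect_log2fc = 0, residual_sd = 0.3, seed = 2)
  expect_equal(nrow(es$truth), 0)
  m <- exprMatrix(es$study)
  grp <- sampleGroups(es$study)
  diffs <- rowMeans(m[, grp == "A"]) - rowMeans(m[, grp == "B"])
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("expression generation is deterministic and validated", {
  a <- genExpressionStudy(n_genes = 100, n_sibling_probes = 10,
                          planted_up = 5, seed = 3)
  b <- genExpressionStudy(n_genes = 100, n_sibling_probes = 10,
                          planted_up = 5, seed = 3)
  expect_identical(exprMatrix(a$study), exprMatrix(b$study))
  expect_identical(a$truth, b$truth)
  expect_error(genExpressionStudy(n_genes = 10, planted_up = 8,
                                  planted_down = 8, seed = 1),
               "exceeds")
  # sibling probes share their host gene's symbol
  map <- probeGeneMap(a$study)
  sib <- grepl("_s_at$", names(map))
  expect_true(all(map[sib] %in% map[!sib]))
})

test_that("promoter planting respects masking and target membership", {
  cons <- consensusPWM("TTGACA")
  prom <- genPromoterSet(cons, n_genes = 30, n_target = 10,
                         region_length = 300, masked_fraction = 0.3,
                         instances_per_gene = 1, seed = 4)
  expect_length(prom$sequences, 30)
  expect_true(all(nchar(prom$sequences) == 300))
  # every target gene scans at least one planted consensus instance
  for (g in prom$truth$gene[prom$truth$is_target]) {
    expect_gte(scanRegion(prom$sequences[[g]], cons)$count, 1)
  }
  # fully masked regions have no eligible windows
  prom2 <- genPromoterSet(cons, n_genes = 5, n_target = 0,
                          region_length = 100, masked_fraction = 1,
                          seed = 5)
  for (s in prom2$sequences) {
    expect_equal(scanRegion(s, cons)$scanned_length, 0)
  }
  expect_error(genPromoterSet(cons, n_genes = 2, n_target = 1,
                              region_length = 5, seed = 1),
               "at least the motif length")
})

test_that("planted instances raise target counts by the planted amount", {
  cons <- consensusPWM("TTGACAGT")
  prom <- genPromoterSet(cons, n_genes = 400, n_target = 200,
                         region_length = 400, masked_fraction = 0,
                         instances_per_gene = 3, seed = 6)
  ct <- countTable(prom$sequences, list(cons))
  tgt <- ct$count[ct$gene %in% prom$truth$gene[prom$truth$is_target]]
  bgd <- ct$count[!ct$gene %in% prom$truth$gene[prom$truth$is_target]]
  # background hits are vanishingly rare for an 8-mer; difference ~ 3
  expect_equal(mean(tgt) - mean(bgd), 3, tolerance = 0.15)
})

test_that("toy ontology generation is seeded and acyclic", {
  a <- genToyOntology(12, 40, seed = 8)
  b <- genToyOntology(12, 40, seed = 8)
  expect_identical(a$edges, b$edges)
  expect_identical(a$annotations, b$annotations)
  # every direct annotation reaches the root by propagation
  root_genes <- termGenes(a$dag, "T0001")
  expect_true(all(unique(a$annotations$gene) %in%
                    unique(unlist(a$dag@annotations))))
  # a gene annotated to a term appears in every ancestor's list
  g1 <- a$annotations$gene[1]; t1 <- a$annotations$term[1]
  expect_true(g1 %in% termGenes(a$dag, t1))
})

test_that("qPCR plates are seeded and recover planted folds", {
  a <- genQpcrPlate(c("X", "Y"), log2fc = c(4, -2), seed = 10)
  b <- genQpcrPlate(c("X", "Y"), log2fc = c(4, -2), seed = 10)
  expect_identical(a, b)
  fi <- foldInduction(a)
  expect_equal(log2(fi$fold[fi$gene == "X"]), 4, tolerance = 0.2)
  expect_equal(log2(fi$fold[fi$gene == "Y"]), -2, tolerance = 0.2)
})

test_that("zero-concordance ranked experiments are null for enrichment", {
  set.seed(11)
  g <- sprintf("g%04d", 1:600)
  set <- sample(g, 60)
  ps <- vapply(1:200, function(i) {
    rl <- genRankedExperiment(g, set, concordance = 0, seed = 7000 + i)
    rankEnrichment(set, rl)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("motif dictionary pooling respects per-source counts", {
  dict <- genMotifDictionary(5, 7, 11, seed = 12)
  expect_length(dict, 23)
  src <- vapply(dict, function(p) p@source_db, character(1))
  expect_equal(as.vector(table(src)[c("jaspar-like", "uniprobe-like",
                                      "transfac-like")]),
               c(5, 7, 11))
  expect_true(all(vapply(dict, pwmLength, numeric(1)) >= 4))
})
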