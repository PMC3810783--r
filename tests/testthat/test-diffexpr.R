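makeStudy <- function(m, genes = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  ExpressionStudy(m, setNames(genes, rownames(m)),
                  rep(c("A", "B"), each = ncol(m) / 2))
}

test_that("detection filter retains by floor and sample count", {
  set.seed(1)
  m <- matrix(rnorm(40, mean = 8), nrow = 10)
  st <- makeStudy(m)
  expect_length(detectionFilter(st, floor = -Inf), 10)
  expect_length(detectionFilter(st, floor = 6, min_samples = 5), 0)
  m[1, ] <- 2   # below floor everywhere
  expect_length(detectionFilter(makeStudy(m), floor = 6), 9)
})

test_that("moderated t with zero prior df is the ordinary t-test", {
  set.seed(2)
  m <- matrix(rnorm(60, mean = 8, sd = runif(10, 0.1, 1)), nrow = 10)
  st <- makeStudy(m)
  res <- moderatedT(st, "A", "B", prior_df = 0)
  for (i in 1:10) {
    tt <- t.test(m[i, 1:3], m[i, 4:6], var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t with infinite prior df shares one variance", {
  set.seed(3)
  m <- matrix(rnorm(120, mean = 8, sd = 0.5), nrow = 20)
  st <- makeStudy(m)
  res <- moderatedT(st, "A", "B", prior_df = Inf)
  s0 <- sqrt(attr(res, "s0_2"))
  expect_equal(res$t_mod, res$log2fc / (s0 * sqrt(1/3 + 1/3)),
               tolerance = 1e-12)
  # all probes use the same denominator
  denom <- res$log2fc / res$t_mod
  expect_lt(diff(range(denom)), 1e-12)
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(4)
  m <- matrix(rnorm(3000, mean = 8, sd = rep(runif(500, 0.1, 0.8), 6)),
              nrow = 500)
  rownames(m) <- sprintf("p%03d", 1:500)
  colnames(m) <- sprintf("s%d", 1:6)
  st <- makeStudy(m)
  res <- moderatedT(st, "A", "B")
  design <- cbind(1, rep(c(1, 0), each = 3))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_2"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("swapping group labels negates effects and keeps p", {
  set.seed(5)
  st <- makeStudy(matrix(rnorm(90, 8), nrow = 15))
  ab <- moderatedT(st, "A", "B")
  ba <- moderatedT(st, "B", "A")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$t_mod, -ba$t_mod)
  expect_equal(ab$p, ba$p)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  set.seed(6)
  p <- runif(50)
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.1, -0.1)), "\\[0, 1\\]")
})

test_that("probe collapse keeps the minimum-p probe with stated tie-breaks", {
  pp <- data.frame(probe = c("a1", "a2", "b1", "c1", "c2"),
                   log2fc = c(1.0, 2.0, 0.5, 1.2, 2.0),
                   t_mod = 1, p = c(0.5, 0.01, 0.2, 0.04, 0.04),
                   stringsAsFactors = FALSE)
  map <- c(a1 = "gA", a2 = "gA", b1 = "gB", c1 = "gC", c2 = "gC")
  out <- collapseProbes(pp, map)
  expect_equal(nrow(out), 3)
  expect_equal(out$chosen_probe[out$gene == "gA"], "a2")   # min p
  expect_equal(out$chosen_probe[out$gene == "gB"], "b1")   # identity
  expect_equal(out$chosen_probe[out$gene == "gC"], "c2")   # tie: larger |fc|
  # exact tie on p and |fc| falls back to probe id
  pp2 <- data.frame(probe = c("z2", "z1"), log2fc = c(1, 1), t_mod = 1,
                    p = c(0.1, 0.1), stringsAsFactors = FALSE)
  expect_equal(collapseProbes(pp2, c(z1 = "g", z2 = "g"))$chosen_probe, "z1")
  # unmapped probes dropped with a message
  expect_message(collapseProbes(pp, map[-1]), "no gene mapping")
})

test_that("classification applies FDR and fold-change jointly", {
  pg <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   log2fc = c(log2(1.6), log2(1.4), log2(0.5), log2(0.6)),
                   q = c(0.04, 0.04, 0.04, 0.2), stringsAsFactors = FALSE)
  out <- classifyGenes(pg)
  expect_equal(out$class, c("increased", "unchanged", "decreased",
                            "unchanged"))
  expect_equal(out$fold_change, 2^pg$log2fc)
})

test_that("increased and decreased partitions are disjoint and complete", {
  set.seed(8)
  es <- genExpressionStudy(n_genes = 400, planted_up = 20,
                           planted_down = 20, effect_log2fc = 2,
                           residual_sd = 0.3, seed = 8)
  de <- runDE(es$study, "A", "B")
  expect_length(intersect(de$increased, de$decreased), 0)
  pg <- de$per_gene
  n_called <- sum(pg$q < 0.05 & (pg$fold_change > 1.5 | pg$fold_change < 0.67))
  expect_equal(length(de$increased) + length(de$decreased), n_called)
})
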