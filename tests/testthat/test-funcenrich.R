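test_that("hypergeometric tail matches enumeration and normalizes", {
  expect_equal(hypergeomTail(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(hypergeomTail(0, 7, 9, 25), 1)
  # pmf sums to one over the support
  ks <- 0:7
  pmf <- vapply(ks, oracleHyperPmf, numeric(1), K = 7, n = 9, N = 25)
  expect_equal(sum(pmf), 1)
  # random configurations against the summation oracle
  set.seed(21)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeomTail(k, K, n, N), oracleHyperTail(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeomTail(6, 5, 5, 20), "inconsistent")
  expect_error(hypergeomTail(2, 25, 5, 20), "inconsistent")
})

flatDag <- function(genes_per_term) {
  terms <- names(genes_per_term)
  ann <- do.call(rbind, lapply(terms, function(tm)
    data.frame(gene = genes_per_term[[tm]], term = tm,
               stringsAsFactors = FALSE)))
  TermDAG(data.frame(child = character(), parent = character()),
          ann, terms = terms)
}

test_that("flat DAG reduces to the unconditional test", {
  genes <- sprintf("g%02d", 1:30)
  dag <- flatDag(list(T1 = genes[1:10], T2 = genes[5:20]))
  set <- genes[1:8]
  res <- conditionalWalk(dag, set, genes)
  expect_equal(res$p[res$term == "T1"],
               hypergeomTail(8, 10, 8, 30))
  expect_equal(res$p[res$term == "T2"],
               hypergeomTail(length(intersect(set, genes[5:20])), 16, 8, 30))
  expect_equal(res$conditioned_on, c("", ""))
})

test_that("a significant child absorbs its parent's signal", {
  genes <- sprintf("g%02d", 1:30)
  # leaf L carries the enriched genes; parent P adds only background genes
  edges <- data.frame(child = c("L", "P"), parent = c("P", "R"),
                      stringsAsFactors = FALSE)
  ann <- rbind(
    data.frame(gene = genes[1:8], term = "L", stringsAsFactors = FALSE),
    data.frame(gene = genes[9:14], term = "P", stringsAsFactors = FALSE),
    data.frame(gene = genes, term = "R", stringsAsFactors = FALSE))
  dag <- TermDAG(edges, ann)
  set <- genes[1:7]
  res <- conditionalWalk(dag, set, genes)
  p_leaf <- res$p[res$term == "L"]
  p_parent_cond <- res$p[res$term == "P"]
  p_parent_uncond <- hypergeomTail(7, 14, 7, 30)
  expect_lt(p_leaf, 0.05)
  expect_equal(res$conditioned_on[res$term == "P"], "L")
  expect_gt(p_parent_cond, p_parent_uncond)
  # root term annotated to every background gene is never enriched
  expect_equal(res$p[res$term == "R"], 1)
})

test_that("a planted enriched leaf ranks first across seeds", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    onto <- genToyOntology(8, 60, seed = s)
    genes <- sprintf("g%05d", 1:60)
    # pick a genuine leaf and plant the set inside it
    leaves <- setdiff(onto$dag@terms, onto$edges$parent)
    leaf <- leaves[1]
    extra <- data.frame(gene = genes[1:10], term = leaf,
                        stringsAsFactors = FALSE)
    dag <- TermDAG(onto$edges, rbind(onto$annotations, extra),
                   terms = onto$dag@terms)
    res <- conditionalWalk(dag, genes[1:10], genes)
    if (nrow(res) && res$term[1] == leaf) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("annotation propagation follows the true-path rule", {
  edges <- data.frame(child = c("B", "C"), parent = c("A", "B"),
                      stringsAsFactors = FALSE)
  ann <- data.frame(gene = "g1", term = "C", stringsAsFactors = FALSE)
  dag <- TermDAG(edges, ann)
  expect_equal(termGenes(dag, "C"), "g1")
  expect_equal(termGenes(dag, "B"), "g1")
  expect_equal(termGenes(dag, "A"), "g1")
  # cycles rejected
  bad <- data.frame(child = c("A", "B"), parent = c("B", "A"),
                    stringsAsFactors = FALSE)
  expect_error(TermDAG(bad, ann), "acyclic")
})

test_that("background construction excludes DE genes", {
  pg <- data.frame(gene = sprintf("g%05d", 1:100),
                   class = c(rep("increased", 5), rep("decreased", 5),
                             rep("unchanged", 90)),
                   stringsAsFactors = FALSE)
  expect_message(bg <- setBackground(pg), "90")
  expect_length(bg, 90)
  pg$class <- "unchanged"
  expect_length(suppressMessages(setBackground(pg)), 100)
  pg$class <- "increased"
  expect_error(suppressMessages(setBackground(pg)), "empty background")
})
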