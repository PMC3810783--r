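#' Upper hypergeometric tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n genes from a
#' background of N of which K carry the term, the probability of seeing k
#' or more carriers.
#'
#' @param k observed carriers in the drawn set (0 <= k <= min(K, n)).
#' @param K background genes carrying the term.
#' @param n drawn set size.
#' @param N background size.
#' @return tail probability in (0, 1].
#' @export
hypergeomTail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n); K, n <= N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Conditional hypergeometric walk over a term DAG
#'
#' Term overrepresentation of a gene set against a background, processed
#' children-before-parents: when a parent term is tested, genes annotated
#' to any of its already-significant direct children (raw p < alpha) are
#' removed from both the set count k and the background count K, so a
#' parent is only called enriched on signal its significant children do
#' not already explain. Terms with fewer than \code{min_K} background
#' carriers are skipped as untestable.
#'
#' @param dag a \code{\link{TermDAG}} (annotations already propagated).
#' @param set character vector of genes (must be within the background).
#' @param background character vector: the gene universe (e.g. expressed,
#'   non-differential genes plus the set).
#' @param alpha child-significance level used for conditioning
#'   (raw p, no FDR inside the walk; default 0.05).
#' @param min_K minimum background carriers for a testable term (default 3).
#' @return data.frame sorted by p: \code{term}, \code{name}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{p}, \code{q} (BH across tested
#'   terms), \code{conditioned_on} (comma-joined child ids removed).
#' @export
conditionalWalk <- function(dag, set, background, alpha = 0.05, min_K = 3L) {
  stopifnot(is(dag, "TermDAG"))
  set <- unique(as.character(set))
  background <- unique(as.character(background))
  if (!all(set %in% background))
    stop("set must be a subset of the background")
  g <- igraph::graph_from_data_frame(
    if (nrow(dag@edges)) dag@edges[, c("child", "parent")] else
      data.frame(child = character(), parent = character()),
    vertices = dag@terms)
  ord <- names(igraph::topo_sort(g, mode = "out"))  # children first
  N <- length(background)
  n <- length(set)
  sig <- character()
  rows <- list()
  for (tm in ord) {
    genes <- intersect(termGenes(dag, tm), background)
    cond_children <- intersect(termChildren(dag, tm), sig)
    removed <- if (length(cond_children))
      unique(unlist(lapply(cond_children, function(ch)
        intersect(termGenes(dag, ch), background)))) else character()
    genes_c <- setdiff(genes, removed)
    K <- length(genes_c)
    if (K < min_K) next
    k <- length(intersect(genes_c, set))
    p <- hypergeomTail(k, K, n, N)
    if (p < alpha) sig <- c(sig, tm)
    rows[[tm]] <- data.frame(
      term = tm, name = unname(dag@term_names[tm]), k = k, K = K,
      n = n, N = N, p = p,
      conditioned_on = paste(cond_children, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(term = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      conditioned_on = character()))
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$q <- bhAdjust(res$p)
  res[order(res$p, res$term), , drop = FALSE]
}

#' Background set for enrichment: expressed genes minus DE genes
#'
#' The overrepresentation background contains only expressed genes not
#' themselves identified as differentially expressed (e.g. 13,201
#' expressed genes minus 365 DE genes leaves a 12,836-gene background).
#'
#' @param de a \code{DEResult} from \code{\link{runDE}}, or a classified
#'   per-gene data.frame with \code{gene} and \code{class} columns.
#' @return character vector of background gene ids.
#' @export
setBackground <- function(de) {
  pg <- if (inherits(de, "DEResult")) de$per_gene else de
  stopifnot(all(c("gene", "class") %in% names(pg)))
  bg <- pg$gene[pg$class == "unchanged"]
  if (length(bg) == 0)
    stop("every expressed gene is differentially expressed: empty background")
  message("background of ", length(bg), " expressed, non-DE genes")
  bg
}
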