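#' Build a ranked list from (gene, score) pairs
#'
#' Ranks are assigned 1..n by descending score; score ties are broken by
#' gene id so that the ranking is deterministic. Genes must be unique.
#'
#' @param genes character vector of gene ids.
#' @param scores signed scores (e.g. log fold changes), same length.
#' @param experiment_id optional label.
#' @return data.frame of class \code{"RankedList"} with columns
#'   \code{gene}, \code{score}, \code{rank}.
#' @export
rankedList <- function(genes, scores, experiment_id = "experiment") {
  stopifnot(length(genes) == length(scores), !anyDuplicated(genes),
            all(is.finite(scores)))
  o <- order(-scores, genes)
  out <- data.frame(gene = as.character(genes)[o], score = scores[o],
                    rank = seq_along(genes), stringsAsFactors = FALSE)
  attr(out, "experiment_id") <- experiment_id
  class(out) <- c("RankedList", "data.frame")
  out
}

#' Rank-based gene-set enrichment (Wilcoxon rank-sum)
#'
#' Tests whether a gene set occupies systematically high or low positions
#' in another experiment's fold-change ordering, by a Wilcoxon rank-sum
#' comparison of set-member scores versus non-member scores. The exact
#' rank-sum distribution is used when the smaller group has at most 10
#' genes and scores are tie-free; otherwise the normal approximation with
#' tie correction. The standardized statistic is positive when set members
#' have higher scores.
#'
#' Set genes absent from the list are dropped (platforms differ between
#' experiments); \code{n_set_in_list} records how many remained. When the
#' set misses the list entirely, or covers it with no complement left,
#' the result is flagged not evaluable.
#'
#' @param set character vector of gene ids.
#' @param list a \code{\link{rankedList}} (or data.frame with \code{gene},
#'   \code{score}).
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (set biased toward high scores) or \code{"less"}.
#' @return list of class \code{"RankEnrichmentResult"}: \code{statistic}
#'   (standardized Z), \code{p}, \code{n_set_in_list}, \code{n_list},
#'   \code{evaluable}, \code{exact}.
#' @export
rankEnrichment <- function(set, list, alternative = c("two.sided",
                                                      "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(list), all(c("gene", "score") %in% names(list)))
  member <- list$gene %in% set
  n1 <- sum(member); n2 <- sum(!member)
  out <- list(statistic = NA_real_, p = NA_real_, n_set_in_list = n1,
              n_list = nrow(list), evaluable = FALSE, exact = FALSE)
  class(out) <- "RankEnrichmentResult"
  if (n1 == 0 || n2 == 0) return(out)
  r <- rank(list$score)        # midranks; ascending, so members-high => large
  W <- sum(r[member])          # rank-sum of set members
  ties <- table(r)
  has_ties <- any(ties > 1)
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  if (min(n1, n2) <= 10 && !has_ties) {
    U <- W - n1 * (n1 + 1) / 2
    p_le <- pwilcox(U, n1, n2)
    p_ge <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    out$exact <- TRUE
  } else {
    p <- switch(alternative,
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z),
                two.sided = 2 * pnorm(-abs(z)))
  }
  out$statistic <- z
  out$p <- max(p, .Machine$double.xmin)
  out$evaluable <- TRUE
  out
}

#' @export
print.RankEnrichmentResult <- function(x, ...) {
  if (!x$evaluable) {
    cat("rank enrichment: not evaluable (set/list overlap degenerate)\n")
  } else {
    cat(sprintf("rank enrichment: Z = %+.3f, p = %.4g (%s; %d of %d genes in set)\n",
                x$statistic, x$p, if (x$exact) "exact" else "normal approx.",
                x$n_set_in_list, x$n_list))
  }
  invisible(x)
}

#' Concordance screen of gene sets across ranked experiments
#'
#' Runs \code{\link{rankEnrichment}} for every (set, experiment) pair and
#' tallies, per set, how many experiments are significant at \code{alpha}
#' with the enrichment sign matching the set's stated direction ("k of m
#' significant"). This mirrors the cross-experiment concordance question:
#' in how many independent intervention experiments does a
#' response-gene set shift the way it did in the index study?
#'
#' @param sets named list of character gene-id vectors.
#' @param experiments named list of \code{\link{rankedList}} objects.
#' @param alpha significance level for the tally (default 0.05).
#' @param directions named numeric vector (+1 / -1) per set: the sign the
#'   set's genes are expected to move; defaults to +1 for every set.
#' @return list of class \code{"ConcordanceScreen"}: \code{results}
#'   (long data.frame set x experiment with statistic, p, sign_match),
#'   \code{tally} (data.frame per set: n_significant_concordant, n_experiments).
#' @export
concordanceScreen <- function(sets, experiments, alpha = 0.05,
                              directions = NULL) {
  stopifnot(length(experiments) >= 1, length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  if (is.null(names(experiments)))
    names(experiments) <- paste0("exp", seq_along(experiments))
  if (is.null(directions))
    directions <- setNames(rep(1, length(sets)), names(sets))
  rows <- list()
  for (s in names(sets)) {
    for (ei in seq_along(experiments)) {
      e <- names(experiments)[ei]
      r <- rankEnrichment(sets[[s]], experiments[[ei]])
      rows[[length(rows) + 1L]] <- data.frame(
        set = s, experiment = e, statistic = r$statistic, p = r$p,
        n_set_in_list = r$n_set_in_list, evaluable = r$evaluable,
        significant = r$evaluable && r$p < alpha,
        sign_match = r$evaluable && sign(r$statistic) == sign(directions[[s]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tally <- do.call(rbind, lapply(names(sets), function(s) {
    sub <- res[res$set == s, ]
    data.frame(set = s,
               n_significant_concordant = sum(sub$significant & sub$sign_match),
               n_experiments = nrow(sub), stringsAsFactors = FALSE)
  }))
  out <- list(results = res, tally = tally, alpha = alpha)
  class(out) <- "ConcordanceScreen"
  out
}

#' @export
print.ConcordanceScreen <- function(x, ...) {
  for (i in seq_len(nrow(x$tally))) {
    cat(sprintf("set '%s': %d of %d experiments significant (p < %g) with concordant sign\n",
                x$tally$set[i], x$tally$n_significant_concordant[i],
                x$tally$n_experiments[i], x$alpha))
  }
  invisible(x)
}

#' Overlap region counts and hypergeometric overlap tests
#'
#' For k gene sets inside a stated universe, counts all 2^k - 1
#' membership regions (Venn regions) and tests each pairwise overlap with
#' an upper hypergeometric tail against the universe.
#'
#' @param sets named list of character gene-id vectors.
#' @param universe character vector containing every set gene.
#' @return list: \code{regions} (data.frame of membership pattern and
#'   count), \code{pairwise} (data.frame set1, set2, overlap, p).
#' @export
overlapCounts <- function(sets, universe) {
  stopifnot(length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  allg <- unique(unlist(sets))
  if (!all(allg %in% universe))
    stop("set gene(s) outside the stated universe")
  k <- length(sets)
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  patterns$count <- apply(patterns, 1, function(p) {
    sum(rowSums(member == matrix(as.logical(p), nrow = length(universe),
                                 ncol = k, byrow = TRUE)) == k)
  })
  pw <- list()
  N <- length(universe)
  cmb <- utils::combn(names(sets), 2)
  for (j in seq_len(ncol(cmb))) {
    a <- cmb[1, j]; b <- cmb[2, j]
    ov <- length(intersect(sets[[a]], sets[[b]]))
    p <- phyper(ov - 1, length(sets[[a]]), N - length(sets[[a]]),
                length(sets[[b]]), lower.tail = FALSE)
    pw[[j]] <- data.frame(set1 = a, set2 = b, overlap = ov, p = p,
                          stringsAsFactors = FALSE)
  }
  list(regions = patterns, pairwise = do.call(rbind, pw), n_universe = N)
}
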