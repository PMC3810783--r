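#' Detection filter on a summarized expression matrix
#'
#' Retains probes whose log2 intensity exceeds a floor in at least
#' \code{min_samples} samples. This is a threshold-based stand-in for
#' probe-level present/absent detection calls, operating on the summarized
#' matrix; the default floor of log2(64) = 6 marks intensities
#' indistinguishable from array background.
#'
#' @param study an \code{\link{ExpressionStudy}}.
#' @param floor log2 intensity floor (finite).
#' @param min_samples minimum number of samples above the floor.
#' @return character vector of retained probe ids (matrix row order).
#' @export
detectionFilter <- function(study, floor = log2(64), min_samples = 1L) {
  stopifnot(is(study, "ExpressionStudy"), is.finite(floor) || floor == -Inf)
  m <- exprMatrix(study)
  keep <- rowSums(m > floor) >= min_samples
  rownames(m)[keep]
}

# Solve trigamma(x) = y by Newton iteration (y > 0). Used to moment-match
# the prior degrees of freedom from the spread of log sample variances.
trigammaInverse <- function(y) {
  stopifnot(all(is.finite(y)), all(y > 0))
  vapply(y, function(yy) {
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

# Moment-match a scaled inverse-chi-square prior (d0, s0^2) to observed
# sample variances s2 on d df, working on the log scale: for
# s2 ~ s0^2 * F(d, d0), e = log(s2) - digamma(d/2) + log(d/2) has
# mean log(s0^2) + digamma(d0/2) - log(d0/2) and excess variance
# trigamma(d0/2) beyond trigamma(d/2).
estimateVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  s2 <- s2[ok]
  n <- length(s2)
  if (n < 2) stop("need at least two positive sample variances")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # variances underdispersed relative to chi-square: infinite shrinkage
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Two-group comparison per probe on a log2 matrix. Each probe's sample
#' variance is shrunk toward a prior variance s0^2 estimated by closed-form
#' moment matching of the scaled-F distribution of sample variances
#' (on the log scale), giving the posterior variance
#' s~^2 = (d0 s0^2 + d s^2) / (d0 + d) and a t-statistic on d0 + d degrees
#' of freedom. With \code{prior_df = 0} this is the ordinary two-sample
#' equal-variance t; with \code{prior_df = Inf} all probes share s0^2.
#'
#' @param study an \code{\link{ExpressionStudy}}.
#' @param group_a,group_b group labels; log2fc = mean(a) - mean(b).
#' @param probes optional probe subset (e.g. from
#'   \code{\link{detectionFilter}}); default all probes.
#' @param prior_df \code{NULL} to estimate the prior df d0 from the data,
#'   or a fixed nonnegative value (0 and \code{Inf} give the limits above).
#' @return data.frame, one row per probe: \code{probe}, \code{log2fc},
#'   \code{t_mod}, \code{p}, \code{df_total}, \code{s2}; with attributes
#'   \code{d0} and \code{s0_2}.
#' @export
moderatedT <- function(study, group_a, group_b, probes = NULL,
                       prior_df = NULL) {
  stopifnot(is(study, "ExpressionStudy"))
  grp <- sampleGroups(study)
  ia <- which(grp == group_a); ib <- which(grp == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need at least 2 samples per group for variance estimation")
  m <- exprMatrix(study)
  if (!is.null(probes)) m <- m[probes, , drop = FALSE]
  na <- length(ia); nb <- length(ib)
  d <- na + nb - 2L
  if (d <= 0) stop("zero residual degrees of freedom")
  ma <- rowMeans(m[, ia, drop = FALSE])
  mb <- rowMeans(m[, ib, drop = FALSE])
  log2fc <- ma - mb
  ssa <- rowSums((m[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((m[, ib, drop = FALSE] - mb)^2)
  s2 <- (ssa + ssb) / d
  if (is.null(prior_df)) {
    prior <- estimateVariancePrior(s2, d)
  } else {
    stopifnot(prior_df >= 0)
    prior <- list(d0 = prior_df,
                  s0_2 = if (prior_df > 0) exp(mean(log(s2[s2 > 0]))) else NA_real_)
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else {
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  cdesign <- sqrt(1 / na + 1 / nb)
  t_mod <- log2fc / (sqrt(s2_post) * cdesign)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  out <- data.frame(probe = rownames(m), log2fc = log2fc, t_mod = t_mod,
                    p = p, df_total = df_total, s2 = s2,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), with input
#' validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of adjusted values q with q >= p elementwise.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Collapse sibling probes to one record per gene
#'
#' Arrays carry multiple ("sibling") probe sets targeting the same gene;
#' redundancy is limited by keeping, per gene, the probe with the lowest
#' p-value. Ties are broken by larger |log2fc|, then lexicographic probe
#' id. Probes without a gene mapping are dropped with a message.
#'
#' @param per_probe data.frame from \code{\link{moderatedT}} (optionally
#'   with a \code{q} column already attached).
#' @param probe_gene named character vector probe id -> gene symbol.
#' @return data.frame with one row per gene, plus a \code{gene} and
#'   \code{chosen_probe} column.
#' @export
collapseProbes <- function(per_probe, probe_gene) {
  gene <- unname(probe_gene[per_probe$probe])
  drop <- is.na(gene) | gene == ""
  if (any(drop)) {
    message("dropping ", sum(drop), " probe(s) with no gene mapping")
    per_probe <- per_probe[!drop, , drop = FALSE]
    gene <- gene[!drop]
  }
  o <- order(gene, per_probe$p, -abs(per_probe$log2fc), per_probe$probe)
  per_probe <- per_probe[o, , drop = FALSE]
  gene <- gene[o]
  keep <- !duplicated(gene)
  out <- per_probe[keep, , drop = FALSE]
  out$gene <- gene[keep]
  out$chosen_probe <- out$probe
  out$probe <- NULL
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Classify genes by FDR and linear fold change
#'
#' Splits per-gene results into increased / decreased / unchanged using a
#' joint rule: q below the FDR threshold AND linear fold change
#' (2^log2fc) outside the [down, up] dead zone.
#'
#' @param per_gene data.frame with columns \code{gene}, \code{log2fc},
#'   \code{q}.
#' @param fdr FDR threshold (default 0.05).
#' @param up linear fold-change threshold for "increased" (default 1.50).
#' @param down linear fold-change threshold for "decreased" (default 0.67).
#' @return the input with added \code{fold_change} and \code{class}
#'   columns (\code{class} in increased/decreased/unchanged).
#' @export
classifyGenes <- function(per_gene, fdr = 0.05, up = 1.50, down = 0.67) {
  stopifnot(down < 1, up > 1, fdr > 0, fdr < 1,
            all(c("gene", "log2fc", "q") %in% names(per_gene)))
  fc <- 2^per_gene$log2fc
  cls <- rep("unchanged", nrow(per_gene))
  cls[per_gene$q < fdr & fc > up] <- "increased"
  cls[per_gene$q < fdr & fc < down] <- "decreased"
  per_gene$fold_change <- fc
  per_gene$class <- cls
  per_gene
}

#' Full differential-expression pipeline
#'
#' Detection filter, moderated t, BH adjustment across all retained probes
#' (the FDR family is pre-collapse), sibling-probe collapse, fold-change
#' classification.
#'
#' @inheritParams moderatedT
#' @inheritParams detectionFilter
#' @inheritParams classifyGenes
#' @return list of class \code{"DEResult"}: \code{per_gene} (classified
#'   table), \code{retained_probes}, \code{n_probes_total},
#'   \code{increased}/\code{decreased} gene-id vectors, and the thresholds
#'   used.
#' @export
runDE <- function(study, group_a, group_b, floor = log2(64),
                  min_samples = 1L, fdr = 0.05, up = 1.50, down = 0.67,
                  prior_df = NULL) {
  retained <- detectionFilter(study, floor = floor, min_samples = min_samples)
  if (length(retained) == 0) stop("detection filter retained no probes")
  pp <- moderatedT(study, group_a, group_b, probes = retained,
                   prior_df = prior_df)
  pp$q <- bhAdjust(pp$p)
  pg <- collapseProbes(pp, probeGeneMap(study))
  pg <- classifyGenes(pg, fdr = fdr, up = up, down = down)
  out <- list(per_gene = pg,
              retained_probes = retained,
              n_probes_total = nrow(study),
              increased = pg$gene[pg$class == "increased"],
              decreased = pg$gene[pg$class == "decreased"],
              thresholds = list(floor = floor, min_samples = min_samples,
                                fdr = fdr, up = up, down = down),
              d0 = attr(pp, "d0"), s0_2 = attr(pp, "s0_2"))
  class(out) <- "DEResult"
  out
}

#' @export
print.DEResult <- function(x, ...) {
  cat("DEResult:", length(x$retained_probes), "of", x$n_probes_total,
      "probes retained;", nrow(x$per_gene), "genes after collapse\n")
  cat(length(x$increased), "increased /", length(x$decreased),
      "decreased (FDR <", x$thresholds$fdr, ", FC >", x$thresholds$up,
      "or <", x$thresholds$down, ")\n")
  invisible(x)
}
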