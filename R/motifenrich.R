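#' @importFrom splines ns
NULL

# IRLS logistic fit with a small ridge on the normal equations for
# numerical stability; returns coefficients and their covariance.
irlsLogistic <- function(X, y, ridge = 1e-8, tol = 1e-8, maxit = 100L) {
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + diag(ridge, p)
    beta_new <- drop(solve(H, XtW %*% z))
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (step < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- t(X * w) %*% X + diag(ridge, p)
  cov <- solve(H)
  separated <- max(abs(beta)) > 15 || !converged
  list(beta = beta, cov = cov, converged = converged,
       separated = separated, iterations = it)
}

#' Semiparametric logistic motif-enrichment model for one motif
#'
#' Fits logit P(y = 1) = b0 + b1 * x1 + s(x2): set membership regressed on
#' the motif occurrence count (x1, parametric) with a natural cubic spline
#' in the scanned sequence length (x2, nonparametric), so that enrichment
#' is judged per additional motif occurrence at comparable scannable
#' length. Without the length term, motifs would look enriched merely
#' because target genes happen to have less-masked promoters. The Wald Z
#' for b1 and its two-sided p quantify enrichment; the sign gives the
#' direction.
#'
#' The spline term is dropped automatically when x2 is constant (the fit
#' then reduces to plain logistic regression of y on x1); its df shrinks
#' when x2 has too few distinct values. A motif with constant x1 is
#' inestimable and returned flagged. Complete separation is flagged and
#' the ridge-penalized fit reported with a warning.
#'
#' @param y 0/1 membership in the target set, one per gene.
#' @param x1 motif occurrence count per gene.
#' @param x2 scanned (unmasked, eligible) length per gene, bases.
#' @param spline_df natural-spline degrees of freedom for x2 (default 4;
#'   knots at quantiles of x2).
#' @param ridge ridge added to the IRLS normal equations (default 1e-8).
#' @param min_per_class minimum genes required in each class (default 20).
#' @param motif motif id carried into the result.
#' @return one-row data.frame: \code{motif}, \code{beta1}, \code{se},
#'   \code{z}, \code{p}, \code{direction}, \code{spline_df},
#'   \code{n_genes}, \code{estimable}, \code{separated}.
#' @export
fitMotifModel <- function(y, x1, x2, spline_df = 4L, ridge = 1e-8,
                          min_per_class = 20L, motif = "motif") {
  stopifnot(length(y) == length(x1), length(x1) == length(x2),
            all(y %in% c(0, 1)), all(x2 >= 0))
  if (length(unique(y)) < 2)
    stop("membership indicator has a single class")
  if (min(sum(y == 1), sum(y == 0)) < min_per_class)
    stop("fewer than ", min_per_class, " genes in one class")
  na_row <- data.frame(motif = motif, beta1 = NA_real_, se = NA_real_,
                       z = NA_real_, p = NA_real_, direction = NA_real_,
                       spline_df = 0L, n_genes = length(y),
                       estimable = FALSE, separated = FALSE,
                       stringsAsFactors = FALSE)
  if (var(x1) == 0) return(na_row)
  nux2 <- length(unique(x2))
  df_use <- min(spline_df, max(nux2 - 1L, 0L))
  # degenerate length distributions (constant, or too clumped for
  # quantile knots) fall back to a linear term, then to dropping x2
  X <- NULL
  while (df_use >= 2L && is.null(X)) {
    S <- tryCatch(splines::ns(x2, df = df_use), error = function(e) NULL)
    if (is.null(S)) df_use <- df_use - 1L else X <- cbind(1, x1, S)
  }
  if (is.null(X) && df_use >= 1L && nux2 >= 2L) {
    # unit-scaled linear term: keeps the normal equations well conditioned
    X <- cbind(1, x1, (x2 - min(x2)) / diff(range(x2)))
    df_use <- 1L
  }
  if (is.null(X)) {
    X <- cbind(1, x1)
    df_use <- 0L
  }
  fit <- irlsLogistic(X, y, ridge = ridge)
  if (fit$separated)
    warning("motif '", motif, "': separation or non-convergence; ",
            "reporting ridge-penalized fit")
  se <- sqrt(fit$cov[2, 2])
  z <- fit$beta[2] / se
  data.frame(motif = motif, beta1 = fit$beta[2], se = se, z = z,
             p = 2 * pnorm(-abs(z)), direction = sign(fit$beta[2]),
             spline_df = df_use, n_genes = length(y),
             estimable = TRUE, separated = fit$separated,
             stringsAsFactors = FALSE)
}

#' Screen a motif dictionary for target-set enrichment
#'
#' Runs \code{\link{fitMotifModel}} for every motif in a count table:
#' response = membership of each (expressed) gene in the target set,
#' x1 = that motif's occurrence count, x2 = scanned length. Only genes in
#' \code{union(target, background)} enter. BH adjustment is applied across
#' estimable motifs only; inestimable motifs are reported unadjusted.
#'
#' @param counts data.frame from \code{\link{countTable}} (\code{gene},
#'   \code{motif}, \code{count}, \code{scanned_length}).
#' @param target character vector: the target gene set (e.g. the
#'   increased genes).
#' @param background character vector: expressed non-target genes.
#' @param spline_df,ridge,min_per_class passed to
#'   \code{\link{fitMotifModel}}.
#' @return data.frame sorted by p: one row per motif with a BH \code{q}
#'   column, plus attribute \code{top_per_direction}.
#' @export
screenDictionary <- function(counts, target, background, spline_df = 4L,
                             ridge = 1e-8, min_per_class = 20L) {
  stopifnot(all(c("gene", "motif", "count", "scanned_length") %in%
                  names(counts)))
  genes <- unique(c(target, background))
  counts <- counts[counts$gene %in% genes, , drop = FALSE]
  motifs <- unique(counts$motif)
  if (length(motifs) == 0) stop("no motifs in count table")
  rows <- vector("list", length(motifs))
  for (i in seq_along(motifs)) {
    sub <- counts[counts$motif == motifs[i], , drop = FALSE]
    sub <- sub[match(genes, sub$gene), , drop = FALSE]
    if (any(is.na(sub$gene)))
      stop("count table is missing genes for motif ", motifs[i])
    y <- as.integer(genes %in% target)
    rows[[i]] <- fitMotifModel(y, sub$count, sub$scanned_length,
                               spline_df = spline_df, ridge = ridge,
                               min_per_class = min_per_class,
                               motif = motifs[i])
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$q <- NA_real_
  est <- res$estimable
  if (!any(est)) stop("no estimable motif in the dictionary")
  res$q[est] <- bhAdjust(res$p[est])
  res <- res[order(res$p, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  top_up <- res$motif[res$estimable & res$direction > 0][1]
  top_dn <- res$motif[res$estimable & res$direction < 0][1]
  attr(res, "top_per_direction") <- c(positive = top_up, negative = top_dn)
  res
}
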