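#' HOMA-IR insulin-resistance index
#'
#' Homeostasis model assessment of insulin resistance:
#' fasting glucose (mg/dl) x fasting insulin (uU/ml) / 405.
#'
#' @param glucose fasting blood glucose, mg/dl (>= 0).
#' @param insulin fasting insulin, uU/ml (>= 0). Vectorized.
#' @return the index (bilinear in its inputs).
#' @examples
#' homaIR(100, 10)  # 2.469...
#' @export
homaIR <- function(glucose, insulin) {
  if (any(glucose < 0) || any(insulin < 0))
    stop("glucose and insulin must be nonnegative")
  glucose * insulin / 405
}

#' Respiratory quotient
#'
#' RQ = VCO2 / VO2, the dimensionless fuel-utilization index from
#' indirect calorimetry (about 0.7 under pure fat oxidation, 1.0 under
#' pure carbohydrate oxidation).
#'
#' @param vco2 CO2 production, ml/hr (>= 0).
#' @param vo2 O2 consumption, ml/hr (> 0). Vectorized.
#' @export
respiratoryQuotient <- function(vco2, vo2) {
  if (any(vo2 <= 0)) stop("VO2 must be positive")
  if (any(vco2 < 0)) stop("VCO2 must be nonnegative")
  vco2 / vo2
}

#' Glucose curve as percent of baseline
#'
#' Rescales a tolerance-test glucose curve to 100 * g(t) / g(0), the
#' usual presentation for GTT/ITT time courses.
#'
#' @param glucose numeric vector of readings, first element = baseline
#'   (> 0).
#' @return percent-of-baseline curve (first element 100).
#' @export
pctBaseline <- function(glucose) {
  stopifnot(length(glucose) >= 1)
  if (glucose[1] <= 0) stop("baseline glucose must be positive")
  100 * glucose / glucose[1]
}

#' Fold induction by the delta-delta-Ct method
#'
#' Relative qPCR quantification: per condition, replicate Ct values are
#' averaged per (sample, gene), normalized to the reference gene
#' (dCt = Ct_gene - Ct_ref, averaged across samples), then contrasted
#' between conditions (ddCt = dCt_treated - dCt_control). Fold induction
#' is 2^(-ddCt), so a transcript amplifying earlier (lower Ct) in treated
#' samples yields fold > 1.
#'
#' @param plate data.frame with columns \code{sample}, \code{condition}
#'   (\code{"treated"} / \code{"control"}), \code{gene}, \code{ct}
#'   (e.g. from \code{\link{genQpcrPlate}} or \code{\link{readQpcrTable}}).
#' @param reference_gene name of the reference gene, present in every
#'   sample (default "Gapdh").
#' @return data.frame per target gene: \code{gene}, \code{dct_treated},
#'   \code{dct_control}, \code{ddct}, \code{fold}.
#' @export
foldInduction <- function(plate, reference_gene = "Gapdh") {
  stopifnot(all(c("sample", "condition", "gene", "ct") %in% names(plate)),
            all(plate$condition %in% c("treated", "control")),
            all(plate$ct > 0))
  # average replicate wells per (sample, gene)
  agg <- stats::aggregate(ct ~ sample + condition + gene, data = plate,
                          FUN = mean)
  dct_of <- function(cond) {
    sub <- agg[agg$condition == cond, , drop = FALSE]
    ref <- sub[sub$gene == reference_gene, c("sample", "ct")]
    if (nrow(ref) == 0)
      stop("reference gene '", reference_gene, "' missing in ", cond,
           " samples")
    tgt <- sub   # the reference normalizes itself to dCt = 0, fold = 1
    tgt$dct <- tgt$ct - ref$ct[match(tgt$sample, ref$sample)]
    if (any(is.na(tgt$dct)))
      stop("reference gene '", reference_gene, "' missing in some ",
           cond, " sample(s)")
    stats::aggregate(dct ~ gene, data = tgt, FUN = mean)
  }
  tr <- dct_of("treated"); ct <- dct_of("control")
  genes <- union(tr$gene, ct$gene)
  out <- data.frame(gene = genes,
                    dct_treated = tr$dct[match(genes, tr$gene)],
                    dct_control = ct$dct[match(genes, ct$gene)],
                    stringsAsFactors = FALSE)
  out$ddct <- out$dct_treated - out$dct_control
  out$fold <- 2^(-out$ddct)
  out
}
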