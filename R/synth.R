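#' Simulate a multi-group survival cohort under Gompertz mortality
#'
#' Draws lifespans per group from a Gompertz law with hazard
#' h(t) = rate * exp(shape * t) — the standard two-parameter rodent
#' mortality model (shape = 0 recovers the exponential). A fraction of
#' animals per group is right-censored by independent uniform truncation:
#' a censored animal's recorded time is uniform on (0, death time), so
#' censoring is non-informative. The same seed reproduces the table
#' exactly.
#'
#' @param groups list of group specifications, each a list/vector with
#'   \code{label}, \code{n} (>= 1), \code{shape} (per day, >= 0),
#'   \code{rate} (per day, > 0), and optional \code{censor_fraction}
#'   in [0, 1] (default 0).
#' @param seed integer RNG seed.
#' @return a \code{\link{SurvivalTable}}.
#' @examples
#' st <- genSurvivalCohort(list(
#'   list(label = "KO", n = 40, shape = 0.006, rate = 1e-5),
#'   list(label = "Ct", n = 40, shape = 0.009, rate = 1e-5)), seed = 1)
#' @export
genSurvivalCohort <- function(groups, seed) {
  stopifnot(length(groups) >= 1)
  set.seed(seed)
  rows <- lapply(groups, function(g) {
    g <- as.list(g)
    if (is.null(g$censor_fraction)) g$censor_fraction <- 0
    n <- as.integer(g$n)
    if (n < 1) stop("n_animals must be >= 1")
    if (!is.numeric(g$rate) || g$rate <= 0)
      stop("gompertz rate must be positive")
    if (g$shape < 0) stop("gompertz shape must be nonnegative")
    if (g$censor_fraction < 0 || g$censor_fraction > 1)
      stop("censor_fraction must lie in [0, 1]")
    death <- flexsurv::rgompertz(n, shape = g$shape, rate = g$rate)
    event <- rep(1L, n)
    time <- death
    ncens <- round(g$censor_fraction * n)
    if (ncens > 0) {
      idx <- sample.int(n, ncens)
      time[idx] <- runif(ncens, min = 0, max = death[idx])
      event[idx] <- 0L
    }
    data.frame(animal_id = sprintf("%s_%04d", g$label, seq_len(n)),
               group = g$label, time = time, event = event,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  new("SurvivalTable", data = d)
}

#' Simulate a two-group expression study with planted fold changes
#'
#' Builds a probes-by-samples log2 matrix emulating a small array study:
#' \code{n_genes} expressed genes (one probe each), plus
#' \code{n_sibling_probes} extra probes re-targeting the first genes
#' (suffixed probe ids sharing the gene symbol, as arrays carry "sibling"
#' probe sets), plus \code{n_unexpressed} probes whose intensities stay
#' below the detection floor in every sample. The first
#' \code{planted_up} genes are shifted by +\code{effect_log2fc} in group
#' "A", the next \code{planted_down} by -\code{effect_log2fc}; all probes
#' of a planted gene shift coherently. Residuals are iid Gaussian.
#'
#' @param n_genes expressed genes.
#' @param n_sibling_probes extra probes sharing gene symbols with the
#'   first genes (default 0).
#' @param n_unexpressed probes generated below \code{floor} in all
#'   samples (default 0); they carry their own gene symbols.
#' @param samples_per_group samples in each of groups "A" and "B"
#'   (default 3).
#' @param planted_up,planted_down numbers of planted genes per direction.
#' @param effect_log2fc planted shift, log2 units (default 2).
#' @param residual_sd Gaussian residual sd, log2 units (default 0.25, > 0).
#' @param floor detection floor the unexpressed probes stay under
#'   (default log2(64)).
#' @param seed integer RNG seed.
#' @return list: \code{study} (an \code{\link{ExpressionStudy}}) and
#'   \code{truth} (data.frame \code{gene}, \code{direction} of planted
#'   genes; empty when no effect is planted).
#' @export
genExpressionStudy <- function(n_genes, n_sibling_probes = 0L,
                               n_unexpressed = 0L, samples_per_group = 3L,
                               planted_up = 0L, planted_down = 0L,
                               effect_log2fc = 2, residual_sd = 0.25,
                               floor = log2(64), seed = 1L) {
  stopifnot(residual_sd > 0, samples_per_group >= 2,
            n_sibling_probes <= n_genes * 10)
  if (planted_up + planted_down > n_genes)
    stop("planted_up + planted_down exceeds n_genes")
  set.seed(seed)
  genes <- sprintf("G%06d", seq_len(n_genes))
  probes <- sprintf("P%06d_at", seq_len(n_genes))
  probe_gene <- setNames(genes, probes)
  if (n_sibling_probes > 0) {
    host <- rep(seq_len(n_genes), length.out = n_sibling_probes)
    sib_probe <- sprintf("P%06d_s_at", seq_len(n_sibling_probes))
    probe_gene <- c(probe_gene, setNames(genes[host], sib_probe))
  }
  if (n_unexpressed > 0) {
    ux_probe <- sprintf("U%06d_at", seq_len(n_unexpressed))
    probe_gene <- c(probe_gene,
                    setNames(sprintf("UNEXP%06d", seq_len(n_unexpressed)),
                             ux_probe))
  }
  n_probe <- length(probe_gene)
  nspg <- samples_per_group
  samples <- c(sprintf("A%d", seq_len(nspg)), sprintf("B%d", seq_len(nspg)))
  group <- rep(c("A", "B"), each = nspg)

  base_gene <- setNames(runif(n_genes, 7, 12), genes)
  baseline <- numeric(n_probe)
  expressed <- !grepl("^U", names(probe_gene))
  baseline[expressed] <- base_gene[probe_gene[expressed]] +
    runif(sum(expressed), -0.5, 0.5)          # sibling probes differ a bit
  baseline[!expressed] <- runif(sum(!expressed), floor - 4, floor - 1)

  effect_gene <- setNames(rep(0, n_genes), genes)
  dir <- character(0)
  if (effect_log2fc != 0 && (planted_up + planted_down) > 0) {
    if (planted_up > 0)
      effect_gene[seq_len(planted_up)] <- effect_log2fc
    if (planted_down > 0)
      effect_gene[planted_up + seq_len(planted_down)] <- -effect_log2fc
    dir <- c(rep("increased", planted_up), rep("decreased", planted_down))
  }
  effect_probe <- numeric(n_probe)
  effect_probe[expressed] <- effect_gene[probe_gene[expressed]]

  m <- matrix(rnorm(n_probe * 2 * nspg, sd = residual_sd),
              nrow = n_probe, ncol = 2 * nspg,
              dimnames = list(names(probe_gene), samples))
  m <- m + baseline
  m[, group == "A"] <- m[, group == "A"] + effect_probe
  # unexpressed probes must stay under the floor in every sample
  if (n_unexpressed > 0) {
    ux <- which(!expressed)
    m[ux, ] <- pmin(m[ux, ], floor - 0.5)
  }
  truth <- if (length(dir))
    data.frame(gene = genes[seq_along(dir)], direction = dir,
               stringsAsFactors = FALSE)
  else data.frame(gene = character(), direction = character(),
                  stringsAsFactors = FALSE)
  list(study = ExpressionStudy(m, probe_gene, group), truth = truth)
}

# sample one motif instance column-wise from the PWM probabilities
samplePwmInstance <- function(pwm) {
  bases <- rownames(pwm@pwm)
  paste(vapply(seq_len(pwmLength(pwm)), function(j)
    sample(bases, 1, prob = pwm@pwm[, j]), character(1)), collapse = "")
}

#' Simulate masked promoter regions with planted motif instances
#'
#' Generates fixed-length upstream regions of iid background sequence,
#' soft-masks a contiguous block covering \code{masked_fraction} of each
#' region (lowercase, emulating masked protein-coding/repeat sequence),
#' and plants \code{instances_per_gene} motif instances — sampled
#' column-wise from the PWM — at non-overlapping unmasked positions of the
#' first \code{n_target} genes.
#'
#' @param pwm a \code{\link{PWMRecord}} to plant.
#' @param n_genes total genes.
#' @param n_target genes receiving planted instances (the target set).
#' @param region_length region size in bases (default 2000; must be at
#'   least the motif length).
#' @param masked_fraction fraction of each region masked (default 0.2).
#' @param instances_per_gene planted instances per target gene (default 1).
#' @param background_base_freqs A/C/G/T composition of the background
#'   sequence, summing to 1 (default uniform).
#' @param seed integer RNG seed.
#' @return list: \code{sequences} (named character vector),
#'   \code{truth} (data.frame \code{gene}, \code{is_target},
#'   \code{planted}).
#' @export
genPromoterSet <- function(pwm, n_genes, n_target,
                           region_length = 2000L, masked_fraction = 0.2,
                           instances_per_gene = 1L,
                           background_base_freqs = c(0.25, 0.25, 0.25, 0.25),
                           seed = 1L) {
  stopifnot(is(pwm, "PWMRecord"), n_target <= n_genes,
            masked_fraction >= 0, masked_fraction <= 1,
            abs(sum(background_base_freqs) - 1) < 1e-9)
  L <- pwmLength(pwm)
  if (region_length < L)
    stop("region_length must be at least the motif length")
  set.seed(seed)
  genes <- sprintf("G%06d", seq_len(n_genes))
  mask_len <- round(masked_fraction * region_length)
  seqs <- character(n_genes)
  planted <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    chars <- sample(c("A", "C", "G", "T"), region_length, replace = TRUE,
                    prob = background_base_freqs)
    if (mask_len > 0) {
      ms <- sample.int(region_length - mask_len + 1L, 1)
      block <- ms:(ms + mask_len - 1L)
      chars[block] <- tolower(chars[block])
    } else {
      block <- integer()
    }
    if (i <= n_target && instances_per_gene > 0) {
      taken <- rep(FALSE, region_length)
      taken[block] <- TRUE
      for (j in seq_len(instances_per_gene)) {
        ok_start <- which(vapply(seq_len(region_length - L + 1L),
                                 function(s) !any(taken[s:(s + L - 1L)]),
                                 logical(1)))
        if (length(ok_start) == 0)
          stop("gene ", genes[i], ": no unmasked space left to plant ",
               "instance ", j)
        s <- if (length(ok_start) == 1) ok_start else sample(ok_start, 1)
        inst <- strsplit(samplePwmInstance(pwm), "", fixed = TRUE)[[1]]
        chars[s:(s + L - 1L)] <- inst
        taken[s:(s + L - 1L)] <- TRUE
        planted[i] <- planted[i] + 1L
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  list(sequences = setNames(seqs, genes),
       truth = data.frame(gene = genes, is_target = seq_len(n_genes) <= n_target,
                          planted = planted, stringsAsFactors = FALSE))
}

#' Simulate a toy ontology DAG with gene annotations
#'
#' Terms are created in index order; every term after the first draws one
#' or two parents among earlier terms, which guarantees acyclicity with a
#' single root. Each gene receives 1-3 direct annotations to random
#' terms; the \code{\link{TermDAG}} constructor propagates them to all
#' ancestors (true-path rule).
#'
#' @param n_terms number of terms (>= 2).
#' @param n_genes number of genes (ignored when \code{genes} is given).
#' @param seed integer RNG seed.
#' @param genes optional character vector of gene ids to annotate
#'   (defaults to \code{g00001, g00002, ...}).
#' @return list: \code{dag} (a \code{TermDAG}), \code{edges},
#'   \code{annotations} (the direct, pre-propagation annotations).
#' @export
genToyOntology <- function(n_terms, n_genes, seed, genes = NULL) {
  if (is.null(genes)) {
    stopifnot(n_genes >= 1)
    genes <- sprintf("g%05d", seq_len(n_genes))
  }
  n_genes <- length(genes)
  stopifnot(n_terms >= 2, n_genes >= 1)
  set.seed(seed)
  terms <- sprintf("T%04d", seq_len(n_terms))
  edges <- do.call(rbind, lapply(2:n_terms, function(i) {
    np <- if (i > 2) sample(1:2, 1) else 1L
    parents <- sample(seq_len(i - 1), min(np, i - 1))
    data.frame(child = terms[i], parent = terms[parents],
               stringsAsFactors = FALSE)
  }))
  ann <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    k <- sample(1:3, 1)
    data.frame(gene = genes[i], term = sample(terms, k),
               stringsAsFactors = FALSE)
  }))
  list(dag = TermDAG(edges, ann, terms = terms),
       edges = edges, annotations = ann)
}

#' Simulate a qPCR plate with planted fold inductions
#'
#' Generates Ct values for a panel of genes plus a reference gene in
#' treated and control samples. A gene with planted log2 fold change f is
#' amplified f cycles earlier in treated samples (Ct drops by f), so the
#' delta-delta-Ct pipeline should recover a fold induction of 2^f.
#'
#' @param genes character vector of target gene names.
#' @param log2fc planted log2 fold inductions, one per gene.
#' @param n_per_condition replicates per condition (default 3).
#' @param reference_gene reference gene name (default "Gapdh").
#' @param ref_ct reference-gene Ct level (default 18 cycles).
#' @param delta_ct baseline Ct offset of each target gene above the
#'   reference (recycled; default 5 cycles).
#' @param noise_sd technical noise on every Ct (default 0.05 cycles).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{sample}, \code{condition},
#'   \code{gene}, \code{ct}.
#' @export
genQpcrPlate <- function(genes, log2fc, n_per_condition = 3L,
                         reference_gene = "Gapdh", ref_ct = 18,
                         delta_ct = 5, noise_sd = 0.05, seed = 1L) {
  stopifnot(length(log2fc) == length(genes), noise_sd >= 0)
  set.seed(seed)
  delta_ct <- rep_len(delta_ct, length(genes))
  rows <- list()
  for (cond in c("treated", "control")) {
    for (s in seq_len(n_per_condition)) {
      sample_id <- sprintf("%s_%d", cond, s)
      shift <- runif(1, -1, 1)   # per-sample loading offset, cancels in dCt
      ct_ref <- ref_ct + shift + rnorm(1, sd = noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, condition = cond, gene = reference_gene,
        ct = ct_ref, stringsAsFactors = FALSE)
      eff <- if (cond == "treated") log2fc else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, condition = cond, gene = genes,
        ct = ref_ct + shift + delta_ct - eff +
          rnorm(length(genes), sd = noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate an external ranked fold-change experiment
#'
#' Produces a ranked list over a gene universe in which members of a
#' reference set are shifted by \code{concordance * direction} standard
#' deviations of the background score noise (one SD per unit of
#' concordance). \code{concordance = 0} gives a null list; positive
#' concordance with \code{direction = +1} biases set members toward the
#' top of the ranking, \code{direction = -1} toward the bottom.
#'
#' @param universe character vector of genes on the simulated platform.
#' @param set reference gene set to bias.
#' @param concordance shift in background-SD units, in [-1, 1].
#' @param direction +1 or -1: the sign of the set's expected movement.
#' @param experiment_id label for the list.
#' @param seed integer RNG seed.
#' @return a \code{\link{rankedList}}.
#' @export
genRankedExperiment <- function(universe, set, concordance, direction = 1,
                                experiment_id = "experiment", seed = 1L) {
  stopifnot(concordance >= -1, concordance <= 1, direction %in% c(-1, 1))
  set.seed(seed)
  score <- rnorm(length(universe))
  score[universe %in% set] <- score[universe %in% set] +
    concordance * direction
  rankedList(universe, score, experiment_id = experiment_id)
}

#' Assemble a synthetic motif dictionary from pooled sources
#'
#' Generates random peaked position frequency matrices tagged with their
#' source database, mimicking the assembly of a binding-site dictionary by
#' pooling several motif collections. Each motif has one dominant base per
#' column over a low uniform background; lengths are drawn from
#' \code{lengths}. Motifs shorter than 4 bases are rejected by
#' \code{\link{buildPWM}}, so dictionary size is a property of the inputs,
#' not a constant.
#'
#' @param n_jaspar,n_uniprobe,n_transfac motif counts per source
#'   collection.
#' @param seed integer RNG seed.
#' @param lengths candidate motif lengths (default 6:12).
#' @return named list of \code{\link{PWMRecord}} objects, pooled in
#'   source order.
#' @export
genMotifDictionary <- function(n_jaspar, n_uniprobe, n_transfac, seed,
                               lengths = 6:12) {
  set.seed(seed)
  mk <- function(n, src, prefix) {
    lapply(seq_len(n), function(i) {
      L <- if (length(lengths) == 1) lengths else sample(lengths, 1)
      pfm <- matrix(rpois(4 * L, 3), nrow = 4,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
      pfm[cbind(sample(1:4, L, replace = TRUE), 1:L)] <- 25
      buildPWM(pfm, id = sprintf("%s%04d", prefix, i), source_db = src)
    })
  }
  dict <- c(mk(n_jaspar, "jaspar-like", "JA"),
            mk(n_uniprobe, "uniprobe-like", "UP"),
            mk(n_transfac, "transfac-like", "TF"))
  names(dict) <- vapply(dict, function(p) p@id, character(1))
  dict
}
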