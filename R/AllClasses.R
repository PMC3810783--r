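#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats pchisq pnorm pt pwilcox phyper fisher.test p.adjust
#'   rnorm runif rpois rbinom var sd quantile setNames complete.cases
#'   binomial glm ks.test wilcox.test
#' @importFrom utils read.delim write.table head tail
NULL

#' SurvivalTable: one row per animal
#'
#' Container for lifespan data: one record per animal with a group label,
#' a lifespan (days) and an event indicator (1 = death observed,
#' 0 = right-censored). The substrate of all lifespan statistics.
#'
#' @slot data a \code{data.frame} with columns \code{animal_id},
#'   \code{group}, \code{time}, \code{event} (extra columns such as sex or
#'   diet are carried along untouched).
#' @export
setClass("SurvivalTable", representation(data = "data.frame"))

setValidity("SurvivalTable", function(object) {
  d <- object@data
  need <- c("animal_id", "group", "time", "event")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$animal_id))
    return("animal_id values must be unique")
  if (any(!is.finite(d$time)) || any(d$time <= 0))
    return("times must be positive and finite")
  if (!all(d$event %in% c(0L, 1L)))
    return("event must be 0 (censored) or 1 (death)")
  TRUE
})

#' Construct a SurvivalTable
#'
#' @param animal_id character vector of unique animal identifiers.
#' @param group group label per animal (genotype, diet arm, ...).
#' @param time lifespan or censoring time in days (> 0).
#' @param event 1 if the death was observed, 0 if right-censored.
#' @param ... further per-animal columns (e.g. \code{sex}, \code{diet}).
#' @return a \code{SurvivalTable}.
#' @examples
#' st <- SurvivalTable(paste0("m", 1:4), rep(c("KO", "Ct"), 2),
#'                     c(900, 600, 950, 640), c(1, 1, 1, 1))
#' @export
SurvivalTable <- function(animal_id, group, time, event, ...) {
  d <- data.frame(animal_id = as.character(animal_id),
                  group = as.character(group),
                  time = as.numeric(time),
                  event = as.integer(event),
                  ...,
                  stringsAsFactors = FALSE)
  new("SurvivalTable", data = d)
}

#' @describeIn SurvivalTable number of animals
#' @param x,object a \code{SurvivalTable}
#' @export
setMethod("length", "SurvivalTable", function(x) nrow(x@data))

setMethod("show", "SurvivalTable", function(object) {
  d <- object@data
  cat("SurvivalTable with", nrow(d), "animals in",
      length(unique(d$group)), "group(s)\n")
  tab <- table(d$group, factor(d$event, levels = c(0, 1),
                               labels = c("censored", "died")))
  print(tab)
})

#' Extract the underlying per-animal data.frame
#' @param x a \code{SurvivalTable}
#' @return a base \code{data.frame}
#' @export
survivalData <- function(x) {
  stopifnot(is(x, "SurvivalTable"))
  x@data
}

#' Group labels of a SurvivalTable
#' @param x a \code{SurvivalTable}
#' @export
survivalGroups <- function(x) unique(survivalData(x)$group)

#' ExpressionStudy: summarized log2 expression with probe-to-gene map
#'
#' Thin wrapper around \link[SummarizedExperiment]{SummarizedExperiment}:
#' the single assay \code{"log2"} holds a probes-by-samples matrix of log2
#' intensities; \code{rowData} carries the probe-to-gene symbol map
#' (column \code{gene}); \code{colData} carries the sample-to-group design
#' (column \code{group}).
#'
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    return("assay 'log2' required")
  if (!"gene" %in% names(SummarizedExperiment::rowData(object)))
    return("rowData column 'gene' (probe-to-gene map) required")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    return("colData column 'group' (design) required")
  grp <- SummarizedExperiment::colData(object)$group
  if (any(is.na(grp)) || any(grp == ""))
    return("every sample needs a non-empty group label")
  TRUE
})

#' Construct an ExpressionStudy
#'
#' @param log2mat numeric matrix, probes x samples, log2 scale, with probe
#'   ids as rownames and sample ids as colnames.
#' @param probe_gene character vector mapping each probe (row) to a gene
#'   symbol, in row order or named by probe id.
#' @param group character vector of group labels, one per sample.
#' @return an \code{ExpressionStudy}.
#' @export
ExpressionStudy <- function(log2mat, probe_gene, group) {
  stopifnot(is.matrix(log2mat), !is.null(rownames(log2mat)),
            !is.null(colnames(log2mat)))
  if (!is.null(names(probe_gene)))
    probe_gene <- probe_gene[rownames(log2mat)]
  stopifnot(length(probe_gene) == nrow(log2mat),
            length(group) == ncol(log2mat))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = log2mat),
    rowData = S4Vectors::DataFrame(gene = as.character(probe_gene),
                                   row.names = rownames(log2mat)),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(log2mat)))
  new("ExpressionStudy", se)
}

#' @describeIn ExpressionStudy the log2 intensity matrix
#' @param x an \code{ExpressionStudy}
#' @export
exprMatrix <- function(x) SummarizedExperiment::assay(x, "log2")

#' @describeIn ExpressionStudy named character vector probe -> gene symbol
#' @export
probeGeneMap <- function(x) {
  setNames(SummarizedExperiment::rowData(x)$gene, rownames(x))
}

#' @describeIn ExpressionStudy sample group labels, named by sample id
#' @export
sampleGroups <- function(x) {
  setNames(SummarizedExperiment::colData(x)$group, colnames(x))
}

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy:", nrow(object), "probes x", ncol(object),
      "samples;", length(unique(SummarizedExperiment::rowData(object)$gene)),
      "unique genes\n")
  print(table(sampleGroups(object)))
})

#' PWMRecord: a position frequency/weight matrix pair
#'
#' A motif from a binding-site dictionary. The PFM holds nonnegative base
#' counts (rows A, C, G, T); the PWM holds per-position base probabilities
#' derived from the PFM with a pseudocount, so every score is nonnegative
#' and a fractional-of-maximum match threshold is well defined.
#'
#' @slot id motif identifier.
#' @slot source_db origin tag: "jaspar-like", "uniprobe-like",
#'   "transfac-like" or "custom".
#' @slot pfm 4 x L nonnegative count matrix, rownames A,C,G,T.
#' @slot pwm 4 x L probability matrix derived from \code{pfm}.
#' @slot max_score maximum attainable window score (sum of column maxima).
#' @slot min_score minimum attainable window score (sum of column minima).
#' @export
setClass("PWMRecord",
         representation(id = "character", source_db = "character",
                        pfm = "matrix", pwm = "matrix",
                        max_score = "numeric", min_score = "numeric"))

setValidity("PWMRecord", function(object) {
  if (!identical(rownames(object@pfm), c("A", "C", "G", "T")))
    return("pfm rownames must be A, C, G, T")
  if (ncol(object@pfm) < 4L)
    return("motif length must be at least 4 bases")
  if (any(object@pfm < 0))
    return("pfm counts must be nonnegative")
  if (any(colSums(object@pfm) == 0))
    return("pfm columns must not be all zero")
  if (!identical(dim(object@pfm), dim(object@pwm)))
    return("pfm and pwm dimensions differ")
  TRUE
})

setMethod("show", "PWMRecord", function(object) {
  cat("PWMRecord", object@id, "(", object@source_db, "), length",
      ncol(object@pfm), "; maxScore", signif(object@max_score, 4), "\n")
  cat("consensus:", pwmConsensus(object), "\n")
})

#' @describeIn PWMRecord motif length in bases
#' @param x a \code{PWMRecord}
#' @export
pwmLength <- function(x) ncol(x@pfm)

#' @describeIn PWMRecord maximum attainable window score
#' @export
pwmMaxScore <- function(x) x@max_score

#' @describeIn PWMRecord consensus string (columnwise argmax base)
#' @export
pwmConsensus <- function(x) {
  paste(rownames(x@pwm)[apply(x@pwm, 2, which.max)], collapse = "")
}

#' TermDAG: an ontology fragment with propagated annotations
#'
#' A directed acyclic graph of terms (edges child -> parent, "is-a") plus
#' gene annotations. Annotations are propagated to all ancestors at
#' construction time (true-path rule), so term gene counts are well defined
#' before any conditional testing.
#'
#' @slot terms character vector of term ids.
#' @slot term_names named character vector of display names.
#' @slot edges data.frame with columns \code{child}, \code{parent}.
#' @slot annotations named list term id -> character vector of genes
#'   (already propagated to ancestors).
#' @export
setClass("TermDAG",
         representation(terms = "character", term_names = "character",
                        edges = "data.frame", annotations = "list"))

setValidity("TermDAG", function(object) {
  e <- object@edges
  if (nrow(e) > 0) {
    if (!all(c("child", "parent") %in% names(e)))
      return("edges need columns child, parent")
    if (!all(c(e$child, e$parent) %in% object@terms))
      return("edge endpoints must be known terms")
    g <- igraph::graph_from_data_frame(e[, c("child", "parent")],
                                       vertices = object@terms)
    if (!igraph::is_dag(g))
      return("term edges must form an acyclic graph")
  }
  if (!all(names(object@annotations) %in% object@terms))
    return("annotations must map known terms")
  TRUE
})

#' Construct a TermDAG with true-path annotation propagation
#'
#' @param edges data.frame with columns \code{child}, \code{parent}
#'   (is-a relations).
#' @param annotations data.frame with columns \code{gene}, \code{term}:
#'   direct annotations; each gene is propagated to all ancestor terms.
#' @param terms optional character vector of all term ids (defaults to
#'   those seen in edges and annotations).
#' @param term_names optional named character vector of display names.
#' @return a \code{TermDAG}.
#' @export
TermDAG <- function(edges, annotations, terms = NULL, term_names = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (is.null(terms))
    terms <- unique(c(edges$child, edges$parent, annotations$term))
  terms <- as.character(terms)
  if (is.null(term_names))
    term_names <- setNames(terms, terms)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, c("child", "parent")] else
      data.frame(child = character(), parent = character()),
    vertices = terms)
  if (!igraph::is_dag(g))
    stop("term edges must form an acyclic graph")
  # ancestors of each term (including itself), child -> parent direction
  anc <- lapply(seq_along(terms), function(i) {
    terms[as.integer(igraph::subcomponent(g, i, mode = "out"))]
  })
  names(anc) <- terms
  ann <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(annotations))) {
    g_i <- annotations$gene[i]
    for (tm in anc[[annotations$term[i]]]) {
      ann[[tm]] <- c(ann[[tm]], g_i)
    }
  }
  ann_list <- lapply(as.list(ann), function(v) sort(unique(v)))
  new("TermDAG", terms = terms, term_names = term_names,
      edges = edges, annotations = ann_list)
}

setMethod("show", "TermDAG", function(object) {
  cat("TermDAG with", length(object@terms), "terms,",
      nrow(object@edges), "edges;",
      length(unique(unlist(object@annotations))), "annotated genes\n")
})

#' @describeIn TermDAG genes annotated to a term (after propagation)
#' @param x a \code{TermDAG}
#' @param term a term id
#' @export
termGenes <- function(x, term) {
  stopifnot(term %in% x@terms)
  g <- x@annotations[[term]]
  if (is.null(g)) character() else g
}

#' @describeIn TermDAG all term ids
#' @export
dagTerms <- function(x) x@terms

#' @describeIn TermDAG direct children of a term
#' @export
termChildren <- function(x, term) {
  x@edges$child[x@edges$parent == term]
}
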