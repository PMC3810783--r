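#' @importFrom Biostrings BStringSet readBStringSet writeXStringSet
NULL

stopParse <- function(file, line, rule) {
  stop("parse error in '", file, "' at line ", line, ": ", rule,
       call. = FALSE)
}

readTsv <- function(file) {
  read.delim(file, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

writeTsv <- function(d, file, header_lines = character()) {
  con <- file(file, open = "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a survival table as TSV
#'
#' Tab-separated, one row per animal. The reader accepts either the
#' package's own column names (\code{animal_id}, \code{group},
#' \code{time}, \code{event}) or the field-style ones (\code{genotype}
#' for group, \code{days} for time); extra columns (sex, diet, ...) are
#' kept. Lines starting with \code{#} are ignored.
#'
#' @param file path.
#' @return a \code{\link{SurvivalTable}}.
#' @export
readSurvivalTable <- function(file) {
  d <- readTsv(file)
  if (!"group" %in% names(d) && "genotype" %in% names(d))
    names(d)[names(d) == "genotype"] <- "group"
  if (!"time" %in% names(d) && "days" %in% names(d))
    names(d)[names(d) == "days"] <- "time"
  need <- c("animal_id", "group", "time", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopParse(file, 1, paste("missing column(s):", paste(miss, collapse = ", ")))
  d$event <- as.integer(d$event)
  new("SurvivalTable", data = d)
}

#' @rdname readSurvivalTable
#' @param table a \code{SurvivalTable}.
#' @param header_lines optional comment lines written with a \code{#}
#'   prefix.
#' @export
writeSurvivalTable <- function(table, file, header_lines = character()) {
  writeTsv(survivalData(table), file, header_lines)
  invisible(file)
}

#' Read / write an expression study as TSV
#'
#' The expression file has columns \code{probe_id}, \code{gene}, then one
#' column per sample (log2 intensities); the design file has columns
#' \code{sample}, \code{group}.
#'
#' @param expr_file path of the expression matrix TSV.
#' @param design_file path of the design TSV.
#' @return an \code{\link{ExpressionStudy}}.
#' @export
readExpressionStudy <- function(expr_file, design_file) {
  d <- readTsv(expr_file)
  if (!all(c("probe_id", "gene") %in% names(d)))
    stopParse(expr_file, 1, "columns probe_id and gene required")
  des <- readTsv(design_file)
  if (!all(c("sample", "group") %in% names(des)))
    stopParse(design_file, 1, "columns sample and group required")
  samp <- setdiff(names(d), c("probe_id", "gene"))
  if (!setequal(samp, des$sample))
    stop("design samples do not match expression columns")
  m <- as.matrix(d[, des$sample, drop = FALSE])
  rownames(m) <- d$probe_id
  ExpressionStudy(m, setNames(d$gene, d$probe_id), des$group)
}

#' @rdname readExpressionStudy
#' @param study an \code{ExpressionStudy}.
#' @param header_lines optional \code{#}-prefixed comment lines.
#' @export
writeExpressionStudy <- function(study, expr_file, design_file,
                                 header_lines = character()) {
  m <- exprMatrix(study)
  d <- data.frame(probe_id = rownames(m),
                  gene = unname(probeGeneMap(study)),
                  m, check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(d, expr_file, header_lines)
  writeTsv(data.frame(sample = colnames(m),
                      group = unname(sampleGroups(study))),
           design_file, header_lines)
  invisible(expr_file)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then one gene per tab-separated
#' field. Lines with fewer than three fields are a format error reported
#' with their line number.
#'
#' @param file path.
#' @return named list of character gene vectors, with a
#'   \code{"descriptions"} attribute.
#' @export
readGMT <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stopParse(file, i, "GMT line needs >= 3 tab-separated fields")
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname readGMT
#' @param sets named list of character gene vectors.
#' @param descriptions optional per-set description strings.
#' @export
writeGMT <- function(sets, file, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read / write masked FASTA
#'
#' Sequences are kept as raw byte strings so lowercase soft-masking
#' survives the round trip untouched.
#'
#' @param file path.
#' @return named character vector of sequences.
#' @export
readMaskedFasta <- function(file) {
  x <- Biostrings::readBStringSet(file)
  setNames(as.character(x), names(x))
}

#' @rdname readMaskedFasta
#' @param sequences named character vector.
#' @export
writeMaskedFasta <- function(sequences, file) {
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read / write a motif dictionary in JASPAR-style PFM text
#'
#' Records start with a \code{">id"} header (an optional second token is
#' kept as the source tag) followed by four rows of counts for A, C, G
#' and T, with or without the \code{A [ ... ]} bracket decoration.
#'
#' @param file path.
#' @param pseudocount,background passed to \code{\link{buildPWM}}.
#' @return named list of \code{\link{PWMRecord}} objects.
#' @export
readPFMs <- function(file, pseudocount = 0.25,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stopParse(file, 1, "no '>' record header found")
  out <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i]
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    toks <- strsplit(sub("^>", "", lines[from]), "\\s+")[[1]]
    id <- toks[1]
    src <- if (length(toks) > 1) toks[2] else "custom"
    body <- lines[(from + 1):to]
    if (length(body) != 4)
      stopParse(file, from, "expected exactly 4 count rows after header")
    rows <- lapply(seq_along(body), function(j) {
      ln <- gsub("^[ACGTacgt]\\s*", "", trimws(body[j]))
      ln <- gsub("[][]", " ", ln)
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (any(is.na(v)))
        stopParse(file, from + j, "non-numeric count field")
      v
    })
    if (length(unique(lengths(rows))) != 1)
      stopParse(file, from, "count rows differ in length")
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    out[[id]] <- buildPWM(pfm, id = id, source_db = src,
                          pseudocount = pseudocount,
                          background = background)
  }
  out
}

#' @rdname readPFMs
#' @param dictionary list of \code{PWMRecord} objects.
#' @export
writePFMs <- function(dictionary, file) {
  con <- file(file, open = "w")
  on.exit(close(con))
  for (p in dictionary) {
    writeLines(paste0(">", p@id, " ", p@source_db), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ", paste(p@pfm[b, ], collapse = " "), " ]"),
                 con)
  }
  invisible(file)
}

#' Read DAG edges and annotations from TSV
#'
#' Edges TSV needs columns \code{child}, \code{parent}; annotations TSV
#' needs \code{gene}, \code{term}.
#'
#' @param edges_file,annotations_file paths.
#' @return a \code{\link{TermDAG}} (annotations propagated to ancestors).
#' @export
readTermDAG <- function(edges_file, annotations_file) {
  e <- readTsv(edges_file)
  if (!all(c("child", "parent") %in% names(e)))
    stopParse(edges_file, 1, "columns child and parent required")
  a <- readTsv(annotations_file)
  if (!all(c("gene", "term") %in% names(a)))
    stopParse(annotations_file, 1, "columns gene and term required")
  TermDAG(e, a)
}

#' Read / write a ranked experiment list (gene, score TSV)
#'
#' @param file path of a TSV with columns \code{gene}, \code{score}.
#' @param experiment_id label (defaults to the file name).
#' @return a \code{\link{rankedList}}.
#' @export
readRankedList <- function(file, experiment_id = basename(file)) {
  d <- readTsv(file)
  if (!all(c("gene", "score") %in% names(d)))
    stopParse(file, 1, "columns gene and score required")
  rankedList(d$gene, d$score, experiment_id = experiment_id)
}

#' @rdname readRankedList
#' @param list a \code{rankedList}.
#' @export
writeRankedList <- function(list, file) {
  writeTsv(list[, c("gene", "score")], file)
  invisible(file)
}

#' Read a qPCR Ct table (sample, condition, gene, ct TSV)
#'
#' @param file path.
#' @return data.frame suitable for \code{\link{foldInduction}}.
#' @export
readQpcrTable <- function(file) {
  d <- readTsv(file)
  if (!all(c("sample", "condition", "gene", "ct") %in% names(d)))
    stopParse(file, 1, "columns sample, condition, gene, ct required")
  d
}

#' @rdname readQpcrTable
#' @param plate a Ct data.frame.
#' @export
writeQpcrTable <- function(plate, file) {
  writeTsv(plate, file)
  invisible(file)
}
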