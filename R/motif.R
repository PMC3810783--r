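#' Build a PWMRecord from a position frequency matrix
#'
#' Converts base counts to per-position probabilities with a pseudocount:
#' score(b, j) = (pfm[b, j] + pseudocount * background[b]) /
#' (colsum(j) + pseudocount). A window score is the sum of its per-position
#' probabilities, so all scores are nonnegative and thresholding at a
#' fraction of the maximum attainable score is well posed (log-odds scores
#' can be negative, which would make a fractional threshold ill-defined).
#' Motifs shorter than 4 bases are rejected, mirroring the dictionary
#' filter that excludes very short sites.
#'
#' @param pfm 4 x L nonnegative count matrix; rows A, C, G, T (rownames
#'   added if missing).
#' @param id motif identifier.
#' @param source_db origin tag (default "custom").
#' @param pseudocount added mass per column, spread by \code{background}
#'   (default 0.25).
#' @param background base composition used for the pseudocount, summing
#'   to 1 (default uniform).
#' @return a \code{\link{PWMRecord}}.
#' @export
buildPWM <- function(pfm, id = "motif", source_db = "custom",
                     pseudocount = 0.25,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  pfm <- as.matrix(pfm)
  if (is.null(rownames(pfm))) rownames(pfm) <- c("A", "C", "G", "T")
  stopifnot(nrow(pfm) == 4, pseudocount >= 0,
            abs(sum(background) - 1) < 1e-9)
  if (ncol(pfm) < 4)
    stop("motif '", id, "' rejected: fewer than 4 base pairs")
  pwm <- sweep(pfm + pseudocount * background,
               2, colSums(pfm) + pseudocount, "/")
  new("PWMRecord", id = id, source_db = source_db, pfm = pfm, pwm = pwm,
      max_score = sum(apply(pwm, 2, max)),
      min_score = sum(apply(pwm, 2, min)))
}

# encode an upper-case A/C/G/T character vector as 1..4; anything else
# (N, lowercase soft-masking, IUPAC ambiguity) becomes NA = ineligible
encodeBases <- function(chars) {
  match(chars, c("A", "C", "G", "T"))
}

# reverse complement preserving masking case; N stays N
revcompMasked <- function(seq) {
  from <- c("A", "C", "G", "T", "a", "c", "g", "t")
  to   <- c("T", "G", "C", "A", "t", "g", "c", "a")
  chars <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  idx <- match(chars, from)
  out <- ifelse(is.na(idx), chars, to[idx])
  paste(out, collapse = "")
}

# scan one strand: returns eligible window starts, their scores
scanOneStrand <- function(chars, pwm_mat) {
  L <- ncol(pwm_mat)
  n <- length(chars)
  if (n < L) return(list(starts = integer(), scores = numeric()))
  code <- encodeBases(chars)
  bad <- cumsum(c(0L, is.na(code)))
  starts <- seq_len(n - L + 1L)
  eligible <- (bad[starts + L] - bad[starts]) == 0L
  starts <- starts[eligible]
  if (length(starts) == 0) return(list(starts = integer(), scores = numeric()))
  sc <- numeric(length(starts))
  for (j in seq_len(L)) {
    sc <- sc + pwm_mat[cbind(code[starts + j - 1L], j)]
  }
  list(starts = starts, scores = sc)
}

#' Scan a masked sequence for PWM matches
#'
#' Slides every window of motif length over the requested strands of a
#' promoter region. Windows containing any masked base (lowercase
#' soft-masking or N hard-masking) are ineligible and are excluded from
#' both matching and the scanned-length covariate. A window is a match
#' when its score strictly exceeds \code{min_frac} of the motif's maximum
#' attainable score (default 0.80).
#'
#' @param seq a character string over A/C/G/T/N plus lowercase masking.
#' @param pwm a \code{\link{PWMRecord}}.
#' @param min_frac fractional score threshold (default 0.80).
#' @param strands \code{"both"} (default), \code{"forward"} or
#'   \code{"reverse"}.
#' @param score_scale \code{"absolute"} thresholds on
#'   \code{min_frac * maxScore} (default); \code{"range"} thresholds on
#'   \code{minScore + min_frac * (maxScore - minScore)}.
#' @return list of class \code{"ScanResult"}: \code{count},
#'   \code{scanned_length} (eligible window starts summed over strands),
#'   \code{matches} (data.frame position, strand, score; positions are
#'   1-based forward-strand window starts).
#' @export
scanRegion <- function(seq, pwm, min_frac = 0.80,
                       strands = c("both", "forward", "reverse"),
                       score_scale = c("absolute", "range")) {
  strands <- match.arg(strands)
  score_scale <- match.arg(score_scale)
  stopifnot(is(pwm, "PWMRecord"), length(seq) == 1, min_frac >= 0)
  L <- pwmLength(pwm)
  cutoff <- if (score_scale == "absolute") min_frac * pwm@max_score else
    pwm@min_score + min_frac * (pwm@max_score - pwm@min_score)
  n <- nchar(seq)
  matches <- list()
  scanned <- 0L
  if (strands %in% c("both", "forward")) {
    sf <- scanOneStrand(strsplit(seq, "", fixed = TRUE)[[1]], pwm@pwm)
    scanned <- scanned + length(sf$starts)
    hit <- sf$scores > cutoff
    matches$fwd <- data.frame(position = sf$starts[hit],
                              strand = rep("+", sum(hit)),
                              score = sf$scores[hit],
                              stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "reverse")) {
    rc <- revcompMasked(seq)
    sr <- scanOneStrand(strsplit(rc, "", fixed = TRUE)[[1]], pwm@pwm)
    scanned <- scanned + length(sr$starts)
    hit <- sr$scores > cutoff
    matches$rev <- data.frame(position = n - (sr$starts[hit] + L - 1L) + 1L,
                              strand = rep("-", sum(hit)),
                              score = sr$scores[hit],
                              stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, c(matches, list(make.row.names = FALSE)))
  if (is.null(m))
    m <- data.frame(position = integer(), strand = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  m <- m[order(m$position, m$strand), , drop = FALSE]
  rownames(m) <- NULL
  out <- list(count = nrow(m), scanned_length = scanned, matches = m,
              motif = pwm@id)
  class(out) <- "ScanResult"
  out
}

#' @export
print.ScanResult <- function(x, ...) {
  cat(sprintf("ScanResult for %s: %d match(es) over %d eligible window start(s)\n",
              x$motif, x$count, x$scanned_length))
  invisible(x)
}

#' Motif count table over a promoter collection
#'
#' Scans every gene's upstream region against every motif in a dictionary
#' and assembles the per-(gene, motif) count and scanned-length covariates
#' used by the enrichment models.
#'
#' @param sequences named character vector (or \code{BStringSet}) of
#'   masked promoter sequences; names are gene ids and must be unique.
#' @param dictionary list of \code{\link{PWMRecord}} objects.
#' @param ... passed to \code{\link{scanRegion}} (\code{min_frac},
#'   \code{strands}, ...).
#' @return data.frame with columns \code{gene}, \code{motif}, \code{count},
#'   \code{scanned_length}; genes in input order, motifs in dictionary
#'   order.
#' @export
countTable <- function(sequences, dictionary, ...) {
  if (is(sequences, "XStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  stopifnot(length(dictionary) >= 1)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by gene id")
  ids <- vapply(dictionary, function(p) p@id, character(1))
  rows <- vector("list", length(sequences) * length(dictionary))
  k <- 0L
  for (g in names(sequences)) {
    for (i in seq_along(dictionary)) {
      sr <- scanRegion(sequences[[g]], dictionary[[i]], ...)
      k <- k + 1L
      rows[[k]] <- data.frame(gene = g, motif = ids[i], count = sr$count,
                              scanned_length = sr$scanned_length,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
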