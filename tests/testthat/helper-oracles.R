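# Independent brute-force oracles used to check the package's
# implementations. These are deliberately written as plain loops over
# definitions, sharing no code with the package internals.

# hypergeometric point mass via binomial coefficients
oracleHyperPmf <- function(k, K, n, N) {
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

# upper tail P(X >= k) by summation
oracleHyperTail <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(K, n)
  sum(vapply(ks[ks >= k], oracleHyperPmf, numeric(1), K = K, n = n, N = N))
}

# two-sided Fisher exact p for a 2x2 table by enumerating all tables with
# the observed margins and summing those no more probable than observed
oracleFisherTwoSided <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pk <- vapply(ks, oracleHyperPmf, numeric(1), K = r1, n = c1, N = N)
  pobs <- oracleHyperPmf(tab[1, 1], K = r1, n = c1, N = N)
  sum(pk[pk <= pobs * (1 + 1e-7)])
}

# Kaplan-Meier by direct product-limit recursion
oracleKM <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(event_times = ut, survival = surv)
}

# exhaustive all-windows PWM scan: score every window by explicit
# character lookup, skip any window touching a non-upper-ACGT character
oracleScan <- function(seq, pwm, min_frac = 0.8, strands = "both") {
  scanStrand <- function(s) {
    L <- ncol(pwm@pwm)
    n <- nchar(s)
    cnt <- 0L
    if (n < L) return(cnt)
    for (start in 1:(n - L + 1)) {
      w <- substr(s, start, start + L - 1)
      letters_w <- strsplit(w, "")[[1]]
      if (any(!letters_w %in% c("A", "C", "G", "T"))) next
      sc <- 0
      for (j in 1:L) sc <- sc + pwm@pwm[letters_w[j], j]
      if (sc > min_frac * pwm@max_score) cnt <- cnt + 1L
    }
    cnt
  }
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A",
              a = "t", c = "g", g = "c", t = "a")
    ch <- rev(strsplit(s, "")[[1]])
    paste(ifelse(ch %in% names(comp), comp[ch], ch), collapse = "")
  }
  total <- 0L
  if (strands %in% c("both", "forward")) total <- total + scanStrand(seq)
  if (strands %in% c("both", "reverse")) total <- total + scanStrand(rc(seq))
  total
}

# random masked sequence for scanner fuzzing
randomMaskedSeq <- function(len, mask_prob = 0.15, n_prob = 0.05) {
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  low <- runif(len) < mask_prob
  ch[low] <- tolower(ch[low])
  nn <- runif(len) < n_prob
  ch[nn] <- "N"
  paste(ch, collapse = "")
}

randomPWM <- function(L = NULL, id = "rnd") {
  if (is.null(L)) L <- sample(4:9, 1)
  pfm <- matrix(sample(0:10, 4 * L, replace = TRUE), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  bad <- colSums(pfm) == 0
  pfm[1, bad] <- 1
  buildPWM(pfm, id = id)
}

# a deterministic single-consensus PWM for a given string
consensusPWM <- function(consensus, id = "cons") {
  ch <- strsplit(consensus, "")[[1]]
  pfm <- matrix(0, nrow = 4, ncol = length(ch),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm[cbind(match(ch, c("A", "C", "G", "T")), seq_along(ch))] <- 10
  buildPWM(pfm, id = id, pseudocount = 0)
}

# tiny survival table builder
makeSurv <- function(times, events = NULL, group = "A") {
  if (is.null(events)) events <- rep(1L, length(times))
  SurvivalTable(sprintf("%s_%03d", group, seq_along(times)),
                rep(group, length(times)), times, events)
}

bindSurv <- function(...) {
  ds <- lapply(list(...), survivalData)
  new("SurvivalTable", data = do.call(rbind, ds))
}
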