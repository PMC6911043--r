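## Independent oracles, deliberately naive implementations.

## type-7 sample quantile by direct interpolation of order statistics
oracleQuantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

## two-sided Fisher exact p by full enumeration of tables with the observed
## margins, summing probabilities <= that of the observed table
oracleFisherP <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  aa <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, aa) + lchoose(r2, c1 - aa) - lchoose(n, c1)
  p <- exp(logp)
  pObs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  sum(p[p <= pObs * (1 + 1e-7)])
}

## Beta(1,1)-binomial Bayes factor by numerical integration
oracleBF <- function(i1, e1, i2, e2) {
  marg <- function(i, e) {
    ## scale by the mode so the integrand is O(1) and rel.tol is honoured
    m <- if (i + e > 0) i / (i + e) else 0.5
    sc <- i * log(ifelse(m > 0, m, 1)) + e * log(ifelse(m < 1, 1 - m, 1))
    v <- stats::integrate(function(th) exp(i * log(th) + e * log1p(-th) -
                                             sc),
                          0, 1, rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 500L)$value
    list(log = log(v) + sc)
  }
  exp(marg(i1, e1)$log + marg(i2, e2)$log - marg(i1 + i2, e1 + e2)$log)
}

## two-sided exact binomial p, minimum-likelihood rule, by enumeration
oracleBinomP <- function(k, n, p0) {
  probs <- vapply(0:n, function(x)
    exp(lchoose(n, x) + x * log(p0) + (n - x) * log(1 - p0)), 0)
  pObs <- probs[k + 1]
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

## brute-force cluster assignment from a display-offset count vector
oracleCluster <- function(counts, span = 25L, minFrac = 0.10,
                          minTotal = 10L) {
  tot <- sum(counts)
  if (tot <= minTotal) return("excluded")
  offs <- as.integer(names(counts))
  fr <- counts / tot
  best <- -Inf; bestOff <- NA
  for (i in order(offs)) {
    if (fr[i] > best) { best <- fr[i]; bestOff <- offs[i] }
  }
  if (bestOff >= -6 && bestOff <= 2 && best >= minFrac)
    paste0("C", bestOff + 7L) else "C10"
}

## hexamer frequencies of a character vector of windows, by substring
oracleHexamerFreq <- function(seqs) {
  hex <- character(0)
  for (s in seqs) {
    if (nchar(s) >= 6) {
      starts <- seq_len(nchar(s) - 5L)
      hex <- c(hex, substring(s, starts, starts + 5L))
    }
  }
  hex <- hex[!grepl("[^ACGT]", hex)]
  tab <- table(factor(hex, levels = Biostrings::mkAllStrings(
    c("A", "C", "G", "T"), 6L)))
  as.numeric(tab) / sum(tab)
}
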