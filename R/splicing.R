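## Differential-splicing calling and cohort co-association statistics.
##
## Two-condition calls use psi = inclusion/(inclusion+exclusion), a
## Beta(1,1)-binomial marginal-likelihood-ratio Bayes factor (independent
## psi vs shared psi), and the gates |dpsi| >= 0.10, BF >= 5, >= 10
## supporting reads.  Cohort (two-group matrix) calls use a Welch t-test
## at p < 0.05 with |median difference| >= 0.025.

#' Percent spliced in from read counts
#'
#' @param inclusion,exclusion nonnegative read counts (vectorised).
#' @return `inclusion / (inclusion + exclusion)`; `NA` where the total is
#'   zero.
#' @export
psiFromCounts <- function(inclusion, exclusion) {
  tot <- inclusion + exclusion
  ifelse(tot > 0, inclusion / tot, NA_real_)
}

#' Beta-binomial Bayes factor for differential inclusion
#'
#' Marginal-likelihood ratio of the independent-psi model (one Beta(1,1)
#' psi per condition) against the shared-psi model (a single Beta(1,1)
#' psi), computed with exact Beta-function identities:
#' `BF = B(i1+1, e1+1) B(i2+1, e2+1) / B(i1+i2+1, e1+e2+1)` (the binomial
#' coefficients cancel).  `BF > 1` favours different inclusion levels;
#' with zero reads in one condition the contributions cancel and BF = 1.
#'
#' @param inc1,exc1 inclusion/exclusion counts in condition 1 (vectorised).
#' @param inc2,exc2 counts in condition 2.
#' @return Numeric Bayes factor(s).
#' @export
bayesFactor <- function(inc1, exc1, inc2, exc2) {
  exp(lbeta(inc1 + 1, exc1 + 1) + lbeta(inc2 + 1, exc2 + 1) -
        lbeta(inc1 + inc2 + 1, exc1 + exc2 + 1))
}

#' Call differentially spliced events between two conditions
#'
#' @param events event-count data.frame (see [validateEventCounts()]) with
#'   conditions `"wt"` and `"mut"`.
#' @param dpsiMin minimum |dpsi| (default 0.10).
#' @param bfMin minimum Bayes factor (default 5).
#' @param readsMin minimum supporting reads, taken as the smaller of the
#'   two conditions' inclusion+exclusion totals (default 10).
#' @return data.frame per event: `event_id`, `type`, `site_id`, `psi_wt`,
#'   `psi_mut`, `dpsi`, `bayes_factor`, `supporting_reads`, `call`
#'   (`mut_preferred` / `wt_preferred` / `none`).
#' @export
callDifferentialEvents <- function(events, dpsiMin = 0.10, bfMin = 5,
                                   readsMin = 10L) {
  validateEventCounts(events)
  wt <- events[events$condition == "wt", ]
  mut <- events[events$condition == "mut", ]
  m <- merge(wt, mut, by = "event_id", suffixes = c("_wt", "_mut"))
  psiWt <- psiFromCounts(m$inclusion_wt, m$exclusion_wt)
  psiMut <- psiFromCounts(m$inclusion_mut, m$exclusion_mut)
  dpsi <- psiMut - psiWt
  bf <- bayesFactor(m$inclusion_wt, m$exclusion_wt,
                    m$inclusion_mut, m$exclusion_mut)
  reads <- pmin(m$inclusion_wt + m$exclusion_wt,
                m$inclusion_mut + m$exclusion_mut)
  pass <- !is.na(dpsi) & abs(dpsi) >= dpsiMin & bf >= bfMin &
    reads >= readsMin
  call <- ifelse(pass & dpsi > 0, "mut_preferred",
                 ifelse(pass & dpsi < 0, "wt_preferred", "none"))
  data.frame(event_id = m$event_id, type = m$type_wt,
             site_id = if ("site_id_wt" %in% names(m)) m$site_id_wt else NA,
             psi_wt = psiWt, psi_mut = psiMut, dpsi = dpsi,
             bayes_factor = bf, supporting_reads = reads, call = call,
             stringsAsFactors = FALSE)
}

#' Event-type frequency test
#'
#' Chi-squared goodness-of-fit of called-event type counts against the
#' annotation's event-type proportions.  Types with zero expected
#' proportion but nonzero observed count are merged into the largest
#' expected category (with a warning).
#'
#' @param calls output of [callDifferentialEvents()] restricted (by the
#'   caller) to called events, or any data.frame with a `type` column.
#' @param annotationCounts named vector of event-type counts (or
#'   proportions) in the annotation database.
#' @return list: `observed`, `observed_pct`, `expected_pct`, `chisq`,
#'   `df`, `p`.
#' @export
eventTypeFrequencyTest <- function(calls, annotationCounts) {
  obs <- table(factor(calls$type, levels = names(annotationCounts)))
  expProp <- annotationCounts / sum(annotationCounts)
  if (any(expProp == 0 & obs > 0)) {
    warning("event types with zero expected proportion merged into the ",
            "largest category")
    tgt <- names(which.max(expProp))
    bad <- names(expProp)[expProp == 0 & obs > 0]
    obs[tgt] <- obs[tgt] + sum(obs[bad])
    keep <- setdiff(names(expProp), bad)
    obs <- obs[keep]; expProp <- expProp[keep]
  }
  keep <- expProp > 0
  obs <- obs[keep]; expProp <- expProp[keep] / sum(expProp[keep])
  if (length(obs) < 2L)
    return(list(observed = as.numeric(obs), observed_pct = 100,
                expected_pct = 100, chisq = 0, df = 0L, p = 1))
  ct <- suppressWarnings(chisq.test(as.numeric(obs), p = expProp))
  list(observed = as.numeric(obs),
       observed_pct = 100 * as.numeric(obs) / sum(obs),
       expected_pct = 100 * as.numeric(expProp),
       chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Acceptor trinucleotide frequencies of skipped exons by dpsi direction
#'
#' For skipped-exon (SE) calls, the frequency of each acceptor
#' trinucleotide at the alternative exon's 3'SS, separately for events
#' with increased vs decreased inclusion.
#'
#' @param calls output of [callDifferentialEvents()].
#' @param sites GRanges splice-site table carrying `acceptor`.
#' @return matrix 64 trinucleotides x 2 (`increased`, `decreased`);
#'   columns sum to 1 (all-zero when a stratum is empty, with a warning).
#' @export
seAcceptorTrinucleotides <- function(calls, sites) {
  se <- calls[calls$type == "SE" & calls$call != "none", , drop = FALSE]
  tris <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3L)
  out <- matrix(0, 64L, 2L, dimnames = list(tris, c("increased",
                                                    "decreased")))
  if (!nrow(se)) {
    warning("no called skipped-exon events")
    return(out)
  }
  acc <- setNames(sites$acceptor, sites$site_id)[se$site_id]
  dir <- ifelse(se$dpsi > 0, "increased", "decreased")
  for (d in colnames(out)) {
    tab <- table(factor(acc[dir == d], levels = tris))
    if (sum(tab) > 0) out[, d] <- as.numeric(tab) / sum(tab)
  }
  out
}

#' Cohort differential-splicing caller
#'
#' Per event: two-sided Welch t-test comparing the two groups' psi values
#' and the difference of group medians.  Events with fewer than two
#' non-missing psi values in either group are skipped.
#'
#' @param psi SummarizedExperiment from [psiExperiment()].
#' @param groupI,groupII group labels (group I is the mutant cohort).
#' @param pMax t-test p-value threshold (default 0.05).
#' @param dmedianMin minimum |median difference| (default 0.025).
#' @return data.frame: `event_id`, `n_I`, `n_II`, `p`, `dmedian`,
#'   `called`, `direction` (+1 increased in group I, -1 decreased, 0 not
#'   called), `skipped`.
#' @export
cohortCall <- function(psi, groupI = "mut", groupII = "wt", pMax = 0.05,
                       dmedianMin = 0.025) {
  mat <- SummarizedExperiment::assay(psi, "psi")
  gi <- psi$group == groupI
  gii <- psi$group == groupII
  res <- lapply(seq_len(nrow(mat)), function(i) {
    a <- mat[i, gi]; b <- mat[i, gii]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(c(length(a), length(b), NA, NA))
    p <- if (sd(a) == 0 && sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else t.test(a, b, var.equal = FALSE)$p.value
    c(length(a), length(b), p, median(a) - median(b))
  })
  res <- do.call(rbind, res)
  skipped <- is.na(res[, 3L])
  called <- !skipped & res[, 3L] < pMax & abs(res[, 4L]) >= dmedianMin
  if (any(skipped))
    message(sum(skipped), " events skipped (fewer than 2 psi values in a ",
            "group)")
  data.frame(event_id = rownames(mat), n_I = res[, 1L], n_II = res[, 2L],
             p = res[, 3L], dmedian = res[, 4L], called = called,
             direction = ifelse(called, sign(res[, 4L]), 0),
             skipped = skipped, stringsAsFactors = FALSE)
}

#' CAG/TAG acceptor co-association test on cohort calls
#'
#' Among called events with CAG or TAG acceptors, a 2x2 Fisher exact test
#' of acceptor {CAG, TAG} against the median-dpsi stratum
#' {> dmedianMin, <= -dmedianMin}.
#'
#' @param calls output of [cohortCall()].
#' @param eventSites named acceptor trinucleotide per event
#'   (event_id -> acceptor).
#' @param dmedianMin stratification threshold (default 0.025).
#' @return list: `table` (2x2), `odds_ratio`, `p` (see
#'   [fisherContingency()]).
#' @export
cohortCagTagTest <- function(calls, eventSites, dmedianMin = 0.025) {
  d <- calls[calls$called, , drop = FALSE]
  acc <- eventSites[d$event_id]
  keep <- acc %in% c("CAG", "TAG")
  d <- d[keep, , drop = FALSE]; acc <- acc[keep]
  up <- d$dmedian > dmedianMin
  dn <- d$dmedian <= -dmedianMin
  tab <- rbind(CAG = c(sum(acc == "CAG" & up), sum(acc == "CAG" & dn)),
               TAG = c(sum(acc == "TAG" & up), sum(acc == "TAG" & dn)))
  colnames(tab) <- c("up", "down")
  fisherContingency(tab)
}

#' Per-sample event Z-scores against the wild-type group
#'
#' `Z[i, j] = (psi[i, j] - mean(psi[i, WT])) / sd(psi[i, WT])` for every
#' non-wild-type sample j; `NA` where fewer than two wild-type values are
#' present or the wild-type SD is zero.
#'
#' @param psi SummarizedExperiment from [psiExperiment()].
#' @param wtGroup label of the wild-type (control) group.
#' @return Numeric matrix events x non-WT samples.
#' @export
eventZscores <- function(psi, wtGroup = "wt") {
  mat <- SummarizedExperiment::assay(psi, "psi")
  wt <- mat[, psi$group == wtGroup, drop = FALSE]
  other <- mat[, psi$group != wtGroup, drop = FALSE]
  mu <- apply(wt, 1L, function(x) mean(x, na.rm = TRUE))
  sdv <- apply(wt, 1L, function(x) sd(x[!is.na(x)]))
  nwt <- rowSums(!is.na(wt))
  sdv[nwt < 2L | sdv == 0] <- NA
  (other - mu) / sdv
}

#' Co-association of cohort Z-scores with reference inclusion direction
#'
#' Event x sample pairs with `|Z| > zThresh` are pooled and crossed with
#' the reference calls' inclusion direction, and the 2x2 table assessed
#' by a two-sided Fisher exact test.
#'
#' @param referenceCalls output of [callDifferentialEvents()] (the
#'   reference two-condition comparison); only called events are used.
#' @param zscores matrix from [eventZscores()].
#' @param zThresh Z threshold (default 1.64, right-tail p = 0.05).
#' @param perEvent count each event once (using its mean Z across
#'   samples) instead of pooling event x sample pairs.
#' @return list: `table` (2x2 Z-sign x reference direction),
#'   `odds_ratio`, `p`.
#' @export
overlapAssociation <- function(referenceCalls, zscores, zThresh = 1.64,
                               perEvent = FALSE) {
  ref <- referenceCalls[referenceCalls$call != "none", , drop = FALSE]
  common <- intersect(ref$event_id, rownames(zscores))
  if (!length(common)) stop("empty contingency: no shared events")
  dir <- setNames(ifelse(ref$dpsi > 0, "increased", "decreased"),
                  ref$event_id)[common]
  z <- zscores[common, , drop = FALSE]
  if (perEvent) z <- matrix(rowMeans(z, na.rm = TRUE), ncol = 1L,
                            dimnames = list(common, "meanZ"))
  pairDir <- rep(dir, times = ncol(z))
  zv <- as.vector(z)
  keep <- !is.na(zv) & abs(zv) > zThresh
  if (!any(keep)) stop("empty contingency: no |Z| above threshold")
  zv <- zv[keep]; pairDir <- pairDir[keep]
  tab <- rbind(`Z>thr` = c(sum(zv > 0 & pairDir == "increased"),
                           sum(zv > 0 & pairDir == "decreased")),
               `Z<-thr` = c(sum(zv < 0 & pairDir == "increased"),
                            sum(zv < 0 & pairDir == "decreased")))
  colnames(tab) <- c("increased", "decreased")
  fisherContingency(tab)
}
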