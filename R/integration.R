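## Cross-layer statistics: fold-change classifications, binding-expression
## concordance, binding-splicing co-association, mutation co-occurrence,
## and the hotspot binomial test.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] returning the table, the
#' conditional odds-ratio estimate and the two-sided p-value.  Degenerate
#' tables (any zero margin) return p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list: `table`, `odds_ratio`, `p`, `test = "fisher"`.
#' @export
fisherContingency <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(list(table = tab, odds_ratio = NA_real_, p = 1,
                test = "fisher"))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       test = "fisher")
}

#' Fold-change classification of paired gene-level values
#'
#' `mut_preferred` when `(mut + eps) / (wt + eps) > fc`, `wt_preferred`
#' when below `1/fc`, otherwise `neutral`.
#'
#' @param valuesWt,valuesMut nonnegative gene-level values (CLIP counts,
#'   FPKM-like abundances, ...).
#' @param fc fold-change threshold (default 1.5).
#' @param pseudocount added to both values before forming the ratio
#'   (default 1, appropriate for counts; use ~0.1 for abundance units).
#' @return Character vector of classes.
#' @export
foldChangeClasses <- function(valuesWt, valuesMut, fc = 1.5,
                              pseudocount = 1) {
  if (any(valuesWt < 0 | valuesMut < 0)) stop("values must be nonnegative")
  ratio <- (valuesMut + pseudocount) / (valuesWt + pseudocount)
  ifelse(ratio > fc, "mut_preferred",
         ifelse(ratio < 1 / fc, "wt_preferred", "neutral"))
}

#' Binding-expression concordance
#'
#' Classifies binding (CLIP counts) and expression with the fold-change
#' rule, counts genes preferred in the same direction on both layers, and
#' reports the ordinary-least-squares R^2 between the log2 binding ratio
#' and the log2 expression ratio.
#'
#' @param geneQuant data.frame with `gene_id`, `clip_wt`, `clip_mut`,
#'   `expr_wt`, `expr_mut`.
#' @param fc fold-change threshold (default 1.5).
#' @param clipPseudo,exprPseudo pseudocounts for the two layers (1 count /
#'   0.1 abundance units).
#' @return list: `binding_class`, `expression_class`, `n_mut_concordant`,
#'   `n_wt_concordant`, `r_squared`.
#' @export
bindingExpressionConcordance <- function(geneQuant, fc = 1.5,
                                         clipPseudo = 1, exprPseudo = 0.1) {
  if (!nrow(geneQuant)) stop("empty gene table")
  bc <- foldChangeClasses(geneQuant$clip_wt, geneQuant$clip_mut, fc,
                          clipPseudo)
  ec <- foldChangeClasses(geneQuant$expr_wt, geneQuant$expr_mut, fc,
                          exprPseudo)
  lb <- log2((geneQuant$clip_mut + clipPseudo) /
               (geneQuant$clip_wt + clipPseudo))
  le <- log2((geneQuant$expr_mut + exprPseudo) /
               (geneQuant$expr_wt + exprPseudo))
  r2 <- summary(lm(le ~ lb))$r.squared
  list(binding_class = bc, expression_class = ec,
       n_mut_concordant = sum(bc == "mut_preferred" & ec == "mut_preferred"),
       n_wt_concordant = sum(bc == "wt_preferred" & ec == "wt_preferred"),
       r_squared = r2)
}

#' Binding-splicing cluster-switch co-association
#'
#' Crosses strongly differentially spliced events (Bayes factor >= bfMin
#' and |dpsi| > dpsiMin) with cluster switches at their linked 3'SS and
#' runs a two-sided Fisher exact test.
#'
#' @param calls output of [callDifferentialEvents()] with `site_id` links.
#' @param switches output of [detectSwitches()].
#' @param bfMin,dpsiMin strong-event thresholds (default 10 and 0.10).
#' @param signed when TRUE only `dpsi > dpsiMin` (mutant-increased) events
#'   count as strong; default uses |dpsi|.
#' @return list: `table`, `odds_ratio`, `p`.
#' @export
bindingSplicingCoassociation <- function(calls, switches, bfMin = 10,
                                         dpsiMin = 0.10, signed = FALSE) {
  m <- merge(calls, switches[, c("site_id", "switch")], by = "site_id")
  if (!nrow(m)) stop("no events mapped to the switch table")
  dp <- if (signed) m$dpsi else abs(m$dpsi)
  strong <- !is.na(dp) & dp > dpsiMin & m$bayes_factor >= bfMin
  tab <- rbind(strong = c(sum(strong & m$switch), sum(strong & !m$switch)),
               other = c(sum(!strong & m$switch), sum(!strong & !m$switch)))
  colnames(tab) <- c("switch", "no_switch")
  fisherContingency(tab)
}

#' Mutation/fusion co-occurrence Fisher test from margins
#'
#' Builds the 2x2 table from cohort margins (`nTotal` cases, `nA` with
#' lesion A, `nB` with lesion B, `nAB` with both) and applies a two-sided
#' Fisher exact test.
#'
#' @param nTotal,nA,nB,nAB cohort margins.
#' @return list: `table`, `odds_ratio`, `p`.
#' @export
cooccurrenceFisher <- function(nTotal, nA, nB, nAB) {
  if (nAB > min(nA, nB) || max(nA, nB) > nTotal || nAB < 0)
    stop("inconsistent margins: need nAB <= min(nA, nB) <= nTotal")
  tab <- rbind(A = c(nAB, nA - nAB),
               notA = c(nB - nAB, nTotal - nA - nB + nAB))
  colnames(tab) <- c("B", "notB")
  fisherContingency(tab)
}

#' Exact two-sided binomial hotspot test
#'
#' Two-sided exact binomial test (minimum-likelihood method, as in
#' [stats::binom.test()]) of `k` hotspot cases out of `n` against the
#' background proportion `p0`.
#'
#' @param k,n observed hotspot count and total.
#' @param p0 background hotspot proportion.
#' @return Two-sided p-value.
#' @export
hotspotBinomialTest <- function(k, n, p0) {
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n with n > 0")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0,1)")
  binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}
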