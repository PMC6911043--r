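## Synthetic-data generator.
##
## Emulates the statistical structure of the real inputs: per-nucleotide
## RT-stop counts around 3'SS with condition-specific peak positions (a
## single-nucleotide shift between conditions), flanking secondary peaks,
## a tunable occupied fraction, trinucleotide-dependent binding weights,
## and two-group PSI cohorts whose effect directions couple to the
## acceptor trinucleotide.  Every output is deterministic given
## (config, seed).

.acceptorClass <- function(acceptor) {
  ifelse(acceptor %in% c("CAG", "TAG", "AAG"), acceptor, "other")
}

#' Simulate a reference genome and splice-site annotation
#'
#' Lays out `nGenes` genes, each on its own contig (half on each strand)
#' as alternating exons and introns with `sitesPerGene` 3' splice sites.
#' Acceptor trinucleotides are drawn from `acceptorComposition` and, when
#' sequence is requested, stamped into otherwise uniform-random sequence
#' at junction offsets -3..-1.  A per-gene expression scale (log-normal,
#' shared by both conditions) is part of the reference.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed.
#' @param genome generate contig sequences (set `FALSE` to skip the
#'   sequence build when only coordinates are needed).
#' @return list with elements `genome` ([Biostrings::DNAStringSet] or
#'   NULL), `sites` (GRanges, see [spliceSites()]) and `genes`
#'   (data.frame: `gene_id`, `contig`, `strand`, `expr`).
#' @export
simulateReference <- function(config, seed, genome = TRUE) {
  set.seed(.subSeed(seed, 1L))
  m <- config@sitesPerGene
  nG <- config@nGenes
  il <- config@intronLength; el <- config@exonLength
  pad <- 100L
  contigLen <- el + m * (il + el) + pad
  geneId <- sprintf("gene%05d", seq_len(nG))
  strand <- rep(c("+", "-"), length.out = nG)
  expr <- rlnorm(nG, meanlog = 0, sdlog = config@exprSdLog)

  ## plus-strand junction positions within a contig
  k <- seq_len(m)
  juncPlus <- el + k * il + (k - 1L) * el + 1L
  junction <- unlist(lapply(seq_len(nG), function(g) {
    if (strand[g] == "+") juncPlus else contigLen - juncPlus + 1L
  }), use.names = FALSE)
  siteContig <- rep(geneId, each = m)
  siteStrand <- rep(strand, each = m)
  siteGene <- rep(geneId, each = m)
  siteId <- sprintf("%s_ss%02d", siteGene, rep(k, times = nG))

  cls <- sample(names(config@acceptorComposition),
                nG * m, replace = TRUE, prob = config@acceptorComposition)
  tri <- cls
  if (any(cls == "other")) {
    pool <- setdiff(Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3L),
                    c("CAG", "TAG", "AAG"))
    tri[cls == "other"] <- sample(pool, sum(cls == "other"), replace = TRUE)
  }

  seqs <- NULL
  if (genome) {
    bases <- c("A", "C", "G", "T")
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(nG), function(g) {
      paste(sample(bases, contigLen, replace = TRUE), collapse = "")
    }, ""))
    names(seqs) <- geneId
    ## stamp acceptor trinucleotides at offsets -3..-1
    idx <- seq_along(junction)
    g1 <- offsetToGenomic(junction, siteStrand, -3L)
    g2 <- offsetToGenomic(junction, siteStrand, -1L)
    lo <- pmin(g1, g2)
    stamp <- ifelse(siteStrand == "+", tri,
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAStringSet(tri))))
    for (ctg in unique(siteContig)) {
      j <- idx[siteContig == ctg]
      seqs[[ctg]] <- Biostrings::replaceAt(
        seqs[[ctg]],
        IRanges::IRanges(start = lo[j], width = 3L),
        Biostrings::DNAStringSet(stamp[j]))
    }
  }
  sites <- spliceSites(siteContig, junction, siteStrand, siteId, siteGene,
                       genome = NULL, acceptor = tri)
  if (genome) {
    ## invariant check: stamped sequence must round-trip
    chk <- .siteWindowSeqs(seqs, siteContig[1:min(5, length(junction))],
                           junction[1:min(5, length(junction))],
                           siteStrand[1:min(5, length(junction))], -3L, -1L)
    stopifnot(identical(chk, tri[1:min(5, length(junction))]))
  }
  list(genome = seqs, sites = sites,
       genes = data.frame(gene_id = geneId, contig = geneId,
                          strand = strand, expr = expr,
                          stringsAsFactors = FALSE))
}

#' Simulate an RT-stop track for one condition
#'
#' Per-gene occupancy is `pi_cond` scaled down for low-expression genes
#' (below the `rampQuantile` expression quantile), giving the rising limb
#' of the saturation curve; the per-gene number of occupied sites is fixed
#' at its expectation `round(sitesPerGene * pi_gene)` and the occupied
#' sites are chosen by weighted sampling without replacement with the
#' condition's trinucleotide multipliers, so the marginal per-site
#' occupancy follows the multiplicative, renormalised law.  Occupied
#' sites receive negative-binomial stop totals whose offsets follow the
#' condition's display-coordinate peak profile (plus a per-site uniform
#' background component); nonspecific background stops are spread
#' uniformly over the gene span at `backgroundFraction` of the signal.
#'
#' @param reference output of [simulateReference()].
#' @param config a [SimConfig-class].
#' @param condition condition name (must be in `occupancy(config)`).
#' @param seed integer seed.
#' @param minSupport minimum RT stops per nucleotide for a position to be
#'   emitted (default 4), emulating crosslink-site support filtering of
#'   processed iCLIP tracks.
#' @return list with `track` ([RTStopTrack-class]) and `truth`
#'   (data.frame: `site_id`, `occupied`, `truePeak` display offset).
#' @export
simulateRTStops <- function(reference, config, condition, seed,
                            minSupport = 4L) {
  if (!condition %in% names(config@occupancy))
    stop("unknown condition '", condition, "'")
  set.seed(.subSeed(seed, 2L + match(condition, names(config@occupancy))))
  sites <- reference$sites
  genes <- reference$genes
  m <- config@sitesPerGene
  piCond <- config@occupancy[[condition]]
  mult <- config@triMultipliers[[condition]]
  prof <- config@peakProfiles[[condition]]
  dOff <- config@displayOffset

  e0 <- qlnorm(config@rampQuantile, meanlog = 0, sdlog = config@exprSdLog)
  piGene <- piCond * pmin(1, genes$expr / e0)
  kGene <- pmin(m, as.integer(round(m * piGene)))

  siteGene <- match(sites$gene_id, genes$gene_id)
  w <- mult[.acceptorClass(sites$acceptor)]
  occupied <- logical(length(sites))
  for (g in seq_len(nrow(genes))) {
    if (kGene[g] == 0L) next
    idx <- which(siteGene == g)
    pick <- if (kGene[g] >= length(idx)) idx else
      sample(idx, kGene[g], prob = w[idx])
    occupied[pick] <- TRUE
  }

  ## stop totals for occupied sites
  occIdx <- which(occupied)
  mu <- config@meanStops * genes$expr[siteGene[occIdx]]
  nStops <- if (config@dispersion > 0)
    rnbinom(length(occIdx), mu = mu, size = 1 / config@dispersion)
  else rpois(length(occIdx), mu)

  ## per-stop display offsets from the peak profile
  comp <- names(prof)
  total <- sum(nStops)
  stopSite <- rep(occIdx, nStops)
  pickComp <- sample(comp, total, replace = TRUE, prob = prof)
  disp <- suppressWarnings(as.integer(pickComp))
  bg <- pickComp == "background"
  if (any(bg))
    disp[bg] <- sample(seq.int(-config@backgroundSpan, config@backgroundSpan),
                       sum(bg), replace = TRUE)
  internal <- disp - dOff
  junct <- GenomicRanges::start(sites)[stopSite]
  str <- as.character(GenomicRanges::strand(sites))[stopSite]
  pos <- offsetToGenomic(junct, str, internal)
  ctg <- as.character(GenomicRanges::seqnames(sites))[stopSite]

  ## gene-span nonspecific background
  bf <- config@backgroundFraction
  if (bf > 0) {
    rate <- bf / (1 - bf) * config@meanStops * genes$expr * m * piGene
    nBg <- rpois(nrow(genes), rate)
    if (sum(nBg) > 0) {
      contigLen <- config@exonLength +
        m * (config@intronLength + config@exonLength) + 100L
      bgGene <- rep(seq_len(nrow(genes)), nBg)
      pos <- c(pos, sample.int(contigLen, sum(nBg), replace = TRUE))
      ctg <- c(ctg, genes$contig[bgGene])
      str <- c(str, genes$strand[bgGene])
    }
  }

  dt <- data.table::data.table(ctg = ctg, pos = pos, str = str)
  ## clip stray positions to contig bounds
  contigLen <- config@exonLength +
    m * (config@intronLength + config@exonLength) + 100L
  dt <- dt[dt$pos >= 1L & dt$pos <= contigLen, ]
  agg <- dt[, list(count = .N), by = c("ctg", "pos", "str")]
  agg <- agg[agg$count >= minSupport, ]
  gr <- GenomicRanges::GRanges(
    seqnames = agg$ctg,
    ranges = IRanges::IRanges(start = agg$pos, width = 1L),
    strand = agg$str, count = as.integer(agg$count))
  mainPeak <- as.integer(names(which.max(prof[comp != "background"])))
  list(track = RTStopTrack(sort(gr), condition),
       truth = data.frame(site_id = sites$site_id, occupied = occupied,
                          truePeak = mainPeak, stringsAsFactors = FALSE))
}

#' Simulate a two-group PSI cohort
#'
#' Unaffected events share a Beta-distributed baseline psi across both
#' groups; affected events shift the group-I (mutant) psi by +/- deltaPsi,
#' with the sign coupled to the linked acceptor trinucleotide (CAG ->
#' increased inclusion in mutant, TAG -> decreased) at probability
#' `coupling`, random sign otherwise.  Observed psi values are binomial
#' read-count ratios at Poisson-distributed depth; per-condition
#' inclusion/exclusion counts for the two-condition caller are emitted
#' alongside.
#'
#' @param reference output of [simulateReference()].
#' @param config a [SimConfig-class]; cohort parameters in `config@cohort`.
#' @param seed integer seed.
#' @return list with `psi` (SummarizedExperiment, groups `"mut"`/`"wt"`),
#'   `counts` (per-condition event counts data.frame) and `truth`.
#' @export
simulatePsiCohort <- function(reference, config, seed) {
  set.seed(.subSeed(seed, 11L))
  ch <- config@cohort
  sites <- reference$sites
  nEvents <- ch$nEvents %||% 500L
  typeProbs <- ch$typeProbs %||%
    c(SE = 0.4, RI = 0.15, A3SS = 0.15, A5SS = 0.15, NAGNAG = 0.15)
  pick <- sample(length(sites), min(nEvents, length(sites)))
  nEvents <- length(pick)
  eventId <- sprintf("ev%05d", seq_len(nEvents))
  siteId <- sites$site_id[pick]
  acc <- .acceptorClass(sites$acceptor[pick])
  type <- sample(names(typeProbs), nEvents, TRUE, typeProbs)

  base <- rbeta(nEvents, ch$psiBetaA, ch$psiBetaB)
  affected <- runif(nEvents) < ch$affectedFraction
  coupled <- runif(nEvents) < ch$coupling
  sgn <- ifelse(coupled & acc == "CAG", 1,
         ifelse(coupled & acc == "TAG", -1,
                sample(c(-1, 1), nEvents, TRUE)))
  delta <- ifelse(affected, sgn * ch$deltaPsi, 0)
  psiMut <- pmin(0.98, pmax(0.02, base + delta))
  psiWt <- pmin(0.98, pmax(0.02, base))
  trueDelta <- psiMut - psiWt

  nMut <- ch$nMut; nWt <- ch$nWt
  sampleId <- c(sprintf("mut%02d", seq_len(nMut)),
                sprintf("wt%02d", seq_len(nWt)))
  groups <- c(rep("mut", nMut), rep("wt", nWt))
  truePsi <- cbind(matrix(psiMut, nEvents, nMut), matrix(psiWt, nEvents, nWt))
  depth <- matrix(rpois(nEvents * (nMut + nWt), ch$depth),
                  nEvents, nMut + nWt)
  inc <- matrix(rbinom(length(depth), as.vector(depth), as.vector(truePsi)),
                nEvents, nMut + nWt)
  psi <- ifelse(depth > 0, inc / depth, NA_real_)
  dimnames(psi) <- list(eventId, sampleId)

  ## pooled per-condition counts for the two-condition caller
  nTotMut <- rpois(nEvents, ch$depth); nTotWt <- rpois(nEvents, ch$depth)
  incMut <- rbinom(nEvents, nTotMut, psiMut)
  incWt <- rbinom(nEvents, nTotWt, psiWt)
  counts <- rbind(
    data.frame(event_id = eventId, condition = "wt", inclusion = incWt,
               exclusion = nTotWt - incWt, type = type, site_id = siteId,
               stringsAsFactors = FALSE),
    data.frame(event_id = eventId, condition = "mut", inclusion = incMut,
               exclusion = nTotMut - incMut, type = type, site_id = siteId,
               stringsAsFactors = FALSE))

  list(psi = psiExperiment(psi, groups),
       counts = validateEventCounts(counts),
       truth = data.frame(event_id = eventId, site_id = siteId,
                          acceptor = sites$acceptor[pick], type = type,
                          affected = affected, trueDelta = trueDelta,
                          psiWt = psiWt, psiMut = psiMut,
                          stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-gene CLIP counts and expression for two conditions
#'
#' Log-normal expression; CLIP counts proportional to expression with
#' log-normal noise; a configurable subset of genes is given true binding
#' and/or expression fold changes (independent subsets, so binding and
#' expression changes are uncorrelated by construction).
#'
#' @param reference output of [simulateReference()].
#' @param config a [SimConfig-class]; parameters in `config@quant`.
#' @param seed integer seed.
#' @return list with `quant` (data.frame: `gene_id`, `clip_wt`, `clip_mut`,
#'   `expr_wt`, `expr_mut`) and `truth` (true fold changes).
#' @export
simulateGeneQuant <- function(reference, config, seed) {
  set.seed(.subSeed(seed, 21L))
  q <- config@quant
  genes <- reference$genes
  n <- nrow(genes)
  exprWt <- rlnorm(n, q$exprMeanLog, q$exprSdLog)
  bindFc <- rep(1, n); exprFc <- rep(1, n)
  nAff <- round(q$affectedFraction * n)
  if (nAff > 0) {
    bi <- sample(n, nAff)
    bindFc[bi] <- rep(c(q$trueFc, 1 / q$trueFc), length.out = nAff)
    ei <- sample(n, nAff)
    exprFc[ei] <- rep(c(q$trueFc, 1 / q$trueFc), length.out = nAff)
  }
  noise <- function() 2^rnorm(n, 0, q$noiseSdLog2)
  clipWt <- round(exprWt * 5 * noise())
  clipMut <- round(exprWt * 5 * bindFc * noise())
  exprMut <- exprWt * exprFc * noise()
  list(quant = data.frame(gene_id = genes$gene_id,
                          clip_wt = clipWt, clip_mut = clipMut,
                          expr_wt = exprWt, expr_mut = exprMut,
                          stringsAsFactors = FALSE),
       truth = data.frame(gene_id = genes$gene_id, bindingFc = bindFc,
                          exprFc = exprFc, stringsAsFactors = FALSE))
}
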