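## Hexamer Z-score analysis with a resampling null, trinucleotide
## sliding-window profiles, positional base frequencies and the
## preferential binding score.
##
## Null model: n resamples of M 3'SS drawn uniformly without replacement
## from all annotated sites; hexamer frequencies are counted in the
## +/- flank window around each junction, yielding per-hexamer null mean
## and SD.  Observed frequencies count hexamers whose start lies within
## [RT - 2, RT + 2] of each RT stop assigned to an occupied site, and
## z = (f - mu) / sigma.

.allKmers <- function(k) Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)

## Transcript-oriented sequence windows around stop positions, N-padded at
## contig ends so truncated k-mer windows drop out of the counts.
.stopWindowSeqs <- function(genome, contig, pos, strand, from, to) {
  strand <- as.character(strand)
  len <- setNames(Biostrings::width(genome), names(genome))[contig]
  if (any(is.na(len))) stop("unknown contig: ", contig[is.na(len)][1L])
  g1 <- offsetToGenomic(pos, strand, from)
  g2 <- offsetToGenomic(pos, strand, to)
  lo <- pmin(g1, g2); hi <- pmax(g1, g2)
  clo <- pmax(1L, lo); chi <- pmin(len, hi)
  out <- character(length(pos))
  for (ctg in unique(contig)) {
    idx <- which(contig == ctg & clo <= chi)
    if (length(idx)) {
      v <- Biostrings::extractAt(
        genome[[ctg]], IRanges::IRanges(start = clo[idx], end = chi[idx]))
      neg <- strand[idx] == "-"
      if (any(neg)) v[neg] <- Biostrings::reverseComplement(v[neg])
      out[idx] <- as.character(v)
    }
  }
  padL <- ifelse(strand == "+", clo - lo, hi - chi)
  padR <- ifelse(strand == "+", hi - chi, clo - lo)
  paste0(strrep("N", padL), out, strrep("N", padR))
}

.hexamerFreq <- function(seqs) {
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 6L))
  list(freq = counts / max(1, sum(counts)), nWindows = sum(counts))
}

#' Build the hexamer resampling null
#'
#' For `n` resamples, `M` 3' splice sites are drawn uniformly without
#' replacement from all annotated sites and hexamer frequencies are
#' counted in the transcript-oriented window at junction offsets
#' `[-flank, +flank]`; the per-hexamer empirical mean and SD over
#' resamples define the null.
#'
#' @param sites GRanges splice-site table (all annotated 3'SS).
#' @param genome [Biostrings::DNAStringSet].
#' @param M resample size; conventionally the number of unique occupied
#'   3'SS in the sample being tested.
#' @param n number of resamples (default 50).
#' @param flank half-width of the site window (default 20 nt).
#' @param seed integer seed.
#' @return list with `mu`, `sigma` (named over the 4096 hexamers), and
#'   `M`, `n`, `flank`.
#' @export
buildHexamerNull <- function(sites, genome, M, n = 50L, flank = 20L,
                             seed = 1L) {
  if (M > length(sites))
    stop("M (", M, ") exceeds the number of annotated sites (",
         length(sites), ")")
  set.seed(.subSeed(seed, 31L))
  seqs <- .stopWindowSeqs(genome,
                          as.character(GenomicRanges::seqnames(sites)),
                          GenomicRanges::start(sites),
                          GenomicRanges::strand(sites), -flank, flank)
  freqs <- matrix(0, nrow = n, ncol = 4096L,
                  dimnames = list(NULL, .allKmers(6L)))
  for (r in seq_len(n)) {
    pick <- sample(length(seqs), M)
    freqs[r, ] <- .hexamerFreq(seqs[pick])$freq
  }
  list(mu = colMeans(freqs), sigma = apply(freqs, 2L, sd),
       M = as.integer(M), n = as.integer(n), flank = as.integer(flank))
}

#' Observed hexamer frequencies in RT-stop windows
#'
#' Counts, for every RT stop assigned to an occupied 3'SS, the `window`
#' hexamers sliding past the stop.  With the default `anchor = "contain"`
#' these are the hexamers containing the cross-linked nucleotide, taken --
#' per the usual iCLIP truncation convention -- as the base immediately
#' 5' of the RT stop (start offsets `[RT - window, RT - 1]`,
#' transcript-oriented): the cross-link lies inside the bound motif.
#' `anchor = "center"` instead takes hexamer starts in `[RT - h, RT + h]`
#' with `h = floor(window/2)`.
#'
#' @param track an [RTStopTrack-class].
#' @param occupiedSites GRanges of the occupied 3'SS.
#' @param genome [Biostrings::DNAStringSet].
#' @param window number of sliding hexamer windows per stop (default 5).
#' @param flank stop-to-site assignment half-window (default 20 nt).
#' @param weighted count each stop once (default) or weight by its RT-stop
#'   count.
#' @param anchor `"contain"` (default) or `"center"`, see above.
#' @return list with `freq` (named over 4096 hexamers) and `nWindows`.
#' @export
observedHexamerFrequencies <- function(track, occupiedSites, genome,
                                       window = 5L, flank = 20L,
                                       weighted = FALSE,
                                       anchor = c("contain", "center")) {
  anchor <- match.arg(anchor)
  gr <- stopPositions(track)
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(occupiedSites),
    ranges = IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(occupiedSites) - flank),
      end = GenomicRanges::start(occupiedSites) + flank),
    strand = GenomicRanges::strand(occupiedSites))
  hit <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(gr, win, ignore.strand = FALSE)))
  if (!length(hit)) stop("no RT stops near occupied sites")
  gr <- gr[hit]
  if (anchor == "contain") {
    from <- -as.integer(window); to <- 4L
  } else {
    h <- floor(window / 2)
    from <- -h; to <- h + 5L
  }
  seqs <- .stopWindowSeqs(genome,
                          as.character(GenomicRanges::seqnames(gr)),
                          GenomicRanges::start(gr),
                          GenomicRanges::strand(gr), from, to)
  if (weighted) seqs <- rep(seqs, gr$count)
  .hexamerFreq(seqs)
}

#' Hexamer Z-scores against the resampling null
#'
#' `z = (f - mu) / sigma`; hexamers with `sigma = 0` are reported with
#' `NA` Z-scores rather than infinities.
#'
#' @inheritParams observedHexamerFrequencies
#' @param null output of [buildHexamerNull()] (built with `M` = number of
#'   unique occupied 3'SS in this sample).
#' @return A [HexamerStats-class].
#' @export
hexamerZscores <- function(track, occupiedSites, genome, null,
                           window = 5L, flank = 20L, weighted = FALSE,
                           anchor = c("contain", "center")) {
  obs <- observedHexamerFrequencies(track, occupiedSites, genome,
                                    window = window, flank = flank,
                                    weighted = weighted,
                                    anchor = match.arg(anchor))
  f <- obs$freq[names(null$mu)]
  z <- ifelse(null$sigma > 0, (f - null$mu) / null$sigma, NA_real_)
  new("HexamerStats",
      table = data.frame(hexamer = names(null$mu), mu = as.numeric(null$mu),
                         sigma = as.numeric(null$sigma), f = as.numeric(f),
                         z = as.numeric(z), stringsAsFactors = FALSE),
      sample = condition(track), M = null$M, nResamples = null$n,
      nWindows = obs$nWindows)
}

#' Trinucleotide sliding-window profile around RT stops
#'
#' A window of size 3 slides over `[RT - span, RT + span]` (window start
#' offsets relative to each RT stop); at each offset the frequency of each
#' of the 64 trinucleotides is computed over all stops.  Windows truncated
#' at contig ends are dropped.
#'
#' @param track an [RTStopTrack-class].
#' @param genome [Biostrings::DNAStringSet].
#' @param sites optional GRanges; when given, only stops within `flank` nt
#'   of a site are used.
#' @param span sliding range half-width (default 25).
#' @param flank stop-to-site assignment half-window (default 20 nt).
#' @return Numeric matrix, offsets `-span..span` x 64 trinucleotides; each
#'   row sums to 1 (over non-truncated windows).
#' @export
trinucleotideProfile <- function(track, genome, sites = NULL, span = 25L,
                                 flank = 20L) {
  gr <- stopPositions(track)
  if (!is.null(sites)) {
    win <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(sites),
      ranges = IRanges::IRanges(
        start = pmax(1L, GenomicRanges::start(sites) - flank),
        end = GenomicRanges::start(sites) + flank),
      strand = GenomicRanges::strand(sites))
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr, win, ignore.strand = FALSE)))
    gr <- gr[hit]
  }
  if (!length(gr)) stop("no RT stops to profile")
  seqs <- .stopWindowSeqs(genome,
                          as.character(GenomicRanges::seqnames(gr)),
                          GenomicRanges::start(gr),
                          GenomicRanges::strand(gr), -span, span + 2L)
  tris <- .allKmers(3L)
  offs <- seq.int(-span, span)
  out <- matrix(0, nrow = length(offs), ncol = 64L,
                dimnames = list(as.character(offs), tris))
  for (i in seq_along(offs)) {
    tri <- substr(seqs, i, i + 2L)
    tab <- table(factor(tri, levels = tris))
    if (sum(tab) > 0) out[i, ] <- as.numeric(tab) / sum(tab)
  }
  attr(out, "condition") <- condition(track)
  out
}

#' Preferential binding score between two samples
#'
#' `score(h) = log2((f_mut + eps) / (f_wt + eps))`, ranked descending so
#' the top of the table is most mutant-preferred.
#'
#' @param statsMut,statsWt [HexamerStats-class] for the two samples.
#' @param pseudocount `eps`; default `1 / (4 * 4096 * mean(nWindows))`.
#' @return data.frame (`hexamer`, `f_mut`, `f_wt`, `score`) sorted by
#'   descending score.
#' @export
preferentialBindingScore <- function(statsMut, statsWt, pseudocount = NULL) {
  fm <- setNames(hexamerTable(statsMut)$f, hexamerTable(statsMut)$hexamer)
  fw <- setNames(hexamerTable(statsWt)$f, hexamerTable(statsWt)$hexamer)
  fw <- fw[names(fm)]
  if (is.null(pseudocount))
    pseudocount <- 1 / (4 * 4096 * mean(c(statsMut@nWindows,
                                          statsWt@nWindows)))
  score <- log2((fm + pseudocount) / (fw + pseudocount))
  out <- data.frame(hexamer = names(fm), f_mut = as.numeric(fm),
                    f_wt = as.numeric(fw), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out[order(-out$score), ]
}

#' Selectively enriched hexamers
#'
#' Hexamers in the top `topFrac` of `|z_mut - z_wt|` (NA Z-scores are
#' dropped).
#'
#' @inheritParams preferentialBindingScore
#' @param topFrac fraction reported (default 0.035).
#' @return Character vector of hexamers.
#' @export
enrichedHexamers <- function(statsMut, statsWt, topFrac = 0.035) {
  zm <- setNames(hexamerTable(statsMut)$z, hexamerTable(statsMut)$hexamer)
  zw <- setNames(hexamerTable(statsWt)$z, hexamerTable(statsWt)$hexamer)
  d <- abs(zm - zw[names(zm)])
  d <- d[!is.na(d)]
  names(sort(d, decreasing = TRUE))[seq_len(ceiling(topFrac * length(d)))]
}

#' Stop-weighted positional base frequencies around 3' splice sites
#'
#' For each junction offset in `[-window, +window]` the frequency of each
#' base across sites, weighting every site by its total RT-stop count in
#' the occupancy window.
#'
#' @param track an [RTStopTrack-class].
#' @param sites GRanges splice-site table.
#' @param genome [Biostrings::DNAStringSet].
#' @param window junction-offset half-width (default 10).
#' @param flank stop-counting half-window for the site weights (default
#'   20 nt).
#' @return Numeric matrix, offsets x A/C/G/T; rows sum to 1.
#' @export
positionalBaseFrequency <- function(track, sites, genome, window = 10L,
                                    flank = 20L) {
  prof <- siteProfiles(track, sites, flank)
  w <- rowSums(prof)
  keep <- w > 0
  if (!any(keep)) stop("no sites with RT stops")
  sites <- sites[keep]
  w <- w[keep]
  seqs <- .stopWindowSeqs(genome,
                          as.character(GenomicRanges::seqnames(sites)),
                          GenomicRanges::start(sites),
                          GenomicRanges::strand(sites), -window, window)
  offs <- seq.int(-window, window)
  out <- matrix(0, nrow = length(offs), ncol = 4L,
                dimnames = list(as.character(offs), c("A", "C", "G", "T")))
  for (i in seq_along(offs)) {
    b <- substr(seqs, i, i)
    ok <- b %in% c("A", "C", "G", "T")
    tot <- tapply(w[ok], factor(b[ok], levels = c("A", "C", "G", "T")), sum)
    tot[is.na(tot)] <- 0
    if (sum(tot) > 0) out[i, ] <- tot / sum(tot)
  }
  out
}
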