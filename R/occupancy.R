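## 3' splice-site occupancy saturation analysis and metagene profile.
##
## A 3'SS is "occupied" when any binding event (an RT-stop position with
## count >= 1) lies within a closed +/- `windowNt` window of the junction.
## Per-gene CLIP binding density is the number of unique RT-stop positions
## assigned to the gene divided by its number of 3'SS; after sorting genes
## by density a rolling quantile of per-gene occupied fractions traces the
## saturation curve, whose plateau is summarised as the mean rolling value
## over the top-decile-density windows.

#' Call occupied 3' splice sites
#'
#' @param track an [RTStopTrack-class].
#' @param sites GRanges splice-site table ([spliceSites()]).
#' @param windowNt half-width of the closed occupancy window (default 20).
#' @return Named logical vector (site_id -> occupied).
#' @export
callOccupiedSites <- function(track, sites, windowNt = 20L) {
  if (windowNt < 0) stop("windowNt must be >= 0")
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(sites),
    ranges = IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(sites) - as.integer(windowNt)),
      end = GenomicRanges::start(sites) + as.integer(windowNt)),
    strand = GenomicRanges::strand(sites))
  hit <- GenomicRanges::countOverlaps(win, stopPositions(track),
                                      ignore.strand = FALSE) > 0L
  setNames(hit, sites$site_id)
}

#' Per-gene 3'SS CLIP binding density
#'
#' Density = (unique RT-stop positions assigned to the gene) / (number of
#' 3'SS in the gene).  A stop is assigned to the gene of its nearest 3'SS
#' provided it lies within `windowAssign` nt of it (`Inf` assigns every
#' stop on a gene's contig/strand to its nearest site's gene).
#'
#' @inheritParams callOccupiedSites
#' @param windowAssign stop-to-gene assignment half-window (default 20 nt).
#' @return data.frame: `gene_id`, `n_sites`, `n_stops`, `density`.
#' @export
geneClipDensity <- function(track, sites, windowAssign = 20L) {
  gr <- stopPositions(track)
  geneOf <- sites$gene_id
  nSites <- table(geneOf)
  assigned <- integer(0)
  if (length(gr)) {
    if (is.infinite(windowAssign)) {
      d2n <- GenomicRanges::distanceToNearest(gr, sites,
                                              ignore.strand = FALSE)
      assigned <- S4Vectors::subjectHits(d2n)
    } else {
      win <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(sites),
        ranges = IRanges::IRanges(
          start = pmax(1L, GenomicRanges::start(sites) -
                         as.integer(windowAssign)),
          end = GenomicRanges::start(sites) + as.integer(windowAssign)),
        strand = GenomicRanges::strand(sites))
      ov <- GenomicRanges::findOverlaps(gr, win, ignore.strand = FALSE)
      if (length(ov)) {
        dt <- data.table::data.table(
          stop = S4Vectors::queryHits(ov),
          site = S4Vectors::subjectHits(ov),
          dist = abs(GenomicRanges::start(gr)[S4Vectors::queryHits(ov)] -
                       GenomicRanges::start(sites)[S4Vectors::subjectHits(ov)]))
        data.table::setorderv(dt, c("stop", "dist", "site"))
        dt <- dt[!duplicated(dt$stop), ]
        assigned <- dt$site
      }
    }
  }
  nStops <- table(factor(geneOf[assigned], levels = names(nSites)))
  data.frame(gene_id = names(nSites),
             n_sites = as.integer(nSites),
             n_stops = as.integer(nStops),
             density = as.numeric(nStops) / as.integer(nSites),
             stringsAsFactors = FALSE)
}

#' Rolling-quantile occupancy saturation curve
#'
#' Genes are sorted by ascending density; a rolling `q`-quantile of the
#' per-gene occupied fraction over windows of `window` genes forms the
#' saturation series; the plateau estimate is the mean of the rolling
#' series over the top-decile-density windows.
#'
#' @param densities per-gene densities (named by gene, optional).
#' @param occupiedFractions per-gene occupied 3'SS fractions, parallel to
#'   `densities`.
#' @param window rolling window size in genes (default 40).
#' @param q rolling quantile (default 0.75).
#' @return An [OccupancyCurve-class].
#' @export
saturationCurve <- function(densities, occupiedFractions, window = 40L,
                            q = 0.75) {
  n <- length(densities)
  if (length(occupiedFractions) != n)
    stop("densities and occupiedFractions must be parallel")
  if (n < window) stop("fewer genes (", n, ") than window (", window, ")")
  ord <- order(densities)
  d <- densities[ord]
  f <- occupiedFractions[ord]
  ids <- if (!is.null(names(densities))) names(densities)[ord] else
    as.character(seq_len(n))
  roll <- zoo::rollapply(f, width = window, FUN = quantile, probs = q,
                         names = FALSE, align = "left")
  rollD <- zoo::rollapply(d, width = window, FUN = mean, align = "left")
  nTop <- max(1L, ceiling(0.1 * length(roll)))
  plate <- mean(utils::tail(roll, nTop))
  new("OccupancyCurve", geneId = ids, density = as.numeric(d),
      occupiedFraction = as.numeric(f), rolling = as.numeric(roll),
      rollingDensity = as.numeric(rollD), window = as.integer(window),
      q = q, plateau = plate)
}

#' Run the full occupancy saturation analysis for one condition
#'
#' Convenience wrapper: calls occupied sites, computes per-gene densities
#' and occupied fractions, and fits the saturation curve.
#'
#' @inheritParams callOccupiedSites
#' @inheritParams saturationCurve
#' @param windowAssign stop-to-gene assignment half-window.
#' @return An [OccupancyCurve-class].
#' @export
occupancyAnalysis <- function(track, sites, windowNt = 20L,
                              windowAssign = 20L, window = 40L, q = 0.75) {
  occ <- callOccupiedSites(track, sites, windowNt)
  dens <- geneClipDensity(track, sites, windowAssign)
  fr <- tapply(occ[sites$site_id], sites$gene_id, mean)
  fr <- fr[dens$gene_id]
  saturationCurve(setNames(dens$density, dens$gene_id), as.numeric(fr),
                  window = window, q = q)
}

#' Metagene cross-link profile around 3' splice sites
#'
#' Per site, stop counts over junction offsets `[-L, +L]` are normalised
#' to sum to 1 (sites with no stops in the window are skipped); site
#' profiles are averaged and the average is scaled to a maximum of 1.
#'
#' @param track an [RTStopTrack-class].
#' @param sites GRanges splice-site table.
#' @param L profile half-width (default 50).
#' @param displayOffset shift used to label the output offsets (default
#'   -3; see [toDisplayOffset()]).
#' @return Named numeric vector over display offsets.
#' @export
metageneProfile <- function(track, sites, L = 50L, displayOffset = -3L) {
  prof <- siteProfiles(track, sites, L)
  tot <- rowSums(prof)
  keep <- tot > 0
  if (!any(keep)) stop("no covered sites")
  frac <- prof[keep, , drop = FALSE] / tot[keep]
  avg <- colMeans(frac)
  avg <- avg / max(avg)
  names(avg) <- as.character(toDisplayOffset(seq.int(-L, L), displayOffset))
  avg
}
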