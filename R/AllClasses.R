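#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats median quantile rbeta rbinom rlnorm rnbinom rnorm rpois
#'   runif sd setNames complete.cases binom.test chisq.test fisher.test
#'   pnorm qlnorm t.test lm
#' @importFrom utils read.table write.table head packageVersion
#' @importFrom data.table data.table setorderv .N
NULL

.datatable.aware <- TRUE

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Strand-aware per-position RT-stop track
#'
#' Holds the cross-link evidence for one condition: unique
#' reverse-transcription stop counts per (contig, strand, position).
#' Positions are width-1 [GenomicRanges::GRanges] with an integer `count`
#' metadata column (all counts >= 1).
#'
#' @slot stops [GenomicRanges::GRanges] of width-1 positions with a `count`
#'   metadata column.
#' @slot condition single condition label, e.g. `"wt"` or `"mut"`.
#' @export
setClass("RTStopTrack",
  representation(stops = "GRanges", condition = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@condition) != 1L)
      msg <- c(msg, "condition must be a single string")
    if (length(object@stops)) {
      if (is.null(object@stops$count))
        msg <- c(msg, "stops must carry a 'count' metadata column")
      else if (any(object@stops$count < 1L))
        msg <- c(msg, "all RT-stop counts must be >= 1")
      if (any(GenomicRanges::width(object@stops) != 1L))
        msg <- c(msg, "all stop positions must have width 1")
      if (any(as.character(GenomicRanges::strand(object@stops)) == "*"))
        msg <- c(msg, "stops must be stranded")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn RTStopTrack Constructor.
#' @param stops GRanges of stop positions with `count`.
#' @param condition condition label.
#' @export
RTStopTrack <- function(stops, condition) {
  new("RTStopTrack", stops = stops, condition = condition)
}

#' @describeIn RTStopTrack Condition label.
#' @param object,x an `RTStopTrack`.
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname RTStopTrack
#' @export
setMethod("condition", "RTStopTrack", function(object) object@condition)

#' @describeIn RTStopTrack Stop positions as GRanges.
#' @export
setGeneric("stopPositions", function(object) standardGeneric("stopPositions"))

#' @rdname RTStopTrack
#' @export
setMethod("stopPositions", "RTStopTrack", function(object) object@stops)

setMethod("show", "RTStopTrack", function(object) {
  cat("RTStopTrack '", object@condition, "': ",
      length(object@stops), " positions, ",
      sum(object@stops$count), " RT stops\n", sep = "")
})

#' 3' splice-site occupancy saturation curve
#'
#' Result of the saturation analysis: genes sorted by 3'SS CLIP binding
#' density, a rolling quantile of per-gene occupied fractions, and a
#' plateau estimate (mean rolling value over the top-decile-density
#' windows).
#'
#' @slot geneId gene identifiers, sorted by ascending density.
#' @slot density per-gene stops-per-3'SS density (sorted ascending).
#' @slot occupiedFraction per-gene fraction of occupied 3'SS, same order.
#' @slot rolling rolling quantile series (length `nGenes - window + 1`).
#' @slot rollingDensity rolling mean density per window (x-axis values).
#' @slot window,q rolling window size (genes) and quantile.
#' @slot plateau plateau occupancy estimate in [0,1].
#' @export
setClass("OccupancyCurve",
  representation(geneId = "character", density = "numeric",
                 occupiedFraction = "numeric", rolling = "numeric",
                 rollingDensity = "numeric", window = "integer",
                 q = "numeric", plateau = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@density)
    if (length(object@occupiedFraction) != n)
      msg <- c(msg, "density and occupiedFraction lengths differ")
    if (length(object@rolling) != n - object@window + 1L)
      msg <- c(msg, "rolling series length must be nGenes - window + 1")
    if (any(object@density < 0)) msg <- c(msg, "densities must be >= 0")
    if (object@plateau < 0 || object@plateau > 1)
      msg <- c(msg, "plateau must lie in [0,1]")
    if (is.unsorted(object@density)) msg <- c(msg, "genes must be density-sorted")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn OccupancyCurve Plateau occupancy estimate.
#' @param object an `OccupancyCurve`.
#' @export
setGeneric("plateau", function(object) standardGeneric("plateau"))

#' @rdname OccupancyCurve
#' @export
setMethod("plateau", "OccupancyCurve", function(object) object@plateau)

#' @describeIn OccupancyCurve Rolling quantile series.
#' @export
setGeneric("rollingSeries", function(object) standardGeneric("rollingSeries"))

#' @rdname OccupancyCurve
#' @export
setMethod("rollingSeries", "OccupancyCurve", function(object) object@rolling)

setMethod("show", "OccupancyCurve", function(object) {
  cat("OccupancyCurve: ", length(object@density), " genes, window ",
      object@window, ", q ", object@q,
      sprintf(", plateau %.3f\n", object@plateau), sep = "")
})

#' Per-hexamer resampling-null statistics
#'
#' One row per hexamer (4^6 = 4096 rows): resampled null mean and SD of
#' hexamer frequency, observed sample frequency, and the Z-score
#' z = (f - mu) / sigma.  Hexamers with sigma = 0 carry `NA` Z-scores.
#'
#' @slot table data.frame with columns `hexamer`, `mu`, `sigma`, `f`, `z`.
#' @slot sample sample label.
#' @slot M number of unique occupied 3'SS defining the null sample size.
#' @slot nResamples number of null resamples.
#' @slot nWindows number of observed hexamer windows counted.
#' @export
setClass("HexamerStats",
  representation(table = "data.frame", sample = "character",
                 M = "integer", nResamples = "integer",
                 nWindows = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@table) != 4096L)
      msg <- c(msg, "table must have exactly 4096 hexamer rows")
    need <- c("hexamer", "mu", "sigma", "f", "z")
    if (!all(need %in% names(object@table)))
      msg <- c(msg, "table must have columns hexamer, mu, sigma, f, z")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn HexamerStats The per-hexamer statistics table.
#' @param object a `HexamerStats`.
#' @export
setGeneric("hexamerTable", function(object) standardGeneric("hexamerTable"))

#' @rdname HexamerStats
#' @export
setMethod("hexamerTable", "HexamerStats", function(object) object@table)

setMethod("show", "HexamerStats", function(object) {
  z <- object@table$z
  cat("HexamerStats '", object@sample, "': M=", object@M,
      ", n=", object@nResamples, " resamples; ",
      sum(!is.na(z)), "/4096 hexamers with finite z\n", sep = "")
})
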