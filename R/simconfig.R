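#' Synthetic-data generator configuration
#'
#' Bundles every tunable of the synthetic iCLIP / splicing cohort
#' generator.  Defaults instantiate the study conditions the analyses are
#' designed around: wild-type 3'SS occupancy 0.86 vs mutant 0.70, a
#' single-nucleotide shift of the main cross-link peak (display -5 for
#' wild-type, -4 for mutant) with smaller flanking peaks at display -12
#' and +1, and a mutant binding preference for CAG over TAG acceptors
#' (multipliers 2.0 / 0.5).
#'
#' Peak profiles map *display-coordinate* offsets to weights plus a
#' `background` component spread uniformly over +/- `backgroundSpan`
#' display offsets around the junction.  Occupancy probability is the
#' condition's pi multiplied by the site's trinucleotide multiplier and
#' renormalised so that the marginal occupied fraction equals pi.
#'
#' @slot nGenes,sitesPerGene number of genes and 3'SS per gene.
#' @slot intronLength,exonLength intron and exon sizes (nt).
#' @slot acceptorComposition probabilities over CAG/TAG/AAG/other.
#' @slot occupancy named per-condition occupied fraction pi (wt, mut).
#' @slot peakProfiles per-condition named weights over display offsets,
#'   plus a `background` weight.
#' @slot triMultipliers per-condition trinucleotide binding multipliers.
#' @slot meanStops mean RT stops per occupied site (before expression
#'   scaling).
#' @slot dispersion negative-binomial dispersion alpha (var = mu + alpha mu^2).
#' @slot backgroundFraction fraction of stops that are nonspecific
#'   background spread over the gene span.
#' @slot backgroundSpan half-width (display offsets) of the per-site
#'   background component of the peak profile.
#' @slot exprSdLog log-sd of per-gene expression scaling.
#' @slot rampQuantile expression quantile below which per-gene occupancy is
#'   ramped down (sub-saturation genes).
#' @slot cohort list: `nMut`, `nWt`, `psiBetaA`, `psiBetaB`, `deltaPsi`,
#'   `affectedFraction`, `depth`, `coupling`.
#' @slot quant list: `exprMeanLog`, `exprSdLog`, `noiseSdLog2`,
#'   `affectedFraction`, `trueFc`.
#' @slot displayOffset display-coordinate shift (see [toDisplayOffset()]).
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer", sitesPerGene = "integer",
    intronLength = "integer", exonLength = "integer",
    acceptorComposition = "numeric", occupancy = "numeric",
    peakProfiles = "list", triMultipliers = "list",
    meanStops = "numeric", dispersion = "numeric",
    backgroundFraction = "numeric", backgroundSpan = "integer",
    exprSdLog = "numeric", rampQuantile = "numeric",
    cohort = "list", quant = "list", displayOffset = "integer"
  ),
  validity = function(object) {
    msg <- NULL
    if (abs(sum(object@acceptorComposition) - 1) > 1e-8)
      msg <- c(msg, "acceptorComposition must sum to 1")
    if (!all(c("CAG", "TAG", "AAG", "other") %in%
             names(object@acceptorComposition)))
      msg <- c(msg, "acceptorComposition needs CAG, TAG, AAG, other")
    if (any(object@occupancy < 0 | object@occupancy > 1))
      msg <- c(msg, "occupancy values must lie in [0,1]")
    if (any(c(object@nGenes, object@sitesPerGene, object@intronLength,
              object@exonLength) <= 0L))
      msg <- c(msg, "all counts and lengths must be positive")
    for (cond in names(object@peakProfiles)) {
      w <- object@peakProfiles[[cond]]
      if (abs(sum(w) - 1) > 1e-8)
        msg <- c(msg, paste0("peak profile '", cond, "' must sum to 1"))
      if (!"background" %in% names(w))
        msg <- c(msg, paste0("peak profile '", cond, "' needs a background weight"))
    }
    if (!all(names(object@occupancy) %in% names(object@peakProfiles)))
      msg <- c(msg, "every occupancy condition needs a peak profile")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a generator configuration
#'
#' @param nGenes,sitesPerGene,intronLength,exonLength see [SimConfig-class].
#' @param acceptorComposition named probabilities over CAG/TAG/AAG/other.
#' @param occupancy named per-condition occupied fractions.
#' @param peakProfiles named list (per condition) of display-offset weights
#'   including a `background` entry.
#' @param triMultipliers named list (per condition) of multipliers for
#'   CAG/TAG/AAG/other.
#' @param meanStops,dispersion,backgroundFraction,backgroundSpan,exprSdLog,rampQuantile
#'   see [SimConfig-class].
#' @param cohort,quant parameter lists, see [SimConfig-class].
#' @param displayOffset display-coordinate shift.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 50)
#' cfg
#' @export
simConfig <- function(nGenes = 2000L, sitesPerGene = 20L,
                      intronLength = 1500L, exonLength = 150L,
                      acceptorComposition = c(CAG = 0.55, TAG = 0.30,
                                              AAG = 0.10, other = 0.05),
                      occupancy = c(wt = 0.86, mut = 0.70),
                      peakProfiles = list(
                        wt  = c("-5" = 0.6, "-12" = 0.2, "1" = 0.1,
                                background = 0.1),
                        mut = c("-4" = 0.7, "-12" = 0.125, "1" = 0.075,
                                background = 0.1)),
                      triMultipliers = list(
                        wt  = c(CAG = 1, TAG = 1, AAG = 1, other = 1),
                        mut = c(CAG = 2, TAG = 0.5, AAG = 1, other = 1)),
                      meanStops = 40, dispersion = 0.3,
                      backgroundFraction = 0.05, backgroundSpan = 50L,
                      exprSdLog = 0.75, rampQuantile = 0.3,
                      cohort = list(nMut = 20L, nWt = 20L, psiBetaA = 2,
                                    psiBetaB = 2, deltaPsi = 0.3,
                                    affectedFraction = 0.2, depth = 100L,
                                    coupling = 0.8),
                      quant = list(exprMeanLog = 3, exprSdLog = 1,
                                   noiseSdLog2 = 0.15,
                                   affectedFraction = 0.1, trueFc = 2),
                      displayOffset = -3L) {
  new("SimConfig",
      nGenes = as.integer(nGenes), sitesPerGene = as.integer(sitesPerGene),
      intronLength = as.integer(intronLength),
      exonLength = as.integer(exonLength),
      acceptorComposition = acceptorComposition, occupancy = occupancy,
      peakProfiles = peakProfiles, triMultipliers = triMultipliers,
      meanStops = meanStops, dispersion = dispersion,
      backgroundFraction = backgroundFraction,
      backgroundSpan = as.integer(backgroundSpan),
      exprSdLog = exprSdLog, rampQuantile = rampQuantile,
      cohort = cohort, quant = quant,
      displayOffset = as.integer(displayOffset))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nGenes, " genes x ", object@sitesPerGene,
      " 3'SS; occupancy ",
      paste(sprintf("%s=%.2f", names(object@occupancy), object@occupancy),
            collapse = ", "), "\n", sep = "")
})
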