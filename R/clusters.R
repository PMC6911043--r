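## Deterministic C1-C10 binding clusters and cluster-switch detection.
##
## Each 3'SS profile is converted to a fraction vector over display
## offsets +/- span; sites with total stops <= minTotal are excluded;
## the global argmax (ties broken toward the most intronic, i.e. most
## negative, offset) assigns C1..C9 when it falls at display -6..+2 with
## fraction >= minFrac, and C10 otherwise.

#' Fraction vector of a binding profile
#'
#' @param profile named integer/numeric count vector over display offsets
#'   (names are display-coordinate offsets).
#' @param span half-width over which fractions are computed (default 25).
#' @return Named fractions over display offsets `-span..span`, summing
#'   to 1.
#' @export
fractionVector <- function(profile, span = 25L) {
  offs <- as.character(seq.int(-span, span))
  v <- setNames(numeric(length(offs)), offs)
  common <- intersect(names(profile), offs)
  v[common] <- profile[common]
  tot <- sum(v)
  if (tot <= 0) stop("no binding in profile")
  v / tot
}

#' Assign one site to a binding cluster
#'
#' @param fractions named fraction vector over display offsets (see
#'   [fractionVector()]).
#' @param totalStops total RT stops in the site's window.
#' @param window display-offset window mapped to C1..C9 (default -6..+2).
#' @param minFrac minimum argmax fraction for a major cluster (default
#'   0.10).
#' @param minTotal sites with `totalStops <= minTotal` are excluded
#'   (default 10; ">10 stops" is read strictly).
#' @return list: `cluster` (`"C1"`..`"C10"` or `"excluded"`),
#'   `max_fraction`, `argmax` (display offset), `total_stops`.
#' @export
assignCluster <- function(fractions, totalStops, window = c(-6L, 2L),
                          minFrac = 0.10, minTotal = 10L) {
  if (totalStops <= minTotal)
    return(list(cluster = "excluded", max_fraction = NA_real_,
                argmax = NA_integer_, total_stops = totalStops))
  offs <- as.integer(names(fractions))
  ord <- order(offs)
  offs <- offs[ord]; fr <- fractions[ord]
  amax <- offs[which.max(fr)]   # ties -> most negative offset
  mfrac <- max(fr)
  cl <- if (amax >= window[1L] && amax <= window[2L] && mfrac >= minFrac)
    paste0("C", amax - window[1L] + 1L) else "C10"
  list(cluster = cl, max_fraction = mfrac, argmax = amax,
       total_stops = totalStops)
}

#' Cluster assignments for all sites of one condition
#'
#' @param track an [RTStopTrack-class].
#' @param sites GRanges splice-site table.
#' @param span fraction-vector half-width in display offsets (default 25).
#' @param minFrac,minTotal,window see [assignCluster()].
#' @param displayOffset display-coordinate shift (default -3).
#' @return data.frame: `site_id`, `condition`, `cluster`, `max_fraction`,
#'   `argmax`, `total_stops`.
#' @export
clusterAssignments <- function(track, sites, span = 25L, minFrac = 0.10,
                               minTotal = 10L, window = c(-6L, 2L),
                               displayOffset = -3L) {
  ## internal offsets needed to cover display -span..span
  Lneed <- span + abs(displayOffset)
  prof <- siteProfiles(track, sites, Lneed)
  internalOffs <- as.integer(colnames(prof))
  dispOffs <- toDisplayOffset(internalOffs, displayOffset)
  keep <- dispOffs >= -span & dispOffs <= span
  counts <- prof[, keep, drop = FALSE]
  colnames(counts) <- as.character(dispOffs[keep])
  res <- lapply(seq_len(nrow(counts)), function(i) {
    tot <- sum(counts[i, ])
    if (tot <= minTotal)
      return(list(cluster = "excluded", max_fraction = NA_real_,
                  argmax = NA_integer_, total_stops = tot))
    assignCluster(fractionVector(counts[i, ], span), tot,
                  window = window, minFrac = minFrac, minTotal = minTotal)
  })
  data.frame(site_id = rownames(counts),
             condition = condition(track),
             cluster = vapply(res, `[[`, "", "cluster"),
             max_fraction = vapply(res, function(x) as.numeric(x$max_fraction), 0),
             argmax = vapply(res, function(x) as.integer(x$argmax), 0L),
             total_stops = vapply(res, function(x) as.numeric(x$total_stops), 0),
             stringsAsFactors = FALSE)
}

#' Detect wild-type to mutant cluster switches
#'
#' A switch is a site assigned to two *different* major clusters (C1..C9)
#' in the two conditions; with `majorsOnly` (default) sites that are C10
#' or excluded in either condition are dropped from the table.
#'
#' @param assignmentsWt,assignmentsMut outputs of [clusterAssignments()].
#' @param majorsOnly restrict to sites major in both conditions.
#' @return data.frame: `site_id`, `cluster_wt`, `cluster_mut`, `switch`.
#' @export
detectSwitches <- function(assignmentsWt, assignmentsMut,
                           majorsOnly = TRUE) {
  m <- merge(assignmentsWt[, c("site_id", "cluster")],
             assignmentsMut[, c("site_id", "cluster")],
             by = "site_id", suffixes = c("_wt", "_mut"))
  majors <- paste0("C", 1:9)
  if (majorsOnly)
    m <- m[m$cluster_wt %in% majors & m$cluster_mut %in% majors, ,
           drop = FALSE]
  m$switch <- m$cluster_wt %in% majors & m$cluster_mut %in% majors &
    m$cluster_wt != m$cluster_mut
  m
}

#' Cluster composition per condition
#'
#' @param assignments one or more [clusterAssignments()] outputs
#'   (rbind-ed).
#' @return Contingency table cluster x condition, clusters ordered
#'   C1..C10, excluded.
#' @export
clusterComposition <- function(assignments) {
  lev <- c(paste0("C", 1:10), "excluded")
  table(cluster = factor(assignments$cluster, levels = lev),
        condition = assignments$condition)
}

#' Display position of the most populated major cluster
#'
#' @param assignments output of [clusterAssignments()].
#' @param window the display window mapped to C1..C9.
#' @return Display-coordinate offset of the modal major cluster.
#' @export
modalMajorPosition <- function(assignments, window = c(-6L, 2L)) {
  majors <- assignments$cluster[assignments$cluster %in% paste0("C", 1:9)]
  if (!length(majors)) stop("no major-cluster assignments")
  k <- as.integer(sub("^C", "", names(which.max(table(majors)))))
  window[1L] + k - 1L
}
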