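## End-to-end driver and the thin command-line dispatcher.
##
## The package functions are the primary interface; `cliMain()` backs the
## inst/scripts/spliceclip.R wrapper with file-based subcommands, and
## `runDemo()` produces a fully scripted synthetic demonstration of every
## analysis stage.

.provHeader <- function(what, seed, params = list()) {
  ver <- tryCatch(as.character(packageVersion("spliceclip")),
                  error = function(e) "dev")
  ph <- paste(names(params), unlist(params), sep = "=", collapse = "; ")
  c(paste0("# spliceclip v", ver, "; ", what),
    paste0("# seed=", seed, if (nzchar(ph)) paste0("; ", ph) else ""))
}

.writeTsv <- function(df, path, what, seed, params = list()) {
  con <- file(path, "w")
  writeLines(.provHeader(what, seed, params), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  close(con)
  invisible(path)
}

#' Run the scripted synthetic end-to-end demonstration
#'
#' Simulates a reference, wild-type and mutant RT-stop tracks, a PSI
#' cohort and gene quantifications, then runs every analysis stage and
#' writes TSV outputs (occupancy curves and plateaus, metagene profiles,
#' cluster assignments and switches, hexamer statistics and preferential
#' binding scores, trinucleotide profiles, splicing calls and the
#' co-association tests) into `outDir`.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving every stage.
#' @param config a [SimConfig-class]; the default uses a reduced problem
#'   size for a quick demonstration.
#' @return Invisibly, a named list of the key results.
#' @export
runDemo <- function(outDir, seed = 1L,
                    config = simConfig(nGenes = 300L, sitesPerGene = 10L,
                                       intronLength = 500L)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulateReference(config, seed, genome = TRUE)
  wt <- simulateRTStops(ref, config, "wt", seed)
  mut <- simulateRTStops(ref, config, "mut", seed)

  ## occupancy saturation (Fig. 3a analogue)
  curves <- lapply(list(wt = wt$track, mut = mut$track), function(tr) {
    occupancyAnalysis(tr, ref$sites)
  })
  for (cond in names(curves)) {
    cv <- curves[[cond]]
    .writeTsv(data.frame(density = cv@rollingDensity,
                         occupancy = cv@rolling),
              file.path(outDir, paste0("occupancy_", cond, ".tsv")),
              paste0("occupancy saturation curve (", cond, ")"), seed,
              list(plateau = sprintf("%.4f", plateau(cv))))
  }

  ## metagene (Fig. 3b analogue)
  mg <- data.frame(
    offset = as.integer(names(metageneProfile(wt$track, ref$sites))),
    wt = as.numeric(metageneProfile(wt$track, ref$sites)),
    mut = as.numeric(metageneProfile(mut$track, ref$sites)))
  .writeTsv(mg, file.path(outDir, "metagene.tsv"),
            "metagene RT-stop profile", seed)

  ## clusters (Fig. 3c analogue)
  aWt <- clusterAssignments(wt$track, ref$sites)
  aMut <- clusterAssignments(mut$track, ref$sites)
  sw <- detectSwitches(aWt, aMut)
  .writeTsv(rbind(aWt, aMut), file.path(outDir, "clusters.tsv"),
            "C1-C10 cluster assignments", seed)
  .writeTsv(sw, file.path(outDir, "cluster_switches.tsv"),
            "major-cluster switches", seed)

  ## motifs (Fig. 3d-f analogues)
  occWt <- callOccupiedSites(wt$track, ref$sites)
  occMut <- callOccupiedSites(mut$track, ref$sites)
  nullWt <- buildHexamerNull(ref$sites, ref$genome, M = sum(occWt),
                             seed = seed)
  nullMut <- buildHexamerNull(ref$sites, ref$genome, M = sum(occMut),
                              seed = seed + 1L)
  hxWt <- hexamerZscores(wt$track, ref$sites[occWt], ref$genome, nullWt)
  hxMut <- hexamerZscores(mut$track, ref$sites[occMut], ref$genome,
                          nullMut)
  .writeTsv(rbind(cbind(sample = "wt", hexamerTable(hxWt)),
                  cbind(sample = "mut", hexamerTable(hxMut))),
            file.path(outDir, "hexamer_stats.tsv"),
            "hexamer Z-scores vs resampling null", seed)
  pref <- preferentialBindingScore(hxMut, hxWt)
  .writeTsv(head(pref, 50L), file.path(outDir, "preferential_binding.tsv"),
            "preferential binding score (top 50)", seed)
  triWt <- trinucleotideProfile(wt$track, ref$genome, ref$sites)
  triMut <- trinucleotideProfile(mut$track, ref$genome, ref$sites)
  .writeTsv(data.frame(offset = rownames(triMut),
                       CAG_wt = triWt[, "CAG"], TAG_wt = triWt[, "TAG"],
                       CAG_mut = triMut[, "CAG"], TAG_mut = triMut[, "TAG"]),
            file.path(outDir, "trinucleotide_profile.tsv"),
            "CAG/TAG sliding-window frequencies", seed)

  ## splicing (Fig. 4d-i analogues)
  cohort <- simulatePsiCohort(ref, config, seed)
  calls <- callDifferentialEvents(cohort$counts)
  .writeTsv(calls, file.path(outDir, "splicing_calls.tsv"),
            "two-condition differential splicing calls", seed)
  cc <- cohortCall(cohort$psi)
  .writeTsv(cc, file.path(outDir, "cohort_calls.tsv"),
            "cohort differential splicing calls", seed)
  acc <- setNames(cohort$truth$acceptor, cohort$truth$event_id)
  ctt <- cohortCagTagTest(cc, acc)
  zs <- eventZscores(cohort$psi)
  ov <- overlapAssociation(calls, zs)
  bs <- bindingSplicingCoassociation(calls, sw)

  ## integration (Fig. 4a-c analogues)
  gq <- simulateGeneQuant(ref, config, seed)
  conc <- bindingExpressionConcordance(gq$quant)
  .writeTsv(data.frame(
      statistic = c("cohort_cagtag_or", "cohort_cagtag_p",
                    "overlap_or", "overlap_p",
                    "binding_splicing_or", "binding_splicing_p",
                    "concordance_mut", "concordance_wt", "concordance_r2",
                    "plateau_wt", "plateau_mut"),
      value = c(ctt$odds_ratio, ctt$p, ov$odds_ratio, ov$p,
                bs$odds_ratio, bs$p, conc$n_mut_concordant,
                conc$n_wt_concordant, conc$r_squared,
                plateau(curves$wt), plateau(curves$mut))),
    file.path(outDir, "summary_statistics.tsv"),
    "integration summary statistics", seed)

  invisible(list(curves = curves, switches = sw, preferential = pref,
                 cohort_cagtag = ctt, overlap = ov,
                 binding_splicing = bs, concordance = conc))
}

.parseArgs <- function(args) {
  if (length(args) %% 2L != 0L)
    stop("options must come in --flag value pairs")
  if (length(args) == 0L) return(list())
  flags <- args[c(TRUE, FALSE)]
  vals <- args[c(FALSE, TRUE)]
  if (!all(startsWith(flags, "--")))
    stop("unknown argument: ", flags[!startsWith(flags, "--")][1L])
  setNames(as.list(vals), sub("^--", "", flags))
}

.opt <- function(opts, name, default = NULL, required = FALSE) {
  if (!is.null(opts[[name]])) return(opts[[name]])
  if (required) stop("missing required option --", name)
  default
}

#' Command-line dispatcher
#'
#' Backs the `inst/scripts/spliceclip.R` wrapper.  Subcommands: `simulate`
#' (write synthetic inputs), `occupancy`, `metagene`, `clusters`,
#' `splicing`, `cohort`, `demo`.
#'
#' @param args character vector of command-line arguments
#'   (`subcommand --flag value ...`).
#' @return Invisibly 0 on success; errors on unknown subcommands or
#'   malformed options.
#' @export
cliMain <- function(args) {
  if (length(args) == 0L)
    stop("usage: spliceclip <simulate|occupancy|metagene|clusters|",
         "splicing|cohort|demo> [--flag value ...]")
  sub <- args[1L]
  opts <- .parseArgs(args[-1L])
  seed <- as.integer(.opt(opts, "seed", 1L))
  out <- .opt(opts, "out", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  loadTracks <- function() {
    genome <- readGenome(.opt(opts, "genome", required = TRUE))
    sites <- readSpliceSites(.opt(opts, "sites", required = TRUE), genome)
    minSup <- as.integer(.opt(opts, "min-support", 4L))
    list(genome = genome, sites = sites,
         wt = readRTStops(.opt(opts, "stops-wt", required = TRUE), "wt",
                          minSupport = minSup),
         mut = readRTStops(.opt(opts, "stops-mut", required = TRUE), "mut",
                           minSupport = minSup))
  }

  switch(sub,
    simulate = {
      cfg <- simConfig(nGenes = as.integer(.opt(opts, "genes", 300L)),
                       sitesPerGene = as.integer(.opt(opts, "sites-per-gene",
                                                      10L)))
      ref <- simulateReference(cfg, seed, genome = TRUE)
      writeGenome(ref$genome, file.path(out, "genome.fa"))
      writeSpliceSites(ref$sites, file.path(out, "sites.bed"))
      writeRTStops(simulateRTStops(ref, cfg, "wt", seed)$track,
                   file.path(out, "stops_wt.bed"))
      writeRTStops(simulateRTStops(ref, cfg, "mut", seed)$track,
                   file.path(out, "stops_mut.bed"))
      cohort <- simulatePsiCohort(ref, cfg, seed)
      writePsiMatrix(cohort$psi, file.path(out, "psi.tsv"))
      writeEventCounts(cohort$counts, file.path(out, "events.tsv"))
      writeQuantTable(simulateGeneQuant(ref, cfg, seed)$quant,
                      file.path(out, "gene_quant.tsv"))
    },
    occupancy = {
      tr <- loadTracks()
      for (cond in c("wt", "mut")) {
        cv <- occupancyAnalysis(
          tr[[cond]], tr$sites,
          windowNt = as.integer(.opt(opts, "window", 20L)),
          window = as.integer(.opt(opts, "roll-window", 40L)),
          q = as.numeric(.opt(opts, "quantile", 0.75)))
        .writeTsv(data.frame(density = cv@rollingDensity,
                             occupancy = cv@rolling),
                  file.path(out, paste0("occupancy_", cond, ".tsv")),
                  paste0("occupancy saturation curve (", cond, ")"), seed,
                  list(plateau = sprintf("%.4f", plateau(cv))))
      }
    },
    metagene = {
      tr <- loadTracks()
      mg <- data.frame(
        offset = as.integer(names(metageneProfile(tr$wt, tr$sites))),
        wt = as.numeric(metageneProfile(tr$wt, tr$sites)),
        mut = as.numeric(metageneProfile(tr$mut, tr$sites)))
      .writeTsv(mg, file.path(out, "metagene.tsv"), "metagene profile",
                seed)
    },
    clusters = {
      tr <- loadTracks()
      span <- as.integer(.opt(opts, "span", 25L))
      minFrac <- as.numeric(.opt(opts, "min-frac", 0.10))
      minTotal <- as.integer(.opt(opts, "min-total", 10L))
      aWt <- clusterAssignments(tr$wt, tr$sites, span = span,
                                minFrac = minFrac, minTotal = minTotal)
      aMut <- clusterAssignments(tr$mut, tr$sites, span = span,
                                 minFrac = minFrac, minTotal = minTotal)
      .writeTsv(rbind(aWt, aMut), file.path(out, "clusters.tsv"),
                "C1-C10 cluster assignments", seed)
      .writeTsv(detectSwitches(aWt, aMut),
                file.path(out, "cluster_switches.tsv"),
                "major-cluster switches", seed)
    },
    splicing = {
      ev <- readEventCounts(.opt(opts, "events", required = TRUE))
      calls <- callDifferentialEvents(
        ev, dpsiMin = as.numeric(.opt(opts, "dpsi-min", 0.10)),
        bfMin = as.numeric(.opt(opts, "bf-min", 5)),
        readsMin = as.integer(.opt(opts, "reads-min", 10L)))
      .writeTsv(calls, file.path(out, "splicing_calls.tsv"),
                "differential splicing calls", seed)
    },
    cohort = {
      se <- readPsiMatrix(.opt(opts, "psi", required = TRUE))
      cc <- cohortCall(se,
                       groupI = .opt(opts, "group-i", "mut"),
                       groupII = .opt(opts, "group-ii", "wt"),
                       pMax = as.numeric(.opt(opts, "p-max", 0.05)),
                       dmedianMin = as.numeric(.opt(opts, "dmedian-min",
                                                    0.025)))
      .writeTsv(cc, file.path(out, "cohort_calls.tsv"),
                "cohort differential splicing calls", seed)
    },
    demo = {
      runDemo(out, seed)
    },
    stop("unknown subcommand: ", sub)
  )
  invisible(0L)
}
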