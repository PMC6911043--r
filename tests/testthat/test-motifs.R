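polyAReference <- function(nSites = 4L, len = 300L) {
  genome <- mkGenome(c1 = strrep("A", len))
  junction <- seq(60L, len - 60L, length.out = nSites)
  spliceSitesObj <- spliceSites("c1", as.integer(junction), "+",
                                sprintf("s%d", seq_len(nSites)),
                                sprintf("g%d", seq_len(nSites)),
                                genome = genome)
  list(genome = genome, sites = spliceSitesObj)
}

test_that("hexamer null is degenerate on a single-hexamer genome", {
  ref <- polyAReference()
  null <- buildHexamerNull(ref$sites, ref$genome, M = 2L, n = 5L, seed = 1)
  expect_equal(unname(null$mu["AAAAAA"]), 1)
  expect_equal(sum(null$mu), 1)
  expect_true(all(null$sigma == 0))
})

test_that("hexamer null matches full enumeration on a two-site toy", {
  ref <- randomReference(nSites = 2L, contigLen = 200L, seed = 3)
  null <- buildHexamerNull(ref$sites, ref$genome, M = 2L, n = 2L, seed = 1)
  ## M = 2 of 2 sites: every resample contains both windows
  g <- as.character(ref$genome[["c1"]])
  windows <- vapply(seq_along(ref$sites), function(i) {
    j <- GenomicRanges::start(ref$sites)[i]
    s <- as.character(GenomicRanges::strand(ref$sites))[i]
    if (s == "+") substr(g, j - 20L, j + 20L) else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(g, j - 20L, j + 20L))))
  }, "")
  expect_equal(unname(null$mu), oracleHexamerFreq(windows))
  expect_true(all(null$sigma == 0))

  ## reproducibility and the M bound
  null2 <- buildHexamerNull(ref$sites, ref$genome, M = 1L, n = 10L,
                            seed = 7)
  null3 <- buildHexamerNull(ref$sites, ref$genome, M = 1L, n = 10L,
                            seed = 7)
  expect_identical(null2$mu, null3$mu)
  expect_error(buildHexamerNull(ref$sites, ref$genome, M = 3L), "exceeds")
})

test_that("z equals (f - mu)/sigma with NA at sigma = 0", {
  ref <- randomReference(nSites = 30L, contigLen = 2000L, seed = 5)
  null <- buildHexamerNull(ref$sites, ref$genome, M = 15L, n = 20L,
                           seed = 2)
  set.seed(9)
  stops <- GenomicRanges::start(ref$sites) +
    sample(-10:10, length(ref$sites), replace = TRUE)
  tr <- mkTrack("c1", stops, as.character(GenomicRanges::strand(ref$sites)),
                count = 5L)
  hx <- hexamerZscores(tr, ref$sites, ref$genome, null)
  tab <- hexamerTable(hx)
  pos <- tab$sigma > 0
  expect_equal(tab$z[pos], (tab$f[pos] - tab$mu[pos]) / tab$sigma[pos])
  expect_true(all(is.na(tab$z[!pos])))
  expect_identical(nrow(tab), 4096L)
  expect_equal(sum(tab$f), 1)
  ## worked value: f=0.016, mu=0.01, sigma=0.002 -> z=3
  expect_equal((0.016 - 0.01) / 0.002, 3)
})

test_that("hexamer Z-scores are approximately N(0,1) under a uniform null", {
  set.seed(31)
  contigLen <- 120000L
  genome <- mkGenome(c1 = paste(sample(c("A", "C", "G", "T"), contigLen,
                                       replace = TRUE), collapse = ""))
  n <- 600L
  junction <- sort(sample(seq(100L, contigLen - 100L), n))
  keep <- c(TRUE, diff(junction) > 60L)
  junction <- junction[keep]
  sites <- spliceSites("c1", junction, "+",
                       sprintf("s%d", seq_along(junction)),
                       sprintf("g%d", seq_along(junction)), genome = genome)
  M <- floor(length(sites) / 2)
  null <- buildHexamerNull(sites, genome, M = M, n = 50L, seed = 4)
  occ <- sort(sample(length(sites), M))
  ## stops every 5 nt so the observed hexamer windows tile the +/-20 site
  ## window with the same structure the null counts
  stopPos <- rep(GenomicRanges::start(sites)[occ], each = 7L) +
    rep(seq(-15L, 15L, by = 5L), times = M)
  tr <- mkTrack("c1", unique(stopPos), "+", count = 4L)
  hx <- hexamerZscores(tr, sites[occ], genome, null)
  z <- hexamerTable(hx)$z
  z <- z[!is.na(z)]
  expect_gt(length(z), 3900)
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(sd(z), 0.8)
  expect_lt(sd(z), 1.2)
})

test_that("trinucleotide profile is exact on degenerate and toy inputs", {
  ref <- polyAReference()
  tr <- mkTrack("c1", 150L, "+", count = 5L)
  prof <- trinucleotideProfile(tr, ref$genome, span = 10L)
  expect_true(all(prof[, "AAA"] == 1))
  expect_equal(unname(rowSums(prof)), rep(1, 21))

  ## single stop on a known random 60-mer: enumerate by hand
  ref2 <- randomReference(nSites = 3L, contigLen = 200L, seed = 8)
  tr2 <- mkTrack("c1", 100L, "+", count = 5L)
  p2 <- trinucleotideProfile(tr2, ref2$genome, span = 5L)
  g <- as.character(ref2$genome[["c1"]])
  for (d in -5:5) {
    tri <- substr(g, 100L + d, 102L + d)
    expect_equal(unname(p2[as.character(d), tri]), 1)
  }
  expect_error(trinucleotideProfile(emptyTrack(), ref2$genome), "no RT")
})

test_that("preferential binding scores are zero for identical samples and log2 of the ratio", {
  ref <- randomReference(nSites = 25L, contigLen = 1600L, seed = 12)
  set.seed(13)
  stops <- GenomicRanges::start(ref$sites) +
    sample(-5:5, length(ref$sites), replace = TRUE)
  tr <- mkTrack("c1", stops, as.character(GenomicRanges::strand(ref$sites)),
                count = 5L)
  null <- buildHexamerNull(ref$sites, ref$genome, M = 10L, n = 10L,
                           seed = 3)
  hx <- hexamerZscores(tr, ref$sites, ref$genome, null)
  pref <- preferentialBindingScore(hx, hx)
  expect_true(all(pref$score == 0))

  ## doubled frequencies with a vanishing pseudocount -> score 1
  hx2 <- hx
  tab <- hexamerTable(hx)
  tab$f <- tab$f * 2
  hx2@table <- tab
  pref2 <- preferentialBindingScore(hx2, hx, pseudocount = 1e-300)
  nz <- pref2$f_wt > 0
  expect_equal(pref2$score[nz], rep(1, sum(nz)))
})

test_that("the mutant condition prefers CAG in hexamer and trinucleotide outputs", {
  cfg <- simConfig(nGenes = 80L, sitesPerGene = 5L, intronLength = 300L)
  ref <- simulateReference(cfg, 51, genome = TRUE)
  wt <- simulateRTStops(ref, cfg, "wt", 51)
  mut <- simulateRTStops(ref, cfg, "mut", 51)
  occWt <- callOccupiedSites(wt$track, ref$sites)
  occMut <- callOccupiedSites(mut$track, ref$sites)
  nullWt <- buildHexamerNull(ref$sites, ref$genome, M = sum(occWt),
                             seed = 52)
  nullMut <- buildHexamerNull(ref$sites, ref$genome, M = sum(occMut),
                              seed = 53)
  hxWt <- hexamerZscores(wt$track, ref$sites[occWt], ref$genome, nullWt)
  hxMut <- hexamerZscores(mut$track, ref$sites[occMut], ref$genome,
                          nullMut)
  isCag <- grepl("CAG", hexamerTable(hxWt)$hexamer, fixed = TRUE)
  zw <- hexamerTable(hxWt)$z; zm <- hexamerTable(hxMut)$z
  expect_gt(mean(zm[isCag], na.rm = TRUE), mean(zw[isCag], na.rm = TRUE))

  ## CAG-containing hexamers rank toward the mutant-preferred end
  pref <- preferentialBindingScore(hxMut, hxWt)
  cagRank <- which(grepl("CAG", pref$hexamer, fixed = TRUE))
  expect_lt(mean(cagRank), (nrow(pref) + 1) / 2)

  ## trinucleotide profile: CAG enriched near the acceptor in the mutant
  triWt <- trinucleotideProfile(wt$track, ref$genome, ref$sites)
  triMut <- trinucleotideProfile(mut$track, ref$genome, ref$sites)
  accRows <- as.character(-4:0)
  expect_gt(max(triMut[accRows, "CAG"]), max(triWt[accRows, "CAG"]))
  ## and the mutant/wild-type CAG vs TAG direction follows the multipliers
  ratio <- function(m) max(m[accRows, "CAG"]) / max(m[accRows, "TAG"])
  expect_gt(ratio(triMut), ratio(triWt))
})

test_that("a TAG-to-CAG preference switch drives the top preferential-binding hexamers", {
  ## strong, sub-saturated contrast (wild-type prefers TAG, mutant CAG)
  ## with count-weighted frequencies: the top-scoring mutant hexamers
  ## should be dominated by CAG
  cfg <- simConfig(nGenes = 200L, sitesPerGene = 10L, intronLength = 300L,
                   occupancy = c(wt = 0.45, mut = 0.45),
                   triMultipliers = list(
                     wt = c(CAG = 0.4, TAG = 2.5, AAG = 1, other = 1),
                     mut = c(CAG = 2.5, TAG = 0.4, AAG = 1, other = 1)))
  ref <- simulateReference(cfg, 61, genome = TRUE)
  wt <- simulateRTStops(ref, cfg, "wt", 61)
  mut <- simulateRTStops(ref, cfg, "mut", 61)
  occWt <- callOccupiedSites(wt$track, ref$sites)
  occMut <- callOccupiedSites(mut$track, ref$sites)
  nullS <- buildHexamerNull(ref$sites, ref$genome, M = sum(occWt),
                            seed = 62)
  hxWt <- hexamerZscores(wt$track, ref$sites[occWt], ref$genome, nullS,
                         weighted = TRUE)
  hxMut <- hexamerZscores(mut$track, ref$sites[occMut], ref$genome, nullS,
                          weighted = TRUE)
  pref <- preferentialBindingScore(hxMut, hxWt, pseudocount = 1e-4)
  cag <- grepl("CAG", pref$hexamer, fixed = TRUE)
  tag <- grepl("TAG", pref$hexamer, fixed = TRUE)
  expect_gt(mean(pref$score[cag & !tag]), mean(pref$score[tag & !cag]))
  ## and the top of the ranking is dominated by acceptor-derived hexamers
  expect_gt(mean(grepl("AG", head(pref$hexamer, 50L), fixed = TRUE)),
            mean(grepl("AG", pref$hexamer, fixed = TRUE)))
})

test_that("positional base frequencies are stop-weighted and exact on toys", {
  ref <- polyAReference(nSites = 2L)
  genome <- mkGenome(c1 = paste0(strrep("A", 96), "CAG",
                                 strrep("A", 101)),
                     c2 = paste0(strrep("A", 96), "TAG",
                                 strrep("A", 101)))
  sites <- spliceSites(c("c1", "c2"), c(100L, 100L), "+", c("s1", "s2"),
                       c("g1", "g2"), genome = genome)
  tr <- mkTrack(c("c1", "c2"), c(98L, 98L), "+", count = 10L)
  pbf <- positionalBaseFrequency(tr, sites, genome, window = 4L)
  expect_equal(unname(pbf["-3", c("C", "T")]), c(0.5, 0.5))
  expect_equal(unname(pbf["-2", "A"]), 1)
  expect_equal(unname(pbf["-1", "G"]), 1)
  expect_equal(unname(rowSums(pbf)), rep(1, 9))

  ## stop weighting: double weight on the CAG site shifts -3 toward C
  tr2 <- mkTrack(c("c1", "c2"), c(98L, 98L), "+", count = c(30L, 10L))
  pbf2 <- positionalBaseFrequency(tr2, sites, genome, window = 4L)
  expect_equal(unname(pbf2["-3", "C"]), 0.75)

  expect_error(positionalBaseFrequency(emptyTrack(), sites, genome),
               "no sites")
})

test_that("motif statistics are invariant under reverse complement", {
  ref <- randomReference(nSites = 12L, contigLen = 900L, seed = 17)
  set.seed(18)
  pos <- GenomicRanges::start(ref$sites) +
    sample(-8:8, length(ref$sites), replace = TRUE)
  str <- as.character(GenomicRanges::strand(ref$sites))
  counts <- 4L + (pos %% 3L)
  tr <- mkTrack("c1", pos, str, count = counts)

  len <- Biostrings::width(ref$genome)[1]
  flip <- c("+" = "-", "-" = "+")
  genomeRC <- mkGenome(c1 = as.character(
    Biostrings::reverseComplement(ref$genome[[1]])))
  sitesRC <- spliceSites("c1", len - GenomicRanges::start(ref$sites) + 1L,
                         flip[str], ref$sites$site_id, ref$sites$gene_id,
                         genome = genomeRC)
  trRC <- mkTrack("c1", len - pos + 1L, flip[str], count = counts)

  null <- buildHexamerNull(ref$sites, ref$genome, M = 8L, n = 10L,
                           seed = 19)
  nullRC <- buildHexamerNull(sitesRC, genomeRC, M = 8L, n = 10L, seed = 19)
  expect_equal(null$mu, nullRC$mu)
  expect_equal(null$sigma, nullRC$sigma)

  obs <- observedHexamerFrequencies(tr, ref$sites, ref$genome)
  obsRC <- observedHexamerFrequencies(trRC, sitesRC, genomeRC)
  expect_equal(obs$freq, obsRC$freq)

  expect_equal(trinucleotideProfile(tr, ref$genome, ref$sites),
               trinucleotideProfile(trRC, genomeRC, sitesRC),
               ignore_attr = TRUE)
})
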