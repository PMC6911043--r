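## Small in-code fixtures shared across test files.

mkGenome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

mkTrack <- function(contig, pos, strand, count = 1L, condition = "wt") {
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = pos, width = 1L),
    strand = strand,
    count = as.integer(rep(count, length.out = length(pos))))
  RTStopTrack(sort(gr), condition)
}

emptyTrack <- function(condition = "wt") {
  gr <- GenomicRanges::GRanges(count = integer(0))
  RTStopTrack(gr, condition)
}

## a 60-nt plus-strand contig with one splice site: junction at position 31,
## acceptor CAG at 28..30
toyGenomePlus <- function() {
  intron <- paste(rep("T", 27), collapse = "")
  exon <- paste(rep("G", 30), collapse = "")
  mkGenome(c1 = paste0(intron, "CAG", exon))
}

## reverse-complement of toyGenomePlus on the minus strand: same transcript
toyGenomeMinus <- function() {
  rc <- Biostrings::reverseComplement(toyGenomePlus()[[1]])
  mkGenome(c1 = as.character(rc))
}

## random genome + random site set for property tests
randomReference <- function(nSites = 20L, contigLen = 400L, seed = 1L) {
  set.seed(seed)
  genome <- mkGenome(c1 = paste(sample(c("A", "C", "G", "T"), contigLen,
                                       replace = TRUE), collapse = ""))
  junction <- sort(sample(60:(contigLen - 60L), nSites))
  strand <- sample(c("+", "-"), nSites, replace = TRUE)
  sites <- spliceSites("c1", junction, strand,
                       sprintf("s%02d", seq_len(nSites)),
                       sprintf("g%02d", seq_len(nSites)), genome = genome)
  list(genome = genome, sites = sites)
}

smallConfig <- function(...) {
  simConfig(nGenes = 60L, sitesPerGene = 5L, intronLength = 300L, ...)
}

## random display-offset count profile for cluster oracle checks
randProfile <- function() {
  n <- sample(c(5L, 20L, 60L), 1L)
  counts <- as.integer(rmultinom(1L, n, prob = rep(1, 51))[, 1L])
  names(counts) <- as.character(-25:25)
  counts
}

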