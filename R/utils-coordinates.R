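## Coordinate conventions
##
## Internally, a splice site is stored as the 1-based genomic coordinate of
## the *junction*: the first exonic nucleotide of the downstream exon.
## Junction offsets are transcript-oriented: offset 0 is the first exonic
## nucleotide, offset -1 the last intronic nucleotide (the G of the AG
## acceptor), offset -2 the A, offset -3 the base defining the acceptor
## trinucleotide (C of CAG, T of TAG).  Minus-strand sites are handled by
## reverse-complementing, so offsets are always transcript-oriented.
##
## "Display" coordinates shift internal offsets by `displayOffset`
## (default -3), so the acceptor A sits at display -5 and the acceptor G at
## display -4 -- the labelling commonly used for U2AF1 cross-link peaks.

#' Convert junction offsets to genomic positions
#'
#' @param junction 1-based genomic coordinate(s) of the first exonic
#'   nucleotide.
#' @param strand `"+"` or `"-"` (recycled).
#' @param offset transcript-oriented junction offset(s).
#' @return Integer genomic positions.
#' @keywords internal
offsetToGenomic <- function(junction, strand, offset) {
  ifelse(as.character(strand) == "+", junction + offset, junction - offset)
}

#' Convert genomic positions to junction offsets
#' @inheritParams offsetToGenomic
#' @param pos 1-based genomic position(s).
#' @keywords internal
genomicToOffset <- function(junction, strand, pos) {
  ifelse(as.character(strand) == "+", pos - junction, junction - pos)
}

#' Convert internal junction offsets to display coordinates
#'
#' @param offset internal junction offsets (0 = first exonic nucleotide).
#' @param displayOffset shift applied for reporting; the default -3 places
#'   the acceptor AG at display positions -5/-4.
#' @return Display offsets.
#' @export
toDisplayOffset <- function(offset, displayOffset = -3L) {
  offset + displayOffset
}

#' @rdname toDisplayOffset
#' @export
fromDisplayOffset <- function(offset, displayOffset = -3L) {
  offset - displayOffset
}

## Extract transcript-oriented sequence at junction offsets from..to for a
## single site.  Returns NA_character_ if the window leaves the contig.
.siteWindowSeq <- function(genome, contig, junction, strand, from, to) {
  len <- Biostrings::width(genome)[match(contig, names(genome))]
  if (is.na(len)) stop("unknown contig: ", contig)
  g1 <- offsetToGenomic(junction, strand, from)
  g2 <- offsetToGenomic(junction, strand, to)
  lo <- min(g1, g2); hi <- max(g1, g2)
  if (lo < 1L || hi > len) return(NA_character_)
  s <- Biostrings::subseq(genome[[contig]], lo, hi)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

## Vectorised variant over sites; returns character vector with NA where the
## window is out of bounds.
.siteWindowSeqs <- function(genome, contig, junction, strand, from, to) {
  n <- length(junction)
  contig <- rep_len(as.character(contig), n)
  strand <- rep_len(as.character(strand), n)
  len <- setNames(Biostrings::width(genome), names(genome))[contig]
  g1 <- offsetToGenomic(junction, strand, from)
  g2 <- offsetToGenomic(junction, strand, to)
  lo <- pmin(g1, g2); hi <- pmax(g1, g2)
  ok <- !is.na(len) & lo >= 1L & hi <= len
  out <- rep(NA_character_, n)
  strand <- as.character(strand)
  for (ctg in unique(contig[ok])) {
    idx <- which(ok & contig == ctg)
    v <- Biostrings::extractAt(
      genome[[ctg]], IRanges::IRanges(start = lo[idx], end = hi[idx])
    )
    neg <- strand[idx] == "-"
    if (any(neg)) v[neg] <- Biostrings::reverseComplement(v[neg])
    out[idx] <- as.character(v)
  }
  out
}

## Deterministic sub-seed derivation (kept below 2^31).
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629) + 1L
}
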