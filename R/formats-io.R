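## Readers/writers for the standard formats the pipeline touches, and the
## splice-site container every other stage consumes.
##
## BED inputs are 0-based half-open; internal coordinates are 1-based
## (GRanges).  For a BED6 splice-site interval the junction (first exonic
## nucleotide) is `start` on "+" and `end - 1` on "-" (0-based), i.e.
## `start + 1` / `end` once 1-based.

.EVENT_TYPES <- c("SE", "RI", "A3SS", "A5SS", "NAGNAG")

#' Read a genome FASTA
#'
#' Sequences are uppercased and restricted to the A/C/G/T/N alphabet.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
  ## read as raw strings first so invalid letters are caught, not dropped
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA: ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("malformed FASTA: no records")
  ## keep only the first word of each header as contig name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::BStringSet(toupper(seqs))
  if (any(Biostrings::width(seqs) == 0L))
    stop("malformed FASTA: empty sequence record")
  good <- Biostrings::letterFrequency(seqs, letters = "ACGTN")
  bad <- Biostrings::width(seqs) - as.vector(good)
  if (any(bad > 0))
    stop("sequence alphabet must be restricted to A,C,G,T,N (record ",
         names(seqs)[which(bad > 0)[1L]], ")")
  Biostrings::DNAStringSet(seqs)
}

#' Write a genome FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Build a splice-site table
#'
#' Sites are width-1 [GenomicRanges::GRanges] located at the junction (the
#' first exonic nucleotide, 1-based) with metadata columns `site_id`,
#' `gene_id` and `acceptor` (the trinucleotide at junction offsets -3..-1,
#' transcript-oriented).
#'
#' @param contig,junction,strand site coordinates (1-based junction).
#' @param siteId,geneId identifiers; `siteId` must be unique.
#' @param genome [Biostrings::DNAStringSet] used to extract the acceptor
#'   trinucleotide (optional if `acceptor` is given).
#' @param acceptor pre-computed acceptor trinucleotides (bypasses genome
#'   extraction; used by the synthetic generator).
#' @return GRanges splice-site table.
#' @export
spliceSites <- function(contig, junction, strand, siteId, geneId,
                        genome = NULL, acceptor = NULL) {
  junction <- as.integer(junction)
  if (anyDuplicated(siteId))
    stop("duplicate site_id: ", siteId[duplicated(siteId)][1L])
  if (is.null(acceptor)) {
    if (is.null(genome))
      stop("either a genome or precomputed acceptor trinucleotides required")
    acceptor <- .siteWindowSeqs(genome, contig, junction, strand, -3L, -1L)
    len <- setNames(Biostrings::width(genome), names(genome))[contig]
    if (any(is.na(len)))
      stop("unknown contig: ", contig[is.na(len)][1L])
    oob <- is.na(acceptor) | junction < 1L | junction > len
    if (any(oob))
      stop("junction out of contig bounds (offsets -3..-1 unavailable) for ",
           siteId[oob][1L])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = junction, width = 1L),
    strand = strand,
    site_id = as.character(siteId), gene_id = as.character(geneId),
    acceptor = as.character(acceptor))
  names(gr) <- gr$site_id
  gr
}

#' Read a splice-site BED6 table
#'
#' BED6 with `name` = `"site_id;gene_id"`; the junction is the interval
#' start on "+" and `end - 1` on "-" (0-based half-open convention).
#'
#' @param path BED6 file.
#' @param genome [Biostrings::DNAStringSet] for acceptor extraction.
#' @return GRanges splice-site table (see [spliceSites()]).
#' @export
readSpliceSites <- function(path, genome) {
  bed <- read.table(path, sep = "\t", comment.char = "#",
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "character", "character"))
  ids <- strsplit(bed$name, ";", fixed = TRUE)
  siteId <- vapply(ids, `[`, "", 1L)
  geneId <- vapply(ids, function(x) if (length(x) > 1L) x[2L] else NA_character_, "")
  junction <- ifelse(bed$strand == "+", bed$start + 1L, bed$end)
  spliceSites(bed$chrom, junction, bed$strand, siteId, geneId, genome)
}

#' Write a splice-site table as BED6
#' @param sites GRanges splice-site table.
#' @param path output file.
#' @export
writeSpliceSites <- function(sites, path) {
  strand <- as.character(GenomicRanges::strand(sites))
  junction <- GenomicRanges::start(sites)
  start0 <- ifelse(strand == "+", junction - 1L, junction - 1L)
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = start0, end = start0 + 1L,
    name = paste(sites$site_id, sites$gene_id, sep = ";"),
    score = 0L, strand = strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an RT-stop track
#'
#' Accepts 4-column bedGraph (`chrom start end count`; strand supplied via
#' the `strand` argument) or BED6 (`chrom start end name count strand`).
#' Intervals wider than 1 nt are expanded to per-position counts.
#' Duplicate positions are summed (with a warning); zero-count lines are
#' dropped; negative counts are an error.  Positions supported by fewer
#' than `minSupport` stops are discarded at load time.
#'
#' @param path input file.
#' @param condition condition label for the track.
#' @param strand strand for 4-column bedGraph input ("+" or "-").
#' @param minSupport minimum RT stops required to keep a position
#'   (default 4).
#' @return An [RTStopTrack-class].
#' @export
readRTStops <- function(path, condition, strand = NULL, minSupport = 4L) {
  raw <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(raw) == 4L) {
    if (is.null(strand) || !strand %in% c("+", "-"))
      stop("bedGraph input requires strand = '+' or '-'")
    df <- data.frame(chrom = as.character(raw[[1L]]), start = raw[[2L]],
                     end = raw[[3L]], count = raw[[4L]], strand = strand)
  } else if (ncol(raw) >= 6L) {
    df <- data.frame(chrom = as.character(raw[[1L]]), start = raw[[2L]],
                     end = raw[[3L]], count = raw[[5L]],
                     strand = as.character(raw[[6L]]))
  } else stop("RT-stop input must be 4-column bedGraph or BED6")
  if (any(df$count < 0)) stop("negative RT-stop count")
  if (any(df$count != floor(df$count))) stop("RT-stop counts must be integers")
  df <- df[df$count > 0, , drop = FALSE]
  ## expand intervals to single positions (1-based)
  w <- df$end - df$start
  tab <- data.table::data.table(
    chrom = rep(df$chrom, w),
    pos = unlist(lapply(seq_len(nrow(df)),
                        function(i) (df$start[i] + 1L):df$end[i]),
                 use.names = FALSE),
    strand = rep(df$strand, w),
    count = rep(as.integer(df$count), w))
  if (anyDuplicated(tab[, c("chrom", "pos", "strand"), with = FALSE])) {
    warning("duplicate RT-stop positions summed")
    tab <- tab[, list(count = sum(count)), by = c("chrom", "pos", "strand")]
  }
  tab <- tab[tab$count >= minSupport, ]
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$pos, width = 1L),
    strand = tab$strand, count = tab$count)
  RTStopTrack(sort(gr), condition)
}

#' Write an RT-stop track as BED6
#' @param track an [RTStopTrack-class].
#' @param path output file.
#' @export
writeRTStops <- function(track, path) {
  gr <- stopPositions(track)
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::start(gr),
    name = ".", count = gr$count,
    strand = as.character(GenomicRanges::strand(gr)))
  con <- file(path, "w")
  writeLines(paste0("# spliceclip RT stops; condition=", condition(track)),
             con)
  write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(path)
}

#' Per-site cross-link profiles
#'
#' For each splice site, the RT-stop counts at transcript-oriented junction
#' offsets `-L..+L` (offset 0 = first exonic nucleotide).  Minus-strand
#' sites are mirrored so profiles are always transcript-oriented; positions
#' outside the contig are zero-filled.
#'
#' @param track an [RTStopTrack-class].
#' @param sites GRanges splice-site table.
#' @param L half-width of the profile window (nt).
#' @return Integer matrix, sites x offsets, rownames = `site_id`, colnames
#'   = internal junction offsets `-L..L`.
#' @export
siteProfiles <- function(track, sites, L = 50L) {
  stopifnot(L >= 1L)
  L <- as.integer(L)
  offs <- seq.int(-L, L)
  mat <- matrix(0L, nrow = length(sites), ncol = 2L * L + 1L,
                dimnames = list(sites$site_id, as.character(offs)))
  gr <- stopPositions(track)
  if (length(gr) == 0L) return(mat)
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(sites),
    ranges = IRanges::IRanges(start = GenomicRanges::start(sites) - L,
                              end = GenomicRanges::start(sites) + L),
    strand = GenomicRanges::strand(sites))
  ov <- GenomicRanges::findOverlaps(win, gr, ignore.strand = FALSE)
  if (length(ov)) {
    si <- S4Vectors::queryHits(ov)
    ti <- S4Vectors::subjectHits(ov)
    off <- genomicToOffset(GenomicRanges::start(sites)[si],
                           GenomicRanges::strand(sites)[si],
                           GenomicRanges::start(gr)[ti])
    idx <- cbind(si, off + L + 1L)
    counts <- gr$count[ti]
    agg <- data.table::data.table(i = idx[, 1L], j = idx[, 2L], n = counts)
    agg <- agg[, list(n = sum(n)), by = c("i", "j")]
    mat[cbind(agg$i, agg$j)] <- as.integer(agg$n)
  }
  mat
}

#' PSI cohort container
#'
#' Wraps an events x samples percent-spliced-in matrix and the sample
#' group labels in a [SummarizedExperiment::SummarizedExperiment]
#' (assay `"psi"`, `colData$group`).
#'
#' @param psi numeric matrix of psi values in [0,1] (NA allowed), rownames
#'   = event ids, colnames = sample ids.
#' @param groups sample group labels (one per column).
#' @return A SummarizedExperiment.
#' @export
psiExperiment <- function(psi, groups) {
  psi <- as.matrix(psi)
  if (any(psi < 0 | psi > 1, na.rm = TRUE))
    stop("psi values must lie in [0,1]")
  if (length(groups) != ncol(psi))
    stop("group labels must cover all samples")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(psi = psi),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(psi)))
}

#' Read / write a PSI matrix TSV
#'
#' Layout: comment header line, a `#groups` line carrying one group label
#' per sample, then `event_id` plus one column per sample; missing psi
#' encoded as `NA`.
#'
#' @param path TSV file.
#' @return [readPsiMatrix()] returns a SummarizedExperiment (see
#'   [psiExperiment()]).
#' @export
readPsiMatrix <- function(path) {
  lines <- readLines(path)
  gl <- grep("^#groups\t", lines, value = TRUE)
  if (length(gl) != 1L) stop("PSI TSV must carry one '#groups' line")
  body <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = body, sep = "\t", header = TRUE,
                    check.names = FALSE, na.strings = "NA")
  psi <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(psi) <- tab[[1L]]
  groups <- strsplit(gl, "\t", fixed = TRUE)[[1L]][-1L]
  psiExperiment(psi, groups)
}

#' @rdname readPsiMatrix
#' @param se SummarizedExperiment from [psiExperiment()].
#' @export
writePsiMatrix <- function(se, path) {
  psi <- SummarizedExperiment::assay(se, "psi")
  con <- file(path, "w")
  writeLines("# spliceclip PSI matrix", con)
  writeLines(paste(c("#groups", se$group), collapse = "\t"), con)
  writeLines(paste(c("event_id", colnames(psi)), collapse = "\t"), con)
  write.table(data.frame(event_id = rownames(psi), psi,
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(path)
}

#' Validate an event-count table
#'
#' Columns: `event_id`, `condition`, `inclusion`, `exclusion`, `type`
#' (one of SE, RI, A3SS, A5SS, NAGNAG) and `site_id` linking the event to
#' a 3' splice site.
#'
#' @param events data.frame of per-event, per-condition read counts.
#' @return The validated data.frame (invisibly coerced column types).
#' @export
validateEventCounts <- function(events) {
  need <- c("event_id", "condition", "inclusion", "exclusion", "type")
  if (!all(need %in% names(events)))
    stop("event counts need columns: ", paste(need, collapse = ", "))
  if (any(events$inclusion < 0 | events$exclusion < 0))
    stop("read counts must be nonnegative")
  if (!all(events$type %in% .EVENT_TYPES))
    stop("event type must be one of ", paste(.EVENT_TYPES, collapse = ", "))
  events
}

#' Read / write an event-count TSV
#' @param path TSV file.
#' @return [readEventCounts()] returns a validated data.frame.
#' @export
readEventCounts <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  validateEventCounts(tab)
}

#' @rdname readEventCounts
#' @param events validated event-count data.frame.
#' @export
writeEventCounts <- function(events, path) {
  validateEventCounts(events)
  con <- file(path, "w")
  writeLines("# spliceclip event counts", con)
  suppressWarnings(write.table(events, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  close(con)
  invisible(path)
}

#' Read / write a generic quantification TSV (e.g. per-gene CLIP counts
#' and expression)
#' @param path TSV file.
#' @return [readQuantTable()] returns a data.frame.
#' @export
readQuantTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' @rdname readQuantTable
#' @param tab data.frame to write.
#' @export
writeQuantTable <- function(tab, path) {
  con <- file(path, "w")
  writeLines("# spliceclip quantification table", con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  close(con)
  invisible(path)
}
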