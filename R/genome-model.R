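# Genomic data model: interval readers, gap derivation, gene-to-domain
# assignment. Intervals live in standard 1-based closed GRanges; the two
# supported input conventions ("bed" 0-based half-open, "inclusive" 1-based
# closed) are converted on read, and inclusiveCoords() renders the 0-based
# inclusive style used in printed TAD tables.

.coordsToGRanges <- function(chrom, start, end, coords = c("bed", "inclusive")) {
  coords <- match.arg(coords)
  if (any(end < start))
    stop("invalid interval: end < start")
  if (coords == "bed") {
    if (any(start < 0)) stop("invalid interval: start < 0")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  } else {
    if (any(start < 1)) stop("invalid interval: start < 1 (1-based inclusive)")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  }
}

#' Read a 3-column TAD BED file
#'
#' @param path path to a BED-like TSV (chrom, start, end; no header).
#' @param coords `"bed"` for 0-based half-open input, `"inclusive"` for
#'   1-based closed input.
#' @return sorted `GRanges`, one range per TAD.
#' @export
readTadBed <- function(path, coords = c("bed", "inclusive")) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  gr <- .coordsToGRanges(d[[1]], d[[2]], d[[3]], coords)
  GenomicRanges::sort(gr)
}

#' Read a 4+ column gene BED file
#'
#' Column 4 carries the stable gene identifier; strand (if present) is
#' ignored throughout.
#'
#' @inheritParams readTadBed
#' @return `GRanges` named by gene id with a `gene_id` metadata column.
#' @export
readGeneBed <- function(path, coords = c("bed", "inclusive")) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(d) < 4) stop("gene BED needs at least 4 columns (chrom,start,end,id)")
  if (anyDuplicated(d[[4]])) stop("gene ids must be unique")
  gr <- .coordsToGRanges(d[[1]], d[[2]], d[[3]], coords)
  S4Vectors::mcols(gr)$gene_id <- as.character(d[[4]])
  names(gr) <- as.character(d[[4]])
  gr
}

#' Render ranges in the 0-based inclusive style of printed TAD tables
#'
#' A half-open region `[0, 3000000)` renders as start 0, end 2,999,999.
#'
#' @param gr a `GRanges`.
#' @return data.frame with `chrom`, `start`, `end` (0-based inclusive) and
#'   any metadata columns.
#' @export
inclusiveCoords <- function(gr) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr) - 1,
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) out <- cbind(out, as.data.frame(mc))
  out
}

#' Derive gap regions from an ordered TAD list
#'
#' Gaps are the complement of the TADs from `chromOrigin` up to the start of
#' the last TAD: the region before the first TAD is gap 1, and each region
#' between two consecutive TADs follows. Zero-length gaps (abutting TADs)
#' are dropped and counted; retained gaps are numbered sequentially. The
#' region after the last TAD is not a gap.
#'
#' @param tads sorted, non-overlapping `GRanges` of TADs.
#' @param chromOrigin chromosome origin in bp (0-based; default 0).
#' @return `GRanges` of gaps with an `ordinal` metadata column;
#'   `metadata(.)$droppedGaps` holds the zero-length count.
#' @export
deriveGaps <- function(tads, chromOrigin = 0) {
  if (length(tads) == 0)
    stop("no TADs supplied")
  s <- GenomicRanges::start(tads)
  e <- GenomicRanges::end(tads)
  if (is.unsorted(s) || (length(tads) > 1 && any(s[-1] <= e[-length(e)])))
    stop("invalid partition: TADs must be sorted and non-overlapping")
  # candidate gaps in 1-based closed coords: [origin+1, s1-1], [e_i+1, s_{i+1}-1]
  gapStart <- c(chromOrigin + 1, e[-length(e)] + 1)
  gapEnd <- s - 1
  keep <- gapEnd >= gapStart
  dropped <- sum(!keep)
  gr <- GenomicRanges::GRanges(
    rep(as.character(GenomicRanges::seqnames(tads))[1], sum(keep)),
    IRanges::IRanges(gapStart[keep], gapEnd[keep])
  )
  S4Vectors::mcols(gr)$ordinal <- seq_len(sum(keep))
  S4Vectors::metadata(gr)$droppedGaps <- dropped
  gr
}

#' Build a DomainPartition from TADs
#'
#' @param tads sorted non-overlapping `GRanges` of TADs.
#' @param chromOrigin origin passed to [deriveGaps()].
#' @return a [DomainPartition-class] without gene assignment.
#' @export
domainPartition <- function(tads, chromOrigin = 0) {
  gaps <- deriveGaps(tads, chromOrigin)
  t2 <- tads
  S4Vectors::mcols(t2)$ordinal <- seq_along(t2)
  methods::new("DomainPartition",
    chrom = as.character(GenomicRanges::seqnames(tads))[1],
    tads = t2, gaps = gaps,
    droppedGaps = as.integer(S4Vectors::metadata(gaps)$droppedGaps)
  )
}

#' Assign genes to the TAD or gap region that fully contains them
#'
#' A gene is assigned if and only if its body is entirely contained in
#' exactly one TAD or gap region; genes spanning a domain boundary, covering
#' several domains, or lying outside every domain are marked excluded with a
#' reason.
#'
#' @param genes `GRanges` with a `gene_id` metadata column (see
#'   [readGeneBed()]).
#' @param partition a [DomainPartition-class].
#' @return the partition with its `assignment` table filled in.
#' @export
assignGenes <- function(genes, partition) {
  stopifnot(methods::is(partition, "DomainPartition"))
  ids <- S4Vectors::mcols(genes)$gene_id
  if (is.null(ids)) stop("genes need a gene_id metadata column")
  onChrom <- as.character(GenomicRanges::seqnames(genes)) == partition@chrom
  if (!all(onChrom)) stop("genes must be on the partition's chromosome")

  doms <- c(GenomicRanges::granges(partition@tads),
            GenomicRanges::granges(partition@gaps))
  kind <- c(rep("tad", length(partition@tads)),
            rep("gap", length(partition@gaps)))
  ord <- c(S4Vectors::mcols(partition@tads)$ordinal,
           S4Vectors::mcols(partition@gaps)$ordinal)

  within <- GenomicRanges::findOverlaps(genes, doms, type = "within")
  anyOv <- GenomicRanges::findOverlaps(genes, doms)

  nWithin <- tabulate(S4Vectors::queryHits(within), nbins = length(genes))
  nAny <- tabulate(S4Vectors::queryHits(anyOv), nbins = length(genes))

  status <- ifelse(nWithin == 1, "assigned", "excluded")
  reason <- rep(NA_character_, length(genes))
  reason[nWithin == 0 & nAny == 0] <- "outside all domains"
  reason[nWithin == 0 & nAny > 0] <- "spans a domain boundary"
  reason[nWithin > 1] <- "contained in multiple domains"
  status[nWithin > 1] <- "excluded"

  akind <- rep(NA_character_, length(genes))
  aord <- rep(NA_integer_, length(genes))
  one <- which(nWithin == 1)
  hitIdx <- S4Vectors::subjectHits(within)[match(one, S4Vectors::queryHits(within))]
  akind[one] <- kind[hitIdx]
  aord[one] <- ord[hitIdx]

  partition@assignment <- data.frame(
    gene_id = ids, kind = akind, ordinal = aord,
    status = status, reason = reason, stringsAsFactors = FALSE
  )
  methods::validObject(partition)
  partition
}

#' Gene anchor positions for genomic distance
#'
#' The default anchor is the gene-body midpoint, `floor((start0 + end0)/2)`
#' on the 0-based half-open scale; `anchor = "start"` uses the 0-based start.
#'
#' @param genes a `GRanges`.
#' @param anchor `"midpoint"` or `"start"`.
#' @return named numeric vector of positions (bp).
#' @export
geneAnchors <- function(genes, anchor = c("midpoint", "start")) {
  anchor <- match.arg(anchor)
  s0 <- GenomicRanges::start(genes) - 1
  e0 <- GenomicRanges::end(genes)
  pos <- if (anchor == "midpoint") floor((s0 + e0) / 2) else s0
  names(pos) <- S4Vectors::mcols(genes)$gene_id
  pos
}

#' Write a gene-to-domain assignment table
#'
#' @param partition an assigned [DomainPartition-class].
#' @param path output TSV path (`gene_id`, `kind`, `ordinal`, `status`).
#' @export
writeAssignment <- function(partition, path) {
  a <- geneAssignment(partition)
  utils::write.table(a[, c("gene_id", "kind", "ordinal", "status")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
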