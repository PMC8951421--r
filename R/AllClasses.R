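#' @import methods
#' @importFrom GenomicRanges GRanges start end width seqnames findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits metadata metadata<-
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' DomainPartition: ordered TADs and derived gap regions of one chromosome
#'
#' Holds the TADs of a single chromosome, the gap regions derived as their
#' complement, the number of zero-length gaps that were dropped during
#' derivation, and (once [assignGenes()] has run) the gene-to-domain
#' assignment table.
#'
#' @slot chrom chromosome label.
#' @slot tads `GRanges` of TADs, sorted and non-overlapping, with an
#'   `ordinal` metadata column (1-based index along the chromosome).
#' @slot gaps `GRanges` of positive-length gap regions with an `ordinal`
#'   metadata column.
#' @slot droppedGaps number of zero-length gaps removed during derivation.
#' @slot assignment `data.frame` with columns `gene_id`, `kind`
#'   (`"tad"`/`"gap"`/`NA`), `ordinal`, `status` (`"assigned"`/`"excluded"`)
#'   and `reason`.
#' @export
setClass("DomainPartition",
  representation(
    chrom = "character",
    tads = "GRanges",
    gaps = "GRanges",
    droppedGaps = "integer",
    assignment = "data.frame"
  ),
  prototype(droppedGaps = 0L, assignment = data.frame())
)

setValidity("DomainPartition", function(object) {
  msg <- character()
  t <- object@tads
  if (length(t) > 1) {
    if (is.unsorted(GenomicRanges::start(t)))
      msg <- c(msg, "TADs must be sorted by start")
    if (any(GenomicRanges::start(t)[-1] <= GenomicRanges::end(t)[-length(t)]))
      msg <- c(msg, "TADs must be non-overlapping")
  }
  if (length(object@gaps) && any(GenomicRanges::width(object@gaps) < 1))
    msg <- c(msg, "gap regions must have positive length")
  if (length(msg)) msg else TRUE
})

#' GoDag: one Gene Ontology DAG covering the three namespaces
#'
#' Parsed, non-obsolete GO terms with their `is_a`/`part_of` parent links.
#' Unknown relation types are collapsed to `is_a`; alternate ids resolve to
#' primary ids. Per-term semantic-value vectors are memoised in an internal
#' environment so repeated gene-pair scoring stays cheap.
#'
#' @slot terms character vector of term ids.
#' @slot namespace named character, term id -> `"BPO"`, `"CCO"` or `"MFO"`.
#' @slot parents named list, term id -> data.frame(`parent`, `relation`).
#' @slot children named integer, number of direct children per term.
#' @slot roots named character, namespace -> root term id.
#' @slot altIds named character, alternate id -> primary id.
#' @slot cache environment memoising semantic-value vectors.
#' @export
setClass("GoDag",
  representation(
    terms = "character",
    namespace = "character",
    parents = "list",
    children = "integer",
    roots = "character",
    altIds = "character",
    cache = "environment"
  )
)

setValidity("GoDag", function(object) {
  msg <- character()
  if (!all(names(object@namespace) %in% object@terms))
    msg <- c(msg, "namespace names must be term ids")
  if (!all(object@roots %in% object@terms))
    msg <- c(msg, "roots must be term ids")
  if (length(msg)) msg else TRUE
})

#' ContactMatrix: binned symmetric Hi-C contacts at a fixed resolution
#'
#' Sparse upper-triangle storage of an intra-chromosomal contact map. Bin
#' coordinates are the 0-based start positions of the resolution-sized bins
#' (as in the raw pair-list files), with `bin1 <= bin2`.
#'
#' @slot chrom chromosome label.
#' @slot resolution bin size in bp.
#' @slot entries `data.frame` with columns `bin1`, `bin2`, `count`.
#' @slot normalized whether counts are normalized (real) or raw (integer).
#' @export
setClass("ContactMatrix",
  representation(
    chrom = "character",
    resolution = "numeric",
    entries = "data.frame",
    normalized = "logical"
  ),
  prototype(normalized = FALSE)
)

setValidity("ContactMatrix", function(object) {
  msg <- character()
  if (object@resolution <= 0) msg <- c(msg, "resolution must be positive")
  e <- object@entries
  if (nrow(e)) {
    if (!all(c("bin1", "bin2", "count") %in% names(e)))
      msg <- c(msg, "entries need columns bin1, bin2, count")
    else {
      if (any(e$count < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(e$bin1 > e$bin2)) msg <- c(msg, "entries must have bin1 <= bin2")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SpatialNetwork: a gene-node graph with per-edge provenance
#'
#' Used for the Hi-C-derived gene-gene spatial interaction networks
#' (HiC-GGSI), their same-TAD-augmented variants (HiC-TAD-GGSI), functional
#' similarity networks, autoencoder reconstructions and unions thereof.
#'
#' @slot kind one of `"HiC-GGSI"`, `"HiC-TAD-GGSI"`, `"FSN"`,
#'   `"reconstructed"`, `"union"`.
#' @slot nodes character vector of gene ids.
#' @slot edges `data.frame` with columns `geneA`, `geneB` (unordered, stored
#'   with `geneA < geneB`), `provenance` (`"contact"`, `"same-TAD"`,
#'   `"similarity"`, `"predicted"`, ...) and `confidence` (NA when the edge
#'   does not come from a reconstruction).
#' @slot threshold edge-inclusion threshold used to build the network
#'   (similarity threshold for FSNs, NA otherwise).
#' @export
setClass("SpatialNetwork",
  representation(
    kind = "character",
    nodes = "character",
    edges = "data.frame",
    threshold = "numeric"
  ),
  prototype(threshold = NA_real_)
)

setValidity("SpatialNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (!all(c("geneA", "geneB") %in% names(e)))
      msg <- c(msg, "edges need columns geneA and geneB")
    else {
      if (any(e$geneA == e$geneB)) msg <- c(msg, "self-loops are not allowed")
      if (!all(c(e$geneA, e$geneB) %in% object@nodes))
        msg <- c(msg, "edge endpoints must be nodes")
    }
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated node ids")
  if (length(msg)) msg else TRUE
})

#' GaeModel: a fitted linear graph autoencoder
#'
#' Encoder `Z = normalize(A) %*% W`, decoder `Ahat = sigmoid(Z Z^T)`.
#'
#' @slot nodes gene ids in matrix order.
#' @slot W n x d weight matrix.
#' @slot Z n x d embedding.
#' @slot Ahat n x n reconstruction, entries in (0, 1).
#' @slot loss per-epoch training loss.
#' @slot config list of training settings (dim, lr, epochs, seed, depth).
#' @export
setClass("GaeModel",
  representation(
    nodes = "character",
    W = "matrix",
    Z = "matrix",
    Ahat = "matrix",
    loss = "numeric",
    config = "list"
  )
)

setValidity("GaeModel", function(object) {
  msg <- character()
  n <- length(object@nodes)
  if (nrow(object@Ahat) != n || ncol(object@Ahat) != n)
    msg <- c(msg, "Ahat must be n x n")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DomainPartition", function(object) {
  cat("DomainPartition on", object@chrom, "\n")
  cat(" ", length(object@tads), "TADs,", length(object@gaps),
      "gap regions (", object@droppedGaps, "zero-length gaps dropped)\n")
  a <- object@assignment
  if (nrow(a)) {
    cat(" ", sum(a$status == "assigned"), "genes assigned,",
        sum(a$status == "excluded"), "excluded\n")
  } else cat("  no gene assignment yet\n")
})

setMethod("show", "GoDag", function(object) {
  ns <- table(object@namespace)
  cat("GoDag with", length(object@terms), "terms (",
      paste(names(ns), as.integer(ns), collapse = ", "), ")\n")
})

setMethod("show", "ContactMatrix", function(object) {
  cat(if (object@normalized) "Normalized" else "Raw",
      "ContactMatrix on", object@chrom, "at", object@resolution, "bp:",
      nrow(object@entries), "non-zero bin pairs\n")
})

setMethod("show", "SpatialNetwork", function(object) {
  cat("SpatialNetwork [", object@kind, "]:", length(object@nodes),
      "nodes,", nrow(object@edges), "edges\n")
})

setMethod("show", "GaeModel", function(object) {
  cat("GaeModel:", length(object@nodes), "nodes, d =", ncol(object@W),
      ", final loss", signif(utils::tail(object@loss, 1), 4), "\n")
})
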