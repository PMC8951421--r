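# Hi-C-derived gene-gene spatial interaction networks: aggregate binned
# contacts to gene pairs, threshold into HiC-GGSI networks, augment with
# same-TAD edges into HiC-TAD-GGSI networks, and compute topology metrics.

#' Construct a ContactMatrix from a bin-pair table
#'
#' @param entries data.frame with `bin1`, `bin2` (0-based bin start
#'   coordinates in bp) and `count`; duplicates are summed, orientation is
#'   canonicalized to `bin1 <= bin2`.
#' @param chrom chromosome label.
#' @param resolution bin size in bp (> 0).
#' @param normalized whether counts are normalized.
#' @export
contactMatrix <- function(entries, chrom, resolution, normalized = FALSE) {
  if (resolution <= 0) stop("resolution must be positive")
  b1 <- pmin(entries$bin1, entries$bin2)
  b2 <- pmax(entries$bin1, entries$bin2)
  agg <- stats::aggregate(list(count = entries$count),
                          by = list(bin1 = b1, bin2 = b2), FUN = sum)
  agg <- agg[order(agg$bin1, agg$bin2), ]
  rownames(agg) <- NULL
  methods::new("ContactMatrix", chrom = chrom, resolution = resolution,
               entries = agg, normalized = normalized)
}

#' Read a contact TSV (bin1_start, bin2_start, count)
#'
#' @param path TSV path, no header, three columns.
#' @inheritParams contactMatrix
#' @export
readContacts <- function(path, chrom, resolution, normalized = FALSE) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("bin1", "bin2", "count"))
  contactMatrix(d, chrom, resolution, normalized)
}

# 0-based start coordinates of the bins a gene body overlaps (>= 1 bp)
.geneBins <- function(genes, resolution) {
  s0 <- GenomicRanges::start(genes) - 1
  e0 <- GenomicRanges::end(genes)
  lapply(seq_along(genes), function(i) {
    seq(floor(s0[i] / resolution), floor((e0[i] - 1) / resolution)) * resolution
  })
}

#' Aggregate Hi-C contacts to gene pairs
#'
#' For each unordered gene pair, sums the matrix entries over all unordered
#' bin pairs (b1, b2) where b1 overlaps one gene body and b2 the other (>= 1
#' bp overlap), counting each bin pair once even when both orientations
#' match. `aggregate = "mean"` divides by the number of overlapping bin
#' pairs instead.
#'
#' @param cm a [ContactMatrix-class].
#' @param genes `GRanges` with `gene_id`, on the matrix chromosome.
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return data.frame `geneA`, `geneB`, `contacts` for pairs with at least
#'   one populated bin pair.
#' @export
genePairContacts <- function(cm, genes, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  res <- contactResolution(cm)
  ids <- S4Vectors::mcols(genes)$gene_id
  bins <- .geneBins(genes, res)
  # bin -> gene index map
  binGenes <- split(rep(seq_along(genes), lengths(bins)),
                    unlist(bins, use.names = FALSE))
  e <- contactEntries(cm)
  acc <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(e))) {
    gA <- binGenes[[as.character(e$bin1[k])]]
    gB <- binGenes[[as.character(e$bin2[k])]]
    if (is.null(gA) || is.null(gB)) next
    pairs <- unique(data.frame(
      i = pmin(rep(gA, each = length(gB)), rep(gB, times = length(gA))),
      j = pmax(rep(gA, each = length(gB)), rep(gB, times = length(gA)))
    ))
    pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      key <- paste0(pairs$i[r], "_", pairs$j[r])
      prev <- acc[[key]]
      acc[[key]] <- if (is.null(prev)) e$count[k] else prev + e$count[k]
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(geneA = character(), geneB = character(),
                      contacts = numeric()))
  ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  contacts <- vapply(keys, function(k) acc[[k]], numeric(1))
  if (aggregate == "mean") {
    nPairs <- vapply(seq_along(i), function(r) {
      bA <- bins[[i[r]]]; bB <- bins[[j[r]]]
      length(unique(.pairKey(rep(bA, each = length(bB)),
                             rep(bB, times = length(bA)))))
    }, numeric(1))
    contacts <- contacts / nPairs
  }
  out <- data.frame(geneA = ids[i], geneB = ids[j], contacts = unname(contacts),
                    stringsAsFactors = FALSE)
  swap <- out$geneA > out$geneB
  tmp <- out$geneA[swap]; out$geneA[swap] <- out$geneB[swap]; out$geneB[swap] <- tmp
  out <- out[order(out$geneA, out$geneB), ]
  rownames(out) <- NULL
  out
}

#' Build a HiC-GGSI network
#'
#' Edge between two genes iff their aggregated Hi-C contacts and genomic
#' distance both meet their thresholds (inclusive, as in the ">= 800
#' contacts, >= 1 Mbp" settings). Genes without any qualifying edge are
#' excluded from the network.
#'
#' @param contactTable data.frame `geneA`, `geneB`, `contacts`
#'   ([genePairContacts()]).
#' @param genes `GRanges` with `gene_id` (for distances).
#' @param contactMin minimum contact count (inclusive).
#' @param distMin minimum genomic distance in bp (inclusive).
#' @param anchor passed to [geneAnchors()].
#' @return a [SpatialNetwork-class] of kind `"HiC-GGSI"`.
#' @export
buildHicGgsi <- function(contactTable, genes, contactMin, distMin,
                         anchor = "midpoint") {
  stopifnot(contactMin >= 0, distMin >= 0)
  ct <- addPairDistances(contactTable, genes, anchor)
  keep <- ct$contacts >= contactMin & ct$distance >= distMin
  e <- ct[keep, , drop = FALSE]
  edges <- data.frame(geneA = e$geneA, geneB = e$geneB,
                      provenance = rep("contact", nrow(e)),
                      confidence = rep(NA_real_, nrow(e)),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  methods::new("SpatialNetwork", kind = "HiC-GGSI",
               nodes = sort(unique(c(edges$geneA, edges$geneB))),
               edges = edges)
}

#' Augment a HiC-GGSI network with same-TAD edges
#'
#' All HiC-GGSI edges are kept; additionally, every pair of genes assigned
#' to the same TAD whose genomic distance is at least `distMin` gains an
#' edge (provenance `"same-TAD"`).
#'
#' @param ggsi a HiC-GGSI [SpatialNetwork-class].
#' @param partition an assigned [DomainPartition-class].
#' @param genes `GRanges` with `gene_id`.
#' @param distMin minimum genomic distance in bp (inclusive).
#' @param anchor passed to [geneAnchors()].
#' @return a [SpatialNetwork-class] of kind `"HiC-TAD-GGSI"` whose edge set
#'   is a superset of the input's.
#' @export
buildHicTadGgsi <- function(ggsi, partition, genes, distMin,
                            anchor = "midpoint") {
  tadPairs <- enumerateIntraPairs(partition, "tad")
  tadPairs <- addPairDistances(tadPairs, genes, anchor)
  tadPairs <- tadPairs[!is.na(tadPairs$distance) &
                       tadPairs$distance >= distMin, , drop = FALSE]
  old <- networkEdges(ggsi)
  oldKey <- .pairKey(old$geneA, old$geneB)
  newKey <- .pairKey(tadPairs$geneA, tadPairs$geneB)
  add <- tadPairs[!(newKey %in% oldKey), , drop = FALSE]
  edges <- rbind(
    old,
    if (nrow(add)) data.frame(geneA = add$geneA, geneB = add$geneB,
                              provenance = rep("same-TAD", nrow(add)),
                              confidence = rep(NA_real_, nrow(add)))
    else NULL
  )
  rownames(edges) <- NULL
  methods::new("SpatialNetwork", kind = "HiC-TAD-GGSI",
               nodes = sort(unique(c(edges$geneA, edges$geneB))),
               edges = edges)
}

#' Topology metrics of a spatial network
#'
#' Per-node degree, local clustering coefficient (0 for nodes with fewer
#' than two neighbours) and closeness centrality (computed within connected
#' components), plus the histogram of finite shortest-path lengths over
#' unordered node pairs.
#'
#' @param network a [SpatialNetwork-class].
#' @return list with `nodes` (data.frame `gene_id`, `degree`, `clustering`,
#'   `closeness`) and `pathLengths` (table of shortest-path length counts).
#' @export
topologyMetrics <- function(network) {
  g <- asIgraph(network)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  comp <- igraph::components(g)
  clo <- rep(NA_real_, igraph::vcount(g))
  names(clo) <- igraph::V(g)$name
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) > 1) {
      sub <- igraph::induced_subgraph(g, vs)
      clo[igraph::V(sub)$name] <- igraph::closeness(sub, normalized = TRUE)
    }
  }
  d <- igraph::distances(g)
  ut <- d[upper.tri(d)]
  ut <- ut[is.finite(ut) & ut > 0]
  list(
    nodes = data.frame(gene_id = igraph::V(g)$name, degree = unname(deg),
                       clustering = unname(cc), closeness = unname(clo)),
    pathLengths = table(ut)
  )
}

#' Write a network edge list with provenance
#'
#' @param network a [SpatialNetwork-class].
#' @param path output TSV path.
#' @export
writeNetwork <- function(network, path) {
  utils::write.table(networkEdges(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
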