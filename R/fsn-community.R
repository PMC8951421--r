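# Functional similarity networks: threshold a gene-pair similarity table
# into a graph, detect divisive edge-betweenness (Girvan-Newman)
# communities, and score each community by its same-TAD-belonging ratio
# against size-matched random communities.

#' Build a functional similarity network
#'
#' Nodes are all genes appearing in the similarity table; an edge connects
#' two genes whose functional similarity is greater than or equal to the
#' threshold (inclusive). Pairs with undefined similarity are ignored.
#'
#' @param simTable data.frame with `geneA`, `geneB`, `sim`.
#' @param threshold similarity threshold in \[0, 1\] (typical values 0.5,
#'   0.7, 1).
#' @return a [SpatialNetwork-class] of kind `"FSN"`.
#' @export
buildFsn <- function(simTable, threshold = 0.5) {
  st <- simTable[!is.na(simTable$sim), , drop = FALSE]
  if (nrow(st) && (any(st$sim < 0) || any(st$sim > 1)))
    stop("similarities must be in [0, 1]")
  nodes <- sort(unique(c(st$geneA, st$geneB)))
  keep <- st$sim >= threshold & st$geneA != st$geneB
  e <- st[keep, , drop = FALSE]
  edges <- data.frame(
    geneA = pmin(e$geneA, e$geneB), geneB = pmax(e$geneA, e$geneB),
    provenance = rep("similarity", nrow(e)), confidence = e$sim,
    stringsAsFactors = FALSE
  )
  edges <- edges[!duplicated(edges[, c("geneA", "geneB")]), , drop = FALSE]
  rownames(edges) <- NULL
  methods::new("SpatialNetwork", kind = "FSN", nodes = nodes, edges = edges,
               threshold = threshold)
}

#' Detect communities by divisive edge betweenness
#'
#' Girvan-Newman: iteratively remove the edge of maximal (unweighted)
#' betweenness and cut the resulting dendrogram at maximal modularity.
#' Isolated nodes come back as singleton communities.
#'
#' @param network a [SpatialNetwork-class] (typically an FSN).
#' @return list of character vectors (member gene ids), sorted by size
#'   descending.
#' @export
detectCommunities <- function(network) {
  g <- asIgraph(network)
  if (igraph::ecount(g) == 0) {
    comm <- as.list(networkNodes(network))
  } else {
    cl <- igraph::cluster_edge_betweenness(g, weights = NULL)
    comm <- igraph::communities(cl)
    comm <- lapply(comm, as.character)
  }
  comm[order(-vapply(comm, length, 0L))]
}

#' Same-TAD-belonging ratio of a community
#'
#' The number of distinct TADs that the community's genes belong to, divided
#' by the number of (TAD-assigned) genes in the community. 1 means every
#' gene sits in its own TAD; smaller values mean more co-localization.
#' Members without a TAD assignment are dropped with a message.
#'
#' @param members character vector of gene ids.
#' @param partition an assigned [DomainPartition-class].
#' @return ratio in `[1/n, 1]`.
#' @export
sameTadRatio <- function(members, partition) {
  if (!length(members)) stop("empty community")
  a <- geneAssignment(partition)
  a <- a[a$status == "assigned" & a$kind == "tad", , drop = FALSE]
  ord <- a$ordinal[match(members, a$gene_id)]
  dropped <- sum(is.na(ord))
  if (dropped)
    message(dropped, " community member(s) without TAD assignment dropped")
  ord <- ord[!is.na(ord)]
  if (!length(ord)) stop("no TAD-assigned members in community")
  length(unique(ord)) / length(ord)
}

#' Size-matched random communities
#'
#' For each requested size, a seeded uniform sample of network nodes without
#' replacement.
#'
#' @param network a [SpatialNetwork-class].
#' @param sizes integer vector of community sizes.
#' @param seed RNG seed.
#' @return list of character vectors.
#' @export
randomCommunities <- function(network, sizes, seed = 1L) {
  nodes <- networkNodes(network)
  if (any(sizes > length(nodes)))
    stop("community size exceeds node count")
  set.seed(seed)
  lapply(sizes, function(s) sample(nodes, s))
}

#' Correlation between community size and same-TAD ratio
#'
#' @param sizes community sizes (>= 3 communities).
#' @param ratios same-TAD-belonging ratios.
#' @return list with `r`, `p.value` (`r` is `NA` and flagged when either
#'   vector is constant).
#' @export
sizeRatioCorrelation <- function(sizes, ratios) {
  if (length(sizes) < 3) stop("insufficient data: need >= 3 communities")
  if (stats::sd(sizes) == 0 || stats::sd(ratios) == 0)
    return(list(r = NA_real_, p.value = NA_real_, constant = TRUE))
  ht <- stats::cor.test(sizes, ratios, method = "pearson")
  list(r = unname(ht$estimate), p.value = ht$p.value, constant = FALSE)
}

#' Community report table
#'
#' Sizes and same-TAD-belonging ratios, sorted by size descending.
#'
#' @param communities list of member vectors ([detectCommunities()]).
#' @param partition an assigned [DomainPartition-class].
#' @export
communityReport <- function(communities, partition) {
  out <- data.frame(
    community_id = seq_along(communities),
    size = vapply(communities, length, 0L),
    ratio = vapply(communities, function(m)
      suppressMessages(sameTadRatio(m, partition)), numeric(1))
  )
  out[order(-out$size), ]
}
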