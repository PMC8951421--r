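# Long-range interactive region detection: classify resolution-sized bin
# pairs of a normalized contact map as strongly (count >= 10) or weakly
# (0 < count <= 0.2) interacting beyond a genomic-distance threshold, map
# genes into bins by >= 1 bp overlap, score region pairs by group-level
# functional similarity, and rank inter-chromosomal gene pairs by raw
# contacts.

#' Classify long-range region pairs as strongly or weakly interacting
#'
#' Only bin pairs whose start-coordinate distance is at least `distMin` are
#' considered; a pair is `strong` when its normalized count is >=
#' `strongMin`, `weak` when it is > 0 and <= `weakMax`, and dropped
#' otherwise.
#'
#' @param cm a normalized [ContactMatrix-class].
#' @param distMin minimum genomic distance between bin starts (bp).
#' @param strongMin strong threshold (default 10, inclusive).
#' @param weakMax weak threshold (default 0.2, inclusive; counts of 0 are
#'   dropped).
#' @return data.frame `bin1`, `bin2`, `count`, `distance`, `label`.
#' @export
classifyRegionPairs <- function(cm, distMin, strongMin = 10, weakMax = 0.2) {
  e <- contactEntries(cm)
  e$distance <- abs(e$bin2 - e$bin1)
  e <- e[e$distance >= distMin, , drop = FALSE]
  label <- rep(NA_character_, nrow(e))
  label[e$count >= strongMin] <- "strong"
  label[e$count > 0 & e$count <= weakMax] <- "weak"
  e$label <- label
  out <- e[!is.na(e$label), c("bin1", "bin2", "count", "distance", "label")]
  rownames(out) <- NULL
  out
}

#' Genes overlapping a resolution-sized bin
#'
#' A gene belongs to the bin when its body overlaps the half-open region
#' `[binStart, binStart + resolution)` by at least one base pair.
#'
#' @param genes `GRanges` with `gene_id`.
#' @param binStart 0-based bin start coordinate (bp).
#' @param resolution bin size (bp).
#' @return character vector of gene ids.
#' @export
genesInBin <- function(genes, binStart, resolution) {
  bin <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(genes))[1],
    IRanges::IRanges(binStart + 1, binStart + resolution)
  )
  ov <- GenomicRanges::findOverlaps(genes, bin, minoverlap = 1)
  S4Vectors::mcols(genes)$gene_id[S4Vectors::queryHits(ov)]
}

#' Group-level functional similarity of two gene sets
#'
#' Symmetric best-match average over the cross-group gene-pair similarity
#' matrix: each gene's best similarity to the other group is averaged, in
#' both directions. A gene sitting in both bins contributes to both groups
#' but its self pair is skipped (unless it is the gene's only counterpart,
#' in which case its best match is 1); genes with no annotation in the
#' ontology are excluded; `NA` when either direction has no scored gene.
#'
#' @param dag a [GoDag-class].
#' @param genesA,genesB character vectors of gene ids.
#' @param geneTerms named list gene -> term ids ([termsByGene()]).
#' @param config a [termSimConfig()].
#' @param cache optional memoisation environment.
#' @return similarity in \[0, 1\] or `NA_real_`.
#' @export
groupSimilarity <- function(dag, genesA, genesB, geneTerms,
                            config = termSimConfig(), cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  genesA <- unique(genesA); genesB <- unique(genesB)
  genesA <- genesA[vapply(genesA, function(g)
    !is.null(geneTerms[[g]]) && length(geneTerms[[g]]) > 0, logical(1))]
  genesB <- genesB[vapply(genesB, function(g)
    !is.null(geneTerms[[g]]) && length(geneTerms[[g]]) > 0, logical(1))]
  if (!length(genesA) || !length(genesB)) return(NA_real_)
  m <- matrix(NA_real_, length(genesA), length(genesB))
  for (i in seq_along(genesA))
    for (j in seq_along(genesB)) {
      if (genesA[i] == genesB[j]) next   # same gene in both bins
      m[i, j] <- genePairSimilarity(dag, geneTerms[[genesA[i]]],
                                    geneTerms[[genesB[j]]], config, cache)
    }
  best <- function(vals, self) {
    if (all(is.na(vals))) { if (self) 1 else NA_real_ }
    else max(vals, na.rm = TRUE)
  }
  rowBest <- vapply(seq_along(genesA), function(i)
    best(m[i, ], genesA[i] %in% genesB), numeric(1))
  colBest <- vapply(seq_along(genesB), function(j)
    best(m[, j], genesB[j] %in% genesA), numeric(1))
  rowBest <- rowBest[!is.na(rowBest)]
  colBest <- colBest[!is.na(colBest)]
  if (!length(rowBest) || !length(colBest)) return(NA_real_)
  (mean(rowBest) + mean(colBest)) / 2
}

#' Report functionally similar long-range region pairs
#'
#' Computes the group similarity for every classified region pair and
#' returns those at or above `simMin` (default 0.5), with the member genes
#' listed. Region pairs whose groups cannot be scored are skipped with a
#' message.
#'
#' @param regionPairs data.frame from [classifyRegionPairs()].
#' @param genes `GRanges` with `gene_id`.
#' @param resolution bin size (bp).
#' @param dag a [GoDag-class].
#' @param geneTerms named list gene -> term ids.
#' @param simMin group-similarity threshold (inclusive).
#' @param config a [termSimConfig()].
#' @param keepAll return all scored pairs instead of only those >= `simMin`.
#' @return data.frame `bin1`, `bin2`, `count`, `distance`, `label`,
#'   `similarity`, `genesA`, `genesB`.
#' @export
reportSimilarPairs <- function(regionPairs, genes, resolution, dag,
                               geneTerms, simMin = 0.5,
                               config = termSimConfig(), keepAll = FALSE) {
  cache <- new.env(parent = emptyenv())
  out <- regionPairs
  out$similarity <- NA_real_
  out$genesA <- NA_character_
  out$genesB <- NA_character_
  nSkipped <- 0L
  for (k in seq_len(nrow(out))) {
    gA <- genesInBin(genes, out$bin1[k], resolution)
    gB <- genesInBin(genes, out$bin2[k], resolution)
    s <- if (length(gA) && length(gB))
      groupSimilarity(dag, gA, gB, geneTerms, config, cache) else NA_real_
    if (is.na(s)) { nSkipped <- nSkipped + 1L; next }
    out$similarity[k] <- s
    out$genesA[k] <- paste(gA, collapse = ",")
    out$genesB[k] <- paste(gB, collapse = ",")
  }
  if (nSkipped) message(nSkipped, " region pair(s) without scorable genes skipped")
  keep <- if (keepAll) !is.na(out$similarity) else
    (!is.na(out$similarity) & out$similarity >= simMin)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank inter-chromosomal gene pairs by raw contact count
#'
#' @param contactTable data.frame `geneA`, `geneB`, `contacts` covering
#'   cross-chromosome pairs.
#' @param topN number of top pairs to keep (clamped to the table size).
#' @return the top rows sorted by contacts descending, ties broken by the
#'   gene-id pair ascending.
#' @export
rankInterchromPairs <- function(contactTable, topN) {
  o <- order(-contactTable$contacts, contactTable$geneA, contactTable$geneB)
  out <- contactTable[utils::head(o, topN), , drop = FALSE]
  rownames(out) <- NULL
  out
}
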