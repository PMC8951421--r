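# Gene function inference by neighbor voting on reconstructed networks:
# threshold the autoencoder reconstruction into a network, optionally union
# it with the original network, rank candidate GO terms for a central gene
# by their occurrence among radius-one neighbors, and evaluate top-k
# predictions against the true annotations by best semantic similarity.

#' Threshold an autoencoder reconstruction into a network
#'
#' Edge between nodes i and j iff the reconstruction confidence is strictly
#' higher than `confMin` (default 0.6); self-pairs are excluded.
#'
#' @param model a [GaeModel-class].
#' @param confMin confidence threshold (strict >).
#' @return a [SpatialNetwork-class] of kind `"reconstructed"` whose node set
#'   is the model's full node set; edges carry their confidence.
#' @export
thresholdReconstruction <- function(model, confMin = 0.6) {
  Ahat <- reconstruction(model)
  nodes <- model@nodes
  idx <- which(upper.tri(Ahat) & Ahat > confMin, arr.ind = TRUE)
  edges <- data.frame(
    geneA = nodes[idx[, 1]], geneB = nodes[idx[, 2]],
    provenance = rep("predicted", nrow(idx)), confidence = Ahat[idx],
    stringsAsFactors = FALSE
  )
  swap <- edges$geneA > edges$geneB
  tmp <- edges$geneA[swap]
  edges$geneA[swap] <- edges$geneB[swap]; edges$geneB[swap] <- tmp
  rownames(edges) <- NULL
  methods::new("SpatialNetwork", kind = "reconstructed", nodes = nodes,
               edges = edges, threshold = confMin)
}

#' Union of an original and a reconstructed network
#'
#' Contains all nodes and edges of both; edges present in both keep the
#' reconstruction confidence and get provenance `"both"`.
#'
#' @param original,reconstructed [SpatialNetwork-class] objects over a
#'   shared gene-id space.
#' @return a [SpatialNetwork-class] of kind `"union"`.
#' @export
unionNetwork <- function(original, reconstructed) {
  eo <- networkEdges(original)
  er <- networkEdges(reconstructed)
  keyO <- .pairKey(eo$geneA, eo$geneB)
  keyR <- .pairKey(er$geneA, er$geneB)
  onlyO <- eo[!(keyO %in% keyR), , drop = FALSE]
  er$provenance <- ifelse(keyR %in% keyO, "both", er$provenance)
  edges <- rbind(er, onlyO)
  rownames(edges) <- NULL
  methods::new("SpatialNetwork", kind = "union",
               nodes = sort(unique(c(networkNodes(original),
                                     networkNodes(reconstructed)))),
               edges = edges)
}

#' Rank GO terms for a central gene by neighbor occurrence voting
#'
#' Gathers the GO terms of all radius-one neighbors of the central gene
#' (annotations de-duplicated per neighbor) and scores each term by the
#' number of neighbors carrying it. Terms are ranked by score descending;
#' ties break by the summed confidence of the edges to the neighbors
#' carrying the term (descending; edges without a confidence count 1), then
#' by term id ascending. The central gene's own annotations play no role.
#'
#' @param network a [SpatialNetwork-class] with the central gene among its
#'   nodes.
#' @param geneTerms named list gene id -> term ids ([termsByGene()]).
#' @param gene central gene id.
#' @return data.frame `term_id`, `score`, `confSum`, ordered by rank
#'   (possibly zero rows when the gene has no annotated neighbors).
#' @export
inferTerms <- function(network, geneTerms, gene) {
  if (!(gene %in% networkNodes(network)))
    stop("gene ", gene, " is not in the network")
  e <- networkEdges(network)
  hitA <- e$geneA == gene
  hitB <- e$geneB == gene
  nbr <- c(e$geneB[hitA], e$geneA[hitB])
  conf <- c(e$confidence[hitA], e$confidence[hitB])
  conf[is.na(conf)] <- 1
  rows <- lapply(seq_along(nbr), function(k) {
    terms <- unique(geneTerms[[nbr[k]]])
    if (is.null(terms) || !length(terms)) return(NULL)
    data.frame(term_id = terms, conf = conf[k], stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(term_id = character(), score = integer(),
                      confSum = numeric()))
  score <- tapply(rows$conf, rows$term_id, length)
  confSum <- tapply(rows$conf, rows$term_id, sum)
  out <- data.frame(term_id = names(score), score = as.integer(score),
                    confSum = as.numeric(confSum), stringsAsFactors = FALSE)
  out <- out[order(-out$score, -out$confSum, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Evaluate top-k neighbor-voting predictions against true annotations
#'
#' Every node of the network is used once as the central gene. For each,
#' the top-k ranked predicted terms are compared to the gene's true terms
#' in the given ontology and the highest term-level semantic similarity is
#' kept; the mean of these per-gene maxima is reported. Genes without true
#' terms or without any prediction are excluded (counted).
#'
#' @param network a [SpatialNetwork-class].
#' @param geneTerms named list gene -> terms used for voting
#'   ([termsByGene()] on the prediction ontology).
#' @param trueTerms named list gene -> true term ids for evaluation.
#' @param dag a [GoDag-class].
#' @param k number of top predictions considered (1 or 4).
#' @param config a [termSimConfig()].
#' @param cache optional memoisation environment shared across calls.
#' @return list with `mean`, `perGene` (named numeric), `nSkipped`.
#' @export
evaluateTopK <- function(network, geneTerms, trueTerms, dag, k = 1,
                         config = termSimConfig(), cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  nodes <- networkNodes(network)
  perGene <- numeric(0)
  nSkipped <- 0L
  for (g in nodes) {
    truth <- unique(trueTerms[[g]])
    if (is.null(truth) || !length(truth)) { nSkipped <- nSkipped + 1L; next }
    pred <- inferTerms(network, geneTerms, g)
    if (!nrow(pred)) { nSkipped <- nSkipped + 1L; next }
    top <- utils::head(pred$term_id, k)
    best <- max(vapply(top, function(p)
      max(vapply(truth, function(t)
        .termSimCached(dag, p, t, config, cache), numeric(1))), numeric(1)))
    perGene[g] <- best
  }
  if (!length(perGene)) stop("no evaluable genes")
  list(mean = mean(perGene), perGene = perGene, nSkipped = nSkipped)
}
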