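# Accessor generics for the S4 containers. Slot access stays internal.

#' @rdname DomainPartition-class
#' @param object a `DomainPartition`
#' @export
setGeneric("tadRegions", function(object) standardGeneric("tadRegions"))
#' @rdname DomainPartition-class
#' @export
setGeneric("gapRegions", function(object) standardGeneric("gapRegions"))
#' @rdname DomainPartition-class
#' @export
setGeneric("geneAssignment", function(object) standardGeneric("geneAssignment"))
#' @rdname DomainPartition-class
#' @export
setGeneric("droppedGapCount", function(object) standardGeneric("droppedGapCount"))

#' @rdname SpatialNetwork-class
#' @param object a `SpatialNetwork`
#' @export
setGeneric("networkKind", function(object) standardGeneric("networkKind"))
#' @rdname SpatialNetwork-class
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname SpatialNetwork-class
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname SpatialNetwork-class
#' @export
setGeneric("asIgraph", function(object, ...) standardGeneric("asIgraph"))

#' @rdname GoDag-class
#' @param object a `GoDag`
#' @export
setGeneric("goTerms", function(object) standardGeneric("goTerms"))
#' @rdname GoDag-class
#' @export
setGeneric("goRoots", function(object) standardGeneric("goRoots"))
#' @rdname GoDag-class
#' @export
setGeneric("termNamespace", function(object, ...) standardGeneric("termNamespace"))

#' @rdname ContactMatrix-class
#' @param object a `ContactMatrix`
#' @export
setGeneric("contactEntries", function(object) standardGeneric("contactEntries"))
#' @rdname ContactMatrix-class
#' @export
setGeneric("contactResolution", function(object) standardGeneric("contactResolution"))

#' @rdname GaeModel-class
#' @param object a `GaeModel`
#' @export
setGeneric("reconstruction", function(object) standardGeneric("reconstruction"))
#' @rdname GaeModel-class
#' @export
setGeneric("embedding", function(object) standardGeneric("embedding"))

setMethod("tadRegions", "DomainPartition", function(object) object@tads)
setMethod("gapRegions", "DomainPartition", function(object) object@gaps)
setMethod("geneAssignment", "DomainPartition", function(object) object@assignment)
setMethod("droppedGapCount", "DomainPartition", function(object) object@droppedGaps)

setMethod("networkKind", "SpatialNetwork", function(object) object@kind)
setMethod("networkNodes", "SpatialNetwork", function(object) object@nodes)
setMethod("networkEdges", "SpatialNetwork", function(object) object@edges)

#' @rdname SpatialNetwork-class
#' @param ... unused
setMethod("asIgraph", "SpatialNetwork", function(object, ...) {
  e <- object@edges
  igraph::graph_from_data_frame(
    d = if (nrow(e)) e[, c("geneA", "geneB")] else
      data.frame(geneA = character(), geneB = character()),
    directed = FALSE,
    vertices = data.frame(name = object@nodes)
  )
})

setMethod("goTerms", "GoDag", function(object) object@terms)
setMethod("goRoots", "GoDag", function(object) object@roots)

#' @rdname GoDag-class
#' @param term term id (alternate ids are resolved)
#' @param ... unused
setMethod("termNamespace", "GoDag", function(object, term, ...) {
  unname(object@namespace[resolveTermIds(object, term)])
})

setMethod("contactEntries", "ContactMatrix", function(object) object@entries)
setMethod("contactResolution", "ContactMatrix", function(object) object@resolution)

setMethod("reconstruction", "GaeModel", function(object) object@Ahat)
setMethod("embedding", "GaeModel", function(object) object@Z)
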