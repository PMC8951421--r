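# GO DAG handling and semantic similarity. The term-level measure is a
# Wang-style hybrid: each term's semantic value is propagated to its
# ancestors through edge weights, and two terms are compared through the
# semantic values of their shared ancestors. The default edge weights are
# topology-dependent (they shrink with the parent's child count); plain
# fixed Wang weights are available via weights = "wang".

.NS_MAP <- c(biological_process = "BPO", cellular_component = "CCO",
             molecular_function = "MFO")
.GO_ROOTS <- c(BPO = "GO:0008150", CCO = "GO:0005575", MFO = "GO:0003674")
.EXP_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Experimental evidence codes retained by annotation filtering
#' @export
experimentalEvidenceCodes <- function() .EXP_CODES

.makeGoDag <- function(ids, namespace, parents, altIds = character()) {
  children <- integer(length(ids))
  names(children) <- ids
  for (p in parents) {
    if (nrow(p)) {
      tab <- table(p$parent)
      # counted below over all terms at once instead
    }
  }
  allParents <- unlist(lapply(parents, function(p) p$parent), use.names = FALSE)
  if (length(allParents)) {
    tab <- table(allParents)
    children[names(tab)] <- as.integer(tab)
  }
  dag <- methods::new("GoDag",
    terms = ids,
    namespace = stats::setNames(namespace, ids),
    parents = stats::setNames(parents, ids),
    children = children,
    roots = .GO_ROOTS[.GO_ROOTS %in% ids],
    altIds = altIds,
    cache = new.env(parent = emptyenv())
  )
  .checkDagReachesRoots(dag)
  dag
}

.checkDagReachesRoots <- function(dag) {
  # every non-root term must reach its namespace root; also guards acyclicity
  for (id in dag@terms) {
    seen <- character()
    frontier <- id
    for (step in seq_len(length(dag@terms) + 1)) {
      if (!length(frontier)) break
      seen <- union(seen, frontier)
      frontier <- setdiff(
        unlist(lapply(dag@parents[frontier], function(p) p$parent),
               use.names = FALSE), seen)
      if (step > length(dag@terms))
        stop("cycle detected in ontology at term ", id)
    }
    root <- .GO_ROOTS[dag@namespace[id]]
    if (!is.na(root) && root %in% dag@terms && !(root %in% seen))
      stop("term ", id, " does not reach its namespace root")
  }
  invisible(TRUE)
}

resolveTermIds <- function(dag, ids) {
  hit <- ids %in% names(dag@altIds)
  ids[hit] <- dag@altIds[ids[hit]]
  ids
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas (id, namespace, is_a, relationship: part_of,
#' is_obsolete, alt_id). Obsolete terms are dropped, unknown relationship
#' types collapse to `is_a`, and alternate ids are kept for resolution.
#'
#' @param path path to a `go.obo`-style file.
#' @return a [GoDag-class].
#' @export
readObo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  bounds <- c(which(grepl("^\\[", lines)), length(lines) + 1)
  ids <- character(); namespace <- character()
  parents <- list(); altIds <- character()
  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1
    block <- lines[s:e]
    val <- function(key) sub(paste0("^", key, ": *"), "",
                             grep(paste0("^", key, ":"), block, value = TRUE))
    if (length(val("is_obsolete")) && any(val("is_obsolete") == "true")) next
    id <- val("id")[1]
    if (is.na(id) || !length(id)) next
    ns <- .NS_MAP[val("namespace")[1]]
    if (is.na(ns)) next
    isa <- sub(" *!.*$", "", val("is_a"))
    rel <- val("relationship")
    relParent <- character(); relType <- character()
    if (length(rel)) {
      relClean <- sub(" *!.*$", "", rel)
      parts <- strsplit(relClean, " +")
      relType <- vapply(parts, `[`, "", 1)
      relParent <- vapply(parts, `[`, "", 2)
      relType[relType != "part_of"] <- "is_a"   # unknown relations -> is_a
    }
    p <- data.frame(
      parent = c(isa, relParent),
      relation = c(rep("is_a", length(isa)), relType),
      stringsAsFactors = FALSE
    )
    ids <- c(ids, id)
    namespace <- c(namespace, ns)
    parents[[length(parents) + 1]] <- p
    alts <- val("alt_id")
    if (length(alts)) altIds[alts] <- id
  }
  # drop parent links that point outside the parsed term set
  parents <- lapply(parents, function(p) p[p$parent %in% ids, , drop = FALSE])
  .makeGoDag(ids, namespace, parents, altIds)
}

#' Read a GAF 2.x gene-annotation file
#'
#' Keeps columns 2 (gene id), 5 (term id), 7 (evidence code) and 9 (aspect);
#' comment lines starting with `!` are skipped. No filtering is applied here
#' (see [filterAnnotations()]).
#'
#' @param path path to a GAF file.
#' @return data.frame with `gene_id`, `term_id`, `evidence`, `aspect`.
#' @export
readGaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_id = character(), term_id = character(),
                      evidence = character(), aspect = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    gene_id = vapply(f, `[`, "", 2),
    term_id = vapply(f, `[`, "", 5),
    evidence = vapply(f, `[`, "", 7),
    aspect = vapply(f, `[`, "", 9),
    stringsAsFactors = FALSE
  )
}

#' Filter annotations to experimental evidence and non-root terms
#'
#' Retains only annotations with evidence codes EXP, IDA, IPI, IMP, IGI or
#' IEP, removes the three namespace root terms, resolves alternate ids,
#' drops term ids unknown to the DAG (with a logged count), and
#' de-duplicates per (gene, term).
#'
#' @param annotations data.frame from [readGaf()] (or with at least
#'   `gene_id`, `term_id`, `evidence`).
#' @param dag a [GoDag-class].
#' @return filtered annotation data.frame with `gene_id`, `term_id`,
#'   `evidence`, `namespace`.
#' @export
filterAnnotations <- function(annotations, dag) {
  a <- annotations
  a <- a[a$evidence %in% .EXP_CODES, , drop = FALSE]
  a$term_id <- resolveTermIds(dag, a$term_id)
  unknown <- !(a$term_id %in% dag@terms)
  if (any(unknown))
    message(sum(unknown), " annotation(s) with unknown term ids dropped")
  a <- a[!unknown, , drop = FALSE]
  a <- a[!(a$term_id %in% .GO_ROOTS), , drop = FALSE]
  a <- a[!duplicated(a[, c("gene_id", "term_id")]), , drop = FALSE]
  a$namespace <- unname(dag@namespace[a$term_id])
  rownames(a) <- NULL
  a[, c("gene_id", "term_id", "evidence", "namespace")]
}

#' Term-similarity configuration
#'
#' @param weights `"topology"` (default) for topology-dependent edge weights
#'   `1/(c + nChildren(parent)) + w0` with `c = 0.67`, `w0 = 0.4` (is_a) /
#'   `0.3` (part_of); `"wang"` for fixed weights 0.8 (is_a) / 0.6 (part_of).
#' @param aggregation gene-pair aggregation of the term-similarity matrix:
#'   `"bma"` best-match average (default) or `"max"`.
#' @export
termSimConfig <- function(weights = c("topology", "wang"),
                          aggregation = c("bma", "max")) {
  list(weights = match.arg(weights), aggregation = match.arg(aggregation))
}

.edgeWeight <- function(dag, parent, relation, weights) {
  if (weights == "wang") {
    ifelse(relation == "part_of", 0.6, 0.8)
  } else {
    base <- ifelse(relation == "part_of", 0.3, 0.4)
    1 / (0.67 + pmax(1L, dag@children[parent])) + base
  }
}

#' Semantic-value vector of a term
#'
#' S-values over the term's ancestor set (term itself has S = 1; each
#' ancestor gets the maximum product of edge weights along a path down to
#' the term). Memoised per (term, weight scheme).
#'
#' @param dag a [GoDag-class].
#' @param term term id.
#' @param config a [termSimConfig()].
#' @return named numeric vector (ancestor ids including `term`).
#' @export
termSValues <- function(dag, term, config = termSimConfig()) {
  term <- resolveTermIds(dag, term)
  if (!(term %in% dag@terms)) stop("unknown term id: ", term)
  key <- paste0(config$weights, "|", term)
  if (!is.null(dag@cache[[key]])) return(dag@cache[[key]])
  sv <- stats::setNames(1, term)
  frontier <- term
  while (length(frontier)) {
    nxt <- character()
    for (ch in frontier) {
      p <- dag@parents[[ch]]
      if (!nrow(p)) next
      w <- .edgeWeight(dag, p$parent, p$relation, config$weights)
      cand <- w * sv[ch]
      for (k in seq_len(nrow(p))) {
        pid <- p$parent[k]
        if (is.na(sv[pid]) || cand[k] > sv[pid]) {
          sv[pid] <- cand[k]
          nxt <- c(nxt, pid)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dag@cache[[key]] <- sv
  sv
}

#' Semantic similarity of two GO terms
#'
#' Shared-ancestor semantic-value overlap: the summed S-values of the common
#' ancestors divided by the two terms' total semantic values. Symmetric,
#' in \[0, 1\], and exactly 1 for identical terms.
#'
#' @inheritParams termSValues
#' @param t1,t2 term ids in the same namespace.
#' @return similarity in \[0, 1\].
#' @export
termSimilarity <- function(dag, t1, t2, config = termSimConfig()) {
  t1 <- resolveTermIds(dag, t1); t2 <- resolveTermIds(dag, t2)
  ns1 <- dag@namespace[t1]; ns2 <- dag@namespace[t2]
  if (is.na(ns1) || is.na(ns2)) stop("unknown term id")
  if (ns1 != ns2)
    stop("namespace mismatch: ", t1, " (", ns1, ") vs ", t2, " (", ns2, ")")
  if (t1 == t2) return(1)
  sv1 <- termSValues(dag, t1, config)
  sv2 <- termSValues(dag, t2, config)
  common <- intersect(names(sv1), names(sv2))
  unname(sum(sv1[common] + sv2[common]) / (sum(sv1) + sum(sv2)))
}

.termSimCached <- function(dag, t1, t2, config, env) {
  key <- if (t1 < t2) paste0(t1, "|", t2) else paste0(t2, "|", t1)
  v <- env[[key]]
  if (is.null(v)) {
    v <- termSimilarity(dag, t1, t2, config)
    env[[key]] <- v
  }
  v
}

.bma <- function(simMat) {
  (sum(apply(simMat, 1, max)) + sum(apply(simMat, 2, max))) /
    (nrow(simMat) + ncol(simMat))
}

#' Functional similarity of a gene pair within one ontology
#'
#' Best-match average (by default) over the term-by-term similarity matrix
#' of the two genes' filtered annotation sets in the requested namespace.
#' Returns `NA` when either gene has no term in that namespace.
#'
#' @param dag a [GoDag-class].
#' @param termsA,termsB character vectors of term ids annotated to the two
#'   genes (already filtered; see [filterAnnotations()]).
#' @param config a [termSimConfig()].
#' @param cache optional environment for memoising term-pair similarities
#'   across many gene pairs.
#' @return similarity in \[0, 1\], or `NA_real_` if undefined.
#' @export
genePairSimilarity <- function(dag, termsA, termsB, config = termSimConfig(),
                               cache = NULL) {
  termsA <- unique(resolveTermIds(dag, termsA))
  termsB <- unique(resolveTermIds(dag, termsB))
  if (!length(termsA) || !length(termsB)) return(NA_real_)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  m <- matrix(0, length(termsA), length(termsB))
  for (i in seq_along(termsA))
    for (j in seq_along(termsB))
      m[i, j] <- .termSimCached(dag, termsA[i], termsB[j], config, cache)
  if (config$aggregation == "max") return(max(m))
  .bma(m)
}

#' Terms annotated to each gene in one namespace
#'
#' @param annotations filtered annotation data.frame ([filterAnnotations()]).
#' @param ontology `"BPO"`, `"CCO"` or `"MFO"`.
#' @return named list gene id -> character vector of term ids.
#' @export
termsByGene <- function(annotations, ontology = c("BPO", "CCO", "MFO")) {
  ontology <- match.arg(ontology)
  a <- annotations[annotations$namespace == ontology, , drop = FALSE]
  split(a$term_id, a$gene_id)
}

#' Functional similarities for a table of gene pairs
#'
#' @param dag a [GoDag-class].
#' @param pairs data.frame with `geneA`, `geneB`.
#' @param geneTerms list from [termsByGene()].
#' @param config a [termSimConfig()].
#' @return the pairs data.frame with a `sim` column (`NA` where a gene has
#'   no terms in the ontology; such pairs are excluded downstream).
#' @export
genePairSimilarities <- function(dag, pairs, geneTerms,
                                 config = termSimConfig()) {
  cache <- new.env(parent = emptyenv())
  pairs$sim <- vapply(seq_len(nrow(pairs)), function(k) {
    ta <- geneTerms[[pairs$geneA[k]]]
    tb <- geneTerms[[pairs$geneB[k]]]
    if (is.null(ta) || is.null(tb)) return(NA_real_)
    genePairSimilarity(dag, ta, tb, config, cache)
  }, numeric(1))
  nUndef <- sum(is.na(pairs$sim))
  if (nUndef) message(nUndef, " pair(s) undefined (gene without terms)")
  pairs
}
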