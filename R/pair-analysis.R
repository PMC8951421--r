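# Gene-pair analyses: intra/inter domain pair enumeration and sampling,
# duplicate filtering by sequence identity, distance binning, rank-sum
# distribution comparison, expression similarity (GESS), similarity /
# expression correlation, mutual pathways.

.canonPairs <- function(geneA, geneB) {
  swap <- geneA > geneB
  tmp <- geneA[swap]; geneA[swap] <- geneB[swap]; geneB[swap] <- tmp
  data.frame(geneA = geneA, geneB = geneB, stringsAsFactors = FALSE)
}

.pairKey <- function(geneA, geneB) {
  paste(pmin(geneA, geneB), pmax(geneA, geneB), sep = "\r")
}

.assignedGenes <- function(partition, kind) {
  a <- geneAssignment(partition)
  if (!nrow(a)) stop("partition has no gene assignment; run assignGenes()")
  a[a$status == "assigned" & a$kind == kind, c("gene_id", "ordinal")]
}

#' Enumerate all intra-domain gene pairs
#'
#' All unordered pairs of assigned genes sharing the same TAD (or gap)
#' ordinal.
#'
#' @param partition an assigned [DomainPartition-class].
#' @param kind `"tad"` or `"gap"`.
#' @return data.frame with `geneA`, `geneB`, `ordinal`, `relation`.
#' @export
enumerateIntraPairs <- function(partition, kind = c("tad", "gap")) {
  kind <- match.arg(kind)
  a <- .assignedGenes(partition, kind)
  out <- lapply(split(a$gene_id, a$ordinal), function(g) {
    if (length(g) < 2) return(NULL)
    idx <- utils::combn(length(g), 2)
    .canonPairs(g[idx[1, ]], g[idx[2, ]])
  })
  ords <- rep(as.integer(names(out)),
              vapply(out, function(x) if (is.null(x)) 0L else nrow(x), 0L))
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(geneA = character(), geneB = character())
  out$ordinal <- ords
  out$relation <- rep(paste0("intra-", kind), nrow(out))
  rownames(out) <- NULL
  out
}

#' Sample inter-domain gene pairs without replacement
#'
#' Seeded uniform sampling of unordered pairs whose two genes are assigned
#' to *different* domains of the given kind.
#'
#' @inheritParams enumerateIntraPairs
#' @param n number of pairs to draw.
#' @param seed RNG seed.
#' @return data.frame with `geneA`, `geneB`, `relation`.
#' @export
sampleInterPairs <- function(partition, kind = c("tad", "gap"), n,
                             seed = 1L) {
  kind <- match.arg(kind)
  a <- .assignedGenes(partition, kind)
  g <- a$gene_id; d <- a$ordinal
  m <- length(g)
  nEligible <- choose(m, 2) - sum(choose(table(d), 2))
  if (n > nEligible)
    stop("insufficient pairs: requested ", n, " but only ", nEligible,
         " eligible inter-", kind, " pairs exist")
  set.seed(seed)
  if (n == 0)
    return(data.frame(geneA = character(), geneB = character(),
                      relation = character()))
  # rejection sampling of unordered index pairs; dedupe until n collected
  seen <- character()
  outA <- character(); outB <- character()
  while (length(outA) < n) {
    need <- n - length(outA)
    i <- sample.int(m, need * 3, replace = TRUE)
    j <- sample.int(m, need * 3, replace = TRUE)
    ok <- i != j & d[i] != d[j]
    i <- i[ok]; j <- j[ok]
    key <- .pairKey(g[i], g[j])
    fresh <- !duplicated(key) & !(key %in% seen)
    i <- i[fresh]; j <- j[fresh]
    take <- seq_len(min(length(i), need))
    outA <- c(outA, pmin(g[i], g[j])[take])
    outB <- c(outB, pmax(g[i], g[j])[take])
    seen <- c(seen, key[fresh][take])
  }
  data.frame(geneA = outA, geneB = outB,
             relation = paste0("inter-", kind), stringsAsFactors = FALSE)
}

#' Sample baseline gene pairs ignoring domain labels
#'
#' Uniform seeded sampling over all assigned genes regardless of which TAD
#' or gap they live in.
#'
#' @param partition an assigned [DomainPartition-class].
#' @param n number of pairs.
#' @param seed RNG seed.
#' @export
sampleBaselinePairs <- function(partition, n, seed = 1L) {
  a <- geneAssignment(partition)
  g <- a$gene_id[a$status == "assigned"]
  if (choose(length(g), 2) < n) stop("insufficient pairs for baseline sample")
  set.seed(seed)
  seen <- character(); outA <- character(); outB <- character()
  while (length(outA) < n) {
    need <- n - length(outA)
    i <- sample.int(length(g), need * 3, replace = TRUE)
    j <- sample.int(length(g), need * 3, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    key <- .pairKey(g[i], g[j])
    fresh <- !duplicated(key) & !(key %in% seen)
    i <- i[fresh]; j <- j[fresh]
    take <- seq_len(min(length(i), need))
    outA <- c(outA, pmin(g[i], g[j])[take])
    outB <- c(outB, pmax(g[i], g[j])[take])
    seen <- c(seen, key[fresh][take])
  }
  data.frame(geneA = outA, geneB = outB, relation = "baseline",
             stringsAsFactors = FALSE)
}

#' Add genomic distances to a pair table
#'
#' Distance is `|anchorA - anchorB|` between gene anchors (midpoints by
#' default); defined only for same-chromosome pairs.
#'
#' @param pairs data.frame with `geneA`, `geneB`.
#' @param genes `GRanges` with `gene_id` (all on one chromosome).
#' @param anchor passed to [geneAnchors()].
#' @export
addPairDistances <- function(pairs, genes, anchor = "midpoint") {
  pos <- geneAnchors(genes, anchor)
  pairs$distance <- abs(pos[pairs$geneA] - pos[pairs$geneB])
  pairs
}

#' Read a pairwise sequence-identity table
#'
#' @param path TSV with columns geneA, geneB, identity (percent), evalue.
#' @export
readIdentityTable <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  names(d)[1:4] <- c("geneA", "geneB", "identity", "evalue")
  if (any(d$identity < 0 | d$identity > 100))
    stop("identity must be in [0, 100]")
  d
}

#' Remove putative duplicate-gene pairs
#'
#' Drops pairs whose sequence identity is strictly greater than 90% AND
#' whose e-value is below 0.01; pairs absent from the identity table are
#' kept.
#'
#' @param pairs data.frame with `geneA`, `geneB`.
#' @param identityTable data.frame with `geneA`, `geneB`, `identity`,
#'   `evalue` (unordered pairs).
#' @param identityMax identity cutoff (percent, exclusive).
#' @param evalueMax e-value cutoff (exclusive).
#' @export
filterDuplicates <- function(pairs, identityTable, identityMax = 90,
                             evalueMax = 0.01) {
  if (!nrow(pairs) || !nrow(identityTable)) return(pairs)
  dupKey <- .pairKey(identityTable$geneA, identityTable$geneB)
  bad <- dupKey[identityTable$identity > identityMax &
                identityTable$evalue < evalueMax]
  keep <- !(.pairKey(pairs$geneA, pairs$geneB) %in% bad)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Down-sample a pair table to a target size
#'
#' Used to re-balance intra and inter pair sets to equal size after
#' duplicate removal.
#'
#' @param pairs data.frame of pairs.
#' @param n target number of rows (must not exceed `nrow(pairs)`).
#' @param seed RNG seed.
#' @export
downsamplePairs <- function(pairs, n, seed = 1L) {
  if (n > nrow(pairs)) stop("cannot downsample ", nrow(pairs), " pairs to ", n)
  set.seed(seed)
  out <- pairs[sort(sample.int(nrow(pairs), n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin gene pairs by genomic distance
#'
#' A pair at distance `d` goes to bin `floor(d / binSize)`; bins are
#' half-open `[k*s, (k+1)*s)`, so bin 1 at bin size 200 kbp covers 200 kbp
#' (inclusive) to 400 kbp (exclusive).
#'
#' @param pairs data.frame with a `distance` column (same-chromosome pairs).
#' @param binSize bin width in bp.
#' @return the pairs with an integer `bin` column.
#' @export
binPairsByDistance <- function(pairs, binSize) {
  stopifnot(binSize > 0)
  pairs$bin <- as.integer(floor(pairs$distance / binSize))
  pairs
}

#' Compare two score distributions by Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test using the tie-corrected normal approximation,
#' plus a significance tier: `***` for p < 0.0001, `**` for
#' 0.0001 <= p < 0.001, `*` for 0.001 <= p < 0.05, `ns` otherwise.
#'
#' @param x,y numeric score vectors (both non-empty).
#' @return list with `p.value`, `tier`, `statistic`.
#' @export
compareDistributions <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input to compareDistributions")
  ht <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(p.value = ht$p.value, tier = significanceTier(ht$p.value),
       statistic = unname(ht$statistic))
}

#' Significance tier for a p-value
#' @param p p-value.
#' @return `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
significanceTier <- function(p) {
  if (p < 1e-4) "***" else if (p < 1e-3) "**" else if (p < 0.05) "*" else "ns"
}

#' Gene expression similarity score (GESS)
#'
#' `1 - |log2(ecA+1) - log2(ecB+1)| / (log2(max+1) - log2(min+1))`, clipped
#' to \[0, 1\]. 1 means the two genes have the same mean expression level; 0
#' means their gap equals the dataset's full log-scale range.
#'
#' @param ecA,ecB mean normalized expression counts of the two genes.
#' @param maxEc,minEc dataset maximum and minimum mean counts (`maxEc >
#'   minEc`).
#' @return score in \[0, 1\] (vectorised over `ecA`/`ecB`).
#' @export
gess <- function(ecA, ecB, maxEc, minEc) {
  if (maxEc <= minEc) stop("degenerate expression range: max <= min")
  rng <- log2(maxEc + 1) - log2(minEc + 1)
  val <- 1 - abs(log2(ecA + 1) - log2(ecB + 1)) / rng
  pmin(1, pmax(0, val))
}

#' Read a mean-expression table
#'
#' @param path TSV with columns gene_id, mean_count.
#' @return named numeric vector of mean counts.
#' @export
readExpressionTable <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (any(d[[2]] < 0)) stop("expression counts must be non-negative")
  stats::setNames(d[[2]], d[[1]])
}

#' GESS for a table of gene pairs
#'
#' @param pairs data.frame with `geneA`, `geneB`.
#' @param expression named numeric vector of mean counts
#'   ([readExpressionTable()]). The dataset max and min are taken over this
#'   vector.
#' @return pairs with a `gess` column (`NA` for genes without expression).
#' @export
pairGess <- function(pairs, expression) {
  mx <- max(expression); mn <- min(expression)
  pairs$gess <- gess(expression[pairs$geneA], expression[pairs$geneB], mx, mn)
  pairs
}

#' Correlate functional and expression similarity over gene pairs
#'
#' Pearson correlation between similarity and GESS over pairs whose
#' functional similarity exceeds `simThreshold` (strict), mirroring a
#' functional-threshold > 0.2 analysis.
#'
#' @param sim functional similarity scores per pair.
#' @param gessScores GESS per pair (same length).
#' @param simThreshold similarity threshold (strict >).
#' @return list with `r`, `p.value`, `n`.
#' @export
correlateScores <- function(sim, gessScores, simThreshold = 0.2) {
  keep <- !is.na(sim) & !is.na(gessScores) & sim > simThreshold
  if (sum(keep) < 3)
    stop("insufficient data: fewer than 3 pairs above similarity threshold")
  ht <- stats::cor.test(sim[keep], gessScores[keep], method = "pearson")
  list(r = unname(ht$estimate), p.value = ht$p.value, n = sum(keep))
}

#' Read a GMT pathway-membership file
#'
#' @param path GMT file: pathway id, description, member genes (tab-sep).
#' @return named list pathway id -> character vector of genes.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(f, function(x) x[-(1:2)]),
                  vapply(f, `[`, "", 1))
}

#' Mutual pathways of a gene pair
#'
#' Pathways in which both genes co-exist; one pair may have several.
#'
#' @param geneA,geneB gene ids.
#' @param pathways named list pathway -> member genes ([readGmt()]).
#' @return character vector of pathway ids (possibly empty).
#' @export
mutualPathways <- function(geneA, geneB, pathways) {
  hit <- vapply(pathways, function(g) (geneA %in% g) && (geneB %in% g),
                logical(1))
  names(pathways)[hit]
}
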