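# Linear graph autoencoder for link prediction on gene-gene spatial
# interaction networks: symmetric adjacency normalization, 7:2:1 edge
# splits with negative sampling, full-batch gradient descent on a
# class-rebalanced reconstruction cross-entropy, inner-product decoding,
# and AUC / average-precision evaluation with t-based confidence intervals.

#' Binary adjacency matrix of a spatial network
#'
#' @param network a [SpatialNetwork-class].
#' @return symmetric 0/1 matrix with zero diagonal, dimnames = gene ids.
#' @export
adjacencyMatrix <- function(network) {
  nodes <- networkNodes(network)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- networkEdges(network)
  if (nrow(e)) {
    i <- match(e$geneA, nodes); j <- match(e$geneB, nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' `Atilde = D^{-1/2} A D^{-1/2}` with D the diagonal degree matrix; rows
#' and columns of zero-degree nodes stay zero.
#'
#' @param A symmetric binary adjacency matrix with zero diagonal.
#' @return the normalized matrix.
#' @export
normalizeAdjacency <- function(A) {
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  A * outer(dinv, dinv)
}

#' Split network edges 7:2:1 with negative sampling
#'
#' Positive edges are shuffled and split into validation (`floor(0.2 m)`),
#' test (`floor(0.1 m)`) and training (the remainder). Validation and test
#' negative sets of matching sizes are sampled uniformly from the non-edges
#' and are disjoint from each other; all remaining non-edges are left as
#' training negatives (they enter the training loss).
#'
#' @param A symmetric binary adjacency matrix (>= 10 edges).
#' @param seed RNG seed.
#' @return list of 2-column index matrices (`i < j`): `trainPos`, `valPos`,
#'   `testPos`, `valNeg`, `testNeg`, plus `n`.
#' @export
splitEdges <- function(A, seed = 1L) {
  n <- nrow(A)
  ut <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 10) stop("need at least 10 edges to split")
  nonEdges <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  nVal <- floor(0.2 * m); nTest <- floor(0.1 * m)
  if (nrow(nonEdges) < nVal + nTest)
    stop("not enough non-edges for negative sampling")
  set.seed(seed)
  perm <- sample.int(m)
  valPos <- ut[perm[seq_len(nVal)], , drop = FALSE]
  testPos <- ut[perm[nVal + seq_len(nTest)], , drop = FALSE]
  trainPos <- ut[perm[-seq_len(nVal + nTest)], , drop = FALSE]
  negPerm <- sample.int(nrow(nonEdges), nVal + nTest)
  valNeg <- nonEdges[negPerm[seq_len(nVal)], , drop = FALSE]
  testNeg <- nonEdges[negPerm[nVal + seq_len(nTest)], , drop = FALSE]
  list(trainPos = trainPos, valPos = valPos, testPos = testPos,
       valNeg = valNeg, testNeg = testNeg, n = n)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train a linear graph autoencoder
#'
#' Encoder `Z = Atilde W` on the training adjacency (built from the
#' training edges only), decoder `Ahat = sigmoid(Z Z^T)`. W is optimized by
#' full-batch plain gradient descent on the class-rebalanced binary
#' cross-entropy between `Ahat` and the training adjacency over all
#' off-diagonal node pairs (positives up-weighted by the negative/positive
#' ratio). The objective is the summed (not averaged) cross-entropy -- the
#' raw rebalanced log-likelihood -- which gives plain gradient descent at
#' the configured learning rate a usable step size. Deterministic given
#' the seed.
#'
#' @param split an edge split from [splitEdges()].
#' @param nodes character vector of node ids (matrix order).
#' @param dim embedding dimension d (default 128).
#' @param lr learning rate (default 0.001).
#' @param epochs training epochs (default 200).
#' @param seed RNG seed for weight initialization.
#' @param selfLoops add A + I before normalization (off by default; the
#'   normalization is applied to the bare training adjacency).
#' @return a [GaeModel-class].
#' @export
trainGae <- function(split, nodes, dim = 128, lr = 0.001, epochs = 200,
                     seed = 1L, selfLoops = FALSE) {
  n <- split$n
  stopifnot(length(nodes) == n)
  A <- matrix(0, n, n)
  A[split$trainPos] <- 1
  A[split$trainPos[, c(2, 1), drop = FALSE]] <- 1
  Anorm <- A
  if (selfLoops) diag(Anorm) <- 1
  At <- normalizeAdjacency(Anorm)

  nPos <- sum(A)                       # ordered positive entries
  nNeg <- n * (n - 1) - nPos           # ordered off-diagonal negatives
  posW <- if (nPos > 0) nNeg / nPos else 1
  Wt <- matrix(1, n, n)
  Wt[A == 1] <- posW
  diag(Wt) <- 0

  set.seed(seed)
  lim <- sqrt(6 / (n + dim))
  W <- matrix(stats::runif(n * dim, -lim, lim), n, dim)

  eps <- 1e-12
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    Z <- At %*% W
    S <- Z %*% t(Z)
    P <- .sigmoid(S)
    L <- -(A * log(P + eps) + (1 - A) * log(1 - P + eps)) * Wt
    loss[ep] <- sum(L)
    if (!is.finite(loss[ep])) stop("divergence: non-finite training loss")
    G <- Wt * (P - A)                  # dLoss/dS, symmetric
    dZ <- 2 * (G %*% Z)
    dW <- t(At) %*% dZ
    W <- W - lr * dW
  }
  Z <- At %*% W
  Ahat <- .sigmoid(Z %*% t(Z))
  dimnames(Ahat) <- list(nodes, nodes)
  methods::new("GaeModel", nodes = nodes, W = W, Z = Z, Ahat = Ahat,
               loss = loss,
               config = list(dim = dim, lr = lr, epochs = epochs,
                             seed = seed, selfLoops = selfLoops))
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted 1/2 (midrank convention).
#'
#' @param posScores,negScores numeric score vectors.
#' @export
aucScore <- function(posScores, negScores) {
  np <- length(posScores); nn <- length(negScores)
  if (!np || !nn) stop("empty score set")
  r <- rank(c(posScores, negScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision (step-interpolated area under precision-recall)
#'
#' Items are ranked by decreasing score (ties broken by putting negatives
#' first, a conservative convention); AP is the mean of the precision at
#' each positive's rank.
#'
#' @param posScores,negScores numeric score vectors.
#' @export
apScore <- function(posScores, negScores) {
  np <- length(posScores)
  if (!np || !length(negScores)) stop("empty score set")
  scores <- c(posScores, negScores)
  labels <- c(rep(1L, np), rep(0L, length(negScores)))
  o <- order(-scores, labels)
  labels <- labels[o]
  prec <- cumsum(labels) / seq_along(labels)
  sum(prec[labels == 1]) / np
}

#' Evaluate a trained autoencoder on held-out edges
#'
#' Scores are the reconstruction entries at the subset's positive and
#' negative node pairs.
#'
#' @param model a [GaeModel-class].
#' @param split the [splitEdges()] split the model was trained on.
#' @param subset `"val"` or `"test"`.
#' @return list with `auc` and `ap`.
#' @export
evaluateGae <- function(model, split, subset = c("test", "val")) {
  subset <- match.arg(subset)
  pos <- split[[paste0(subset, "Pos")]]
  neg <- split[[paste0(subset, "Neg")]]
  if (!nrow(pos)) stop("empty evaluation subset")
  Ahat <- reconstruction(model)
  list(auc = aucScore(Ahat[pos], Ahat[neg]),
       ap = apScore(Ahat[pos], Ahat[neg]))
}

#' t-based confidence interval for a mean
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)` with the sample standard
#' deviation (n - 1 denominator).
#'
#' @param values numeric vector (n >= 2).
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `halfWidth`, `n`, `level`.
#' @export
confidenceInterval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  m <- mean(values)
  hw <- stats::qt((1 + level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  list(mean = m, halfWidth = hw, n = n, level = level)
}

#' Repeated link-prediction experiment on one network
#'
#' Re-splits the network with a distinct seed per repeat, trains, and
#' evaluates on the blind test split; reports per-repeat AUC/AP and their
#' means with 95% t-based confidence intervals (the ten-repeat protocol).
#'
#' @param network a [SpatialNetwork-class].
#' @param repeats number of repeats (default 10).
#' @param seed master seed; repeat r uses `seed + r - 1`.
#' @param ... passed to [trainGae()].
#' @return list with `runs` (data.frame seed/auc/ap), `auc` and `ap`
#'   ([confidenceInterval()] results).
#' @export
runGaeExperiment <- function(network, repeats = 10, seed = 1L, ...) {
  A <- adjacencyMatrix(network)
  nodes <- networkNodes(network)
  runs <- data.frame(seed = integer(), auc = numeric(), ap = numeric())
  for (r in seq_len(repeats)) {
    s <- seed + r - 1L
    split <- splitEdges(A, seed = s)
    model <- trainGae(split, nodes, seed = s, ...)
    ev <- evaluateGae(model, split, "test")
    runs <- rbind(runs, data.frame(seed = s, auc = ev$auc, ap = ev$ap))
  }
  list(runs = runs,
       auc = confidenceInterval(runs$auc),
       ap = confidenceInterval(runs$ap))
}
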