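# Functional similarity networks, Girvan-Newman communities, same-TAD
# ratios and random-community baselines.

simTableOf <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(geneA = m[, 1], geneB = m[, 2], sim = as.numeric(m[, 3]),
             stringsAsFactors = FALSE)
}

test_that("FSN edges follow the inclusive threshold", {
  st <- simTableOf("a", "b", 1, "a", "c", 0.7, "b", "c", 0.69, "c", "d", 0.2)
  expect_equal(nrow(networkEdges(buildFsn(st, 1.0))), 1)
  expect_equal(nrow(networkEdges(buildFsn(st, 0))), 4)
  f <- buildFsn(st, 0.7)
  expect_equal(nrow(networkEdges(f)), 2)   # exactly sim >= 0.7
  expect_setequal(networkNodes(f), c("a", "b", "c", "d"))
  # brute-force filter oracle
  expect_setequal(paste(networkEdges(f)$geneA, networkEdges(f)$geneB),
                  with(st[st$sim >= 0.7, ], paste(pmin(geneA, geneB),
                                                  pmax(geneA, geneB))))
})

test_that("a clique is one community and isolated nodes are singletons", {
  cl <- t(utils::combn(paste0("n", 1:4), 2))
  st <- data.frame(geneA = cl[, 1], geneB = cl[, 2], sim = 0.9)
  comm <- detectCommunities(buildFsn(st, 0.5))
  expect_length(comm, 1)
  expect_setequal(comm[[1]], paste0("n", 1:4))
  # graph with no edges at threshold 1 -> all singletons
  comm2 <- detectCommunities(buildFsn(st, 1))
  expect_length(comm2, 4)
  expect_true(all(lengths(comm2) == 1))
})

test_that("the bridge between two cliques has maximal betweenness and is cut", {
  # barbell: two 5-cliques joined by one bridge
  cliqueEdges <- function(nodes)
    t(utils::combn(nodes, 2))
  left <- paste0("L", 1:5); right <- paste0("R", 1:5)
  e <- rbind(cliqueEdges(left), cliqueEdges(right), c("L1", "R1"))
  st <- data.frame(geneA = e[, 1], geneB = e[, 2], sim = 0.9)
  fsn <- buildFsn(st, 0.5)

  # oracle: exhaustive shortest-path edge betweenness
  g <- igraph::graph_from_data_frame(st[, 1:2], directed = FALSE)
  eb <- numeric(nrow(st))
  nodes <- igraph::V(g)$name
  for (s in nodes) for (t in nodes) {
    if (s >= t) next
    paths <- igraph::all_shortest_paths(g, s, t)$res
    for (p in paths) {
      nm <- names(p)
      for (k in seq_len(length(nm) - 1)) {
        hit <- (st$geneA == nm[k] & st$geneB == nm[k + 1]) |
               (st$geneB == nm[k] & st$geneA == nm[k + 1])
        eb[hit] <- eb[hit] + 1 / length(paths)
      }
    }
  }
  bridge <- which(st$geneA == "L1" & st$geneB == "R1")
  expect_equal(which.max(eb), bridge)

  comm <- detectCommunities(fsn)
  expect_length(comm, 2)
  expect_setequal(comm[[1]], if ("L1" %in% comm[[1]]) left else right)
  expect_setequal(sort(unlist(comm)), sort(c(left, right)))
})

test_that("same-TAD ratio equals distinct TADs over members", {
  sim <- cachedSim()
  part <- assignGenes(sim$genome$genes, domainPartition(sim$genome$tads))
  a <- geneAssignment(part)
  a <- a[a$status == "assigned" & a$kind == "tad", ]
  byTad <- split(a$gene_id, a$ordinal)
  byTad <- byTad[lengths(byTad) >= 3]
  # all members in one TAD -> 1/n
  m1 <- byTad[[1]][1:3]
  expect_equal(sameTadRatio(m1, part), 1 / 3)
  # one member from each of 5 TADs -> 1
  m2 <- vapply(byTad[1:5], `[`, "", 1)
  expect_equal(sameTadRatio(m2, part), 1)
  # 2 + 2 across two TADs -> 0.5
  m3 <- c(byTad[[1]][1:2], byTad[[2]][1:2])
  expect_equal(sameTadRatio(m3, part), 0.5)
  expect_error(sameTadRatio(character(), part), "empty community")
  # members without TAD assignment are dropped with a message
  gapGene <- geneAssignment(part)
  gapGene <- gapGene$gene_id[gapGene$kind == "gap"][1]
  expect_message(r <- sameTadRatio(c(m1, gapGene), part), "dropped")
  expect_equal(r, 1 / 3)
})

test_that("random communities are seeded node subsets of the requested sizes", {
  st <- simTableOf("a", "b", 0.9, "c", "d", 0.9, "e", "f", 0.9)
  fsn <- buildFsn(st, 0.5)
  r1 <- randomCommunities(fsn, c(2, 3), seed = 5)
  r2 <- randomCommunities(fsn, c(2, 3), seed = 5)
  expect_identical(r1, r2)
  expect_equal(lengths(r1), c(2L, 3L))
  expect_true(all(unlist(r1) %in% networkNodes(fsn)))
  expect_false(any(vapply(r1, anyDuplicated, 0L) > 0))
  expect_setequal(randomCommunities(buildFsn(simTableOf("a", "b", 1), 0.5),
                                    2, 1)[[1]], c("a", "b"))
  expect_error(randomCommunities(fsn, 10, 1), "exceeds")
})

test_that("size-ratio correlation matches the formula and flags constants", {
  sizes <- c(10, 8, 6, 5, 3, 2)
  ratios <- c(0.1, 0.2, 0.3, 0.5, 0.8, 1.0)
  res <- sizeRatioCorrelation(sizes, ratios)
  expect_equal(res$r, stats::cor(sizes, ratios), tolerance = 1e-12)
  expect_lt(res$r, 0)
  expect_true(sizeRatioCorrelation(1:5, rep(0.5, 5))$constant)
  expect_equal(sizeRatioCorrelation(1:4, (1:4) * 0.1)$r, 1)
  expect_error(sizeRatioCorrelation(1:2, 1:2), "insufficient")
})

test_that("returned partition has modularity at least that of one big community", {
  left <- paste0("L", 1:5); right <- paste0("R", 1:5)
  e <- rbind(t(utils::combn(left, 2)), t(utils::combn(right, 2)), c("L1", "R1"))
  st <- data.frame(geneA = e[, 1], geneB = e[, 2], sim = 0.9)
  fsn <- buildFsn(st, 0.5)
  comm <- detectCommunities(fsn)
  g <- asIgraph(fsn)
  member <- integer(igraph::vcount(g))
  names(member) <- igraph::V(g)$name
  for (i in seq_along(comm)) member[comm[[i]]] <- i
  expect_gte(igraph::modularity(g, member),
             igraph::modularity(g, rep(1, igraph::vcount(g))))
})

test_that("detected communities are more TAD-coherent than size-matched random ones", {
  # a wider chromosome with more modules gives the comparison power
  cfg <- simConfig(seed = 2, chromLength = 20e6, nTads = 20, genesPerTad = 14,
                   loops = list(list(tadA = 3, tadB = 16, strength = 60)))
  sim <- simulateStudy(cfg)
  part <- assignGenes(sim$genome$genes, domainPartition(sim$genome$tads))
  dag <- sim$ontology$dag
  ann <- filterAnnotations(sim$ontology$annotations, dag)
  gt <- termsByGene(ann, "BPO")
  a <- geneAssignment(part)
  fg <- intersect(a$gene_id[a$status == "assigned" & a$kind == "tad"],
                  names(gt))
  idx <- utils::combn(length(fg), 2)
  st <- suppressMessages(genePairSimilarities(
    dag, data.frame(geneA = fg[idx[1, ]], geneB = fg[idx[2, ]]), gt))
  fsn <- buildFsn(st, 0.5)
  rep <- communityReport(detectCommunities(fsn), part)
  rnd <- vapply(randomCommunities(fsn, rep$size, seed = 9), function(m)
    suppressMessages(sameTadRatio(m, part)), numeric(1))
  big <- rep$size >= 2   # singletons are trivially tied at ratio 1
  expect_lt(mean(rep$ratio[big]), mean(rnd[big]))
  expect_lt(compareDistributions(rep$ratio[big], rnd[big])$p.value, 0.05)
})
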