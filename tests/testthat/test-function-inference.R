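# Reconstruction thresholding, network unions, neighbor-voting term
# ranking, and top-k evaluation.

workedExampleNetwork <- function() {
  edges <- data.frame(
    geneA = c("g1", "g1", "g1"), geneB = c("g2", "g3", "g4"),
    provenance = "predicted", confidence = c(0.7, 0.6, 0.8),
    stringsAsFactors = FALSE
  )
  methods::new("SpatialNetwork", kind = "reconstructed",
               nodes = c("g1", "g2", "g3", "g4"), edges = edges,
               threshold = 0.5)
}

workedExampleTerms <- function() {
  list(g2 = c("GO1", "GO2", "GO3"), g3 = c("GO1", "GO4"), g4 = "GO1")
}

test_that("the four-gene worked example scores GO1 = 3 and GO2 = 1", {
  ranked <- inferTerms(workedExampleNetwork(), workedExampleTerms(), "g1")
  expect_equal(ranked$term_id[1], "GO1")
  expect_equal(ranked$score[1], 3L)
  expect_equal(ranked$score[ranked$term_id == "GO2"], 1L)
  # tie-breaking: GO2/GO3 (conf 0.7 each) precede GO4 (conf 0.6),
  # GO2 before GO3 by id
  expect_equal(ranked$term_id, c("GO1", "GO2", "GO3", "GO4"))
  expect_equal(ranked$confSum[1], 0.7 + 0.6 + 0.8)
})

test_that("inference handles missing genes and unannotated neighborhoods", {
  net <- workedExampleNetwork()
  expect_error(inferTerms(net, workedExampleTerms(), "gX"), "not in the network")
  expect_equal(nrow(inferTerms(net, list(), "g1")), 0)
  # a neighbor annotated twice with one term counts once
  gt <- list(g2 = c("GO1", "GO1"), g3 = "GO1", g4 = "GO2")
  r <- inferTerms(net, gt, "g1")
  expect_equal(r$score[r$term_id == "GO1"], 2L)
})

test_that("reconstruction threshold is strict and matches a predicate filter", {
  nodes <- c("a", "b", "c")
  Ahat <- matrix(c(0.5, 0.61, 0.60,
                   0.61, 0.5, 0.70,
                   0.60, 0.70, 0.5), 3, 3,
                 dimnames = list(nodes, nodes))
  model <- methods::new("GaeModel", nodes = nodes,
                        W = matrix(0, 3, 1), Z = matrix(0, 3, 1),
                        Ahat = Ahat, loss = 0, config = list())
  net <- thresholdReconstruction(model, 0.6)
  e <- networkEdges(net)
  expect_setequal(paste(e$geneA, e$geneB), c("a b", "b c"))   # 0.60 excluded
  expect_setequal(networkNodes(net), nodes)
  # an all-0.5 reconstruction yields an empty network
  model2 <- methods::new("GaeModel", nodes = nodes,
                         W = matrix(0, 3, 1), Z = matrix(0, 3, 1),
                         Ahat = matrix(0.5, 3, 3,
                                       dimnames = list(nodes, nodes)),
                         loss = 0, config = list())
  expect_equal(nrow(networkEdges(thresholdReconstruction(model2, 0.6))), 0)
})

test_that("network union is the set union with provenance", {
  orig <- methods::new("SpatialNetwork", kind = "HiC-GGSI",
                       nodes = c("a", "b", "c"),
                       edges = data.frame(geneA = c("a", "b"),
                                          geneB = c("b", "c"),
                                          provenance = "contact",
                                          confidence = NA_real_))
  empty <- methods::new("SpatialNetwork", kind = "reconstructed",
                        nodes = c("a", "b"),
                        edges = data.frame(geneA = character(),
                                           geneB = character(),
                                           provenance = character(),
                                           confidence = numeric()))
  u0 <- unionNetwork(orig, empty)
  expect_setequal(with(networkEdges(u0), paste(geneA, geneB)),
                  c("a b", "b c"))
  uSelf <- unionNetwork(orig, orig)
  expect_equal(nrow(networkEdges(uSelf)), 2)
  recon <- methods::new("SpatialNetwork", kind = "reconstructed",
                        nodes = c("b", "c", "d"),
                        edges = data.frame(geneA = c("b", "c"),
                                           geneB = c("c", "d"),
                                           provenance = "predicted",
                                           confidence = c(0.9, 0.8)))
  u <- unionNetwork(orig, recon)
  e <- networkEdges(u)
  expect_setequal(paste(e$geneA, e$geneB), c("a b", "b c", "c d"))
  expect_equal(e$provenance[e$geneA == "b" & e$geneB == "c"], "both")
  expect_setequal(networkNodes(u), c("a", "b", "c", "d"))
})

test_that("top-k evaluation takes the best similarity over the k x truth grid", {
  dag <- toyDag()
  # central gene gX has 4 neighbors voting for distinct terms with a clear
  # ranking; truth matches the rank-3 prediction exactly
  edges <- data.frame(geneA = "gX", geneB = paste0("n", 1:4),
                      provenance = "predicted",
                      confidence = c(0.9, 0.8, 0.7, 0.6))
  # votes: GO:A x3, GO:B x2, GO:C x1 (from distinct neighbors)
  gt <- list(n1 = c("GO:A", "GO:B"), n2 = c("GO:A", "GO:B"),
             n3 = c("GO:A", "GO:C"), n4 = "GO:D")
  net <- methods::new("SpatialNetwork", kind = "reconstructed",
                      nodes = c("gX", paste0("n", 1:4)), edges = edges)
  truth <- list(gX = "GO:C")
  top1 <- evaluateTopK(net, gt, truth, dag, k = 1)
  top4 <- evaluateTopK(net, gt, truth, dag, k = 4)
  # top-1 = GO:A; best match is sim(A, C)
  expect_equal(top1$mean, termSimilarity(dag, "GO:A", "GO:C"))
  # top-4 includes GO:C itself (rank 3) -> exact hit
  expect_equal(top4$mean, 1)
  expect_gte(top4$mean, top1$mean)
  # brute-force grid oracle for k = 4
  ranked <- inferTerms(net, gt, "gX")
  grid <- outer(utils::head(ranked$term_id, 4), truth$gX,
                Vectorize(function(p, t) termSimilarity(dag, p, t)))
  expect_equal(top4$mean, max(grid))
})

test_that("two-gene evaluation averages the per-gene maxima", {
  dag <- toyDag()
  edges <- data.frame(geneA = c("u", "u", "v"), geneB = c("v", "w", "w"),
                      provenance = "predicted", confidence = 0.9)
  net <- methods::new("SpatialNetwork", kind = "reconstructed",
                      nodes = c("u", "v", "w"), edges = edges)
  gt <- list(u = "GO:C", v = "GO:D", w = "GO:B")
  truth <- list(u = "GO:C", v = "GO:D")   # w has no truth -> skipped
  res <- evaluateTopK(net, gt, truth, dag, k = 1)
  # u's neighbors: v, w -> predictions GO:B, GO:D (tie conf; id order GO:B first)
  pu <- inferTerms(net, gt, "u")$term_id[1]
  pv <- inferTerms(net, gt, "v")$term_id[1]
  oracle <- mean(c(termSimilarity(dag, pu, "GO:C"),
                   termSimilarity(dag, pv, "GO:D")))
  expect_equal(res$mean, oracle)
  expect_equal(res$nSkipped, 1L)
})

test_that("top-4 never scores below top-1 on synthetic reconstructions", {
  sim <- cachedSim()
  genes <- sim$genome$genes
  part <- assignGenes(genes, domainPartition(sim$genome$tads))
  ct <- genePairContacts(sim$contacts$raw, genes)
  ggsi <- buildHicGgsi(ct, genes, 40, 800e3)
  A <- adjacencyMatrix(ggsi)
  sp <- splitEdges(A, seed = 1)
  model <- trainGae(sp, networkNodes(ggsi), dim = 32, epochs = 100, seed = 1)
  recon <- thresholdReconstruction(model, 0.6)
  dag <- sim$ontology$dag
  ann <- filterAnnotations(sim$ontology$annotations, dag)
  gt <- termsByGene(ann, "BPO")
  cache <- new.env()
  t1 <- evaluateTopK(recon, gt, gt, dag, k = 1, cache = cache)
  t4 <- evaluateTopK(recon, gt, gt, dag, k = 4, cache = cache)
  expect_gte(t4$mean, t1$mean)
})

test_that("TAD-augmented networks support inference at least as well over 10 repeats", {
  sim <- cachedSim()
  genes <- sim$genome$genes
  part <- assignGenes(genes, domainPartition(sim$genome$tads))
  dag <- sim$ontology$dag
  ann <- filterAnnotations(sim$ontology$annotations, dag)
  gt <- termsByGene(ann, "BPO")
  ct <- genePairContacts(sim$contacts$raw, genes)
  ggsi <- buildHicGgsi(ct, genes, 40, 800e3)
  tad <- buildHicTadGgsi(ggsi, part, genes, 800e3)
  cache <- new.env()
  scoreNet <- function(net, s) {
    A <- adjacencyMatrix(net)
    m <- trainGae(splitEdges(A, seed = s), networkNodes(net), seed = s)
    recon <- thresholdReconstruction(m, 0.6)
    tryCatch(evaluateTopK(recon, gt, gt, dag, k = 4, cache = cache)$mean,
             error = function(e) NA_real_)
  }
  sG <- vapply(1:10, function(s) scoreNet(ggsi, s), numeric(1))
  sT <- vapply(1:10, function(s) scoreNet(tad, s), numeric(1))
  expect_gte(mean(sT, na.rm = TRUE), mean(sG, na.rm = TRUE))
})
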