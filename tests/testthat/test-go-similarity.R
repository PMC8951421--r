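# Annotation filtering and Wang-style term / gene-pair semantic similarity.

test_that("annotation filtering keeps only experimental evidence and non-root terms", {
  dag <- toyDag()
  raw <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g2", "g3", "g3", "g3"),
    term_id = c("GO:0008150", "GO:A", "GO:C", "GO:C", "GO:D",
                "GO:M1", "GO:B", "GO:ZZZ"),
    evidence = c("EXP", "IEA", "IDA", "IDA", "IMP", "IPI", "TAS", "EXP"),
    aspect = "P"
  )
  expect_message(out <- filterAnnotations(raw, dag), "unknown term")
  # root removed (even with EXP), IEA/TAS removed, duplicate (g2, GO:C)
  # collapsed, unknown GO:ZZZ dropped
  expect_equal(sort(paste(out$gene_id, out$term_id)),
               sort(c("g2 GO:C", "g2 GO:D", "g3 GO:M1")))
  expect_true(all(out$evidence %in% experimentalEvidenceCodes()))
  expect_equal(out$namespace[out$term_id == "GO:M1"], "MFO")
})

test_that("the six experimental codes survive a mixed-code annotation set", {
  dag <- toyDag()
  codes <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "IEA", "ISS", "TAS", "ND")
  raw <- data.frame(gene_id = paste0("g", seq_along(codes)),
                    term_id = "GO:C", evidence = codes, aspect = "P")
  out <- filterAnnotations(raw, dag)
  expect_equal(sort(out$evidence), sort(experimentalEvidenceCodes()))
})

test_that("term similarity is 1 on identity and errors across namespaces", {
  dag <- toyDag()
  expect_equal(termSimilarity(dag, "GO:C", "GO:C"), 1)
  expect_error(termSimilarity(dag, "GO:A", "GO:M1"), "namespace mismatch")
})

test_that("term similarity matches the path-enumeration oracle on the toy DAG", {
  dag <- toyDag()
  pairs <- list(c("GO:A", "GO:B"), c("GO:C", "GO:D"), c("GO:C", "GO:B"),
                c("GO:C", "GO:E"), c("GO:A", "GO:C"), c("GO:E", "GO:B"))
  for (w in c("topology", "wang")) {
    cfg <- termSimConfig(weights = w)
    for (p in pairs) {
      expect_equal(termSimilarity(dag, p[1], p[2], cfg),
                   oracleTermSim(dag, p[1], p[2], w),
                   tolerance = 1e-12,
                   info = paste(w, p[1], p[2]))
      # symmetry
      expect_equal(termSimilarity(dag, p[1], p[2], cfg),
                   termSimilarity(dag, p[2], p[1], cfg))
    }
  }
})

test_that("hand-computed similarity of two root children is reproduced", {
  dag <- toyDag()
  # fixed Wang weights: S-values of A = {A:1, root:0.8}; same for B.
  # shared ancestor = root only: sim = (0.8+0.8)/(1.8+1.8) = 4/9
  expect_equal(termSimilarity(dag, "GO:A", "GO:B", termSimConfig("wang")),
               4 / 9, tolerance = 1e-12)
  # topology weights: root has 2 children -> w = 1/2.67 + 0.4
  w <- 1 / 2.67 + 0.4
  expect_equal(termSimilarity(dag, "GO:A", "GO:B", termSimConfig("topology")),
               2 * w / (2 * (1 + w)), tolerance = 1e-12)
})

test_that("gene-pair similarity reduces to term similarity for singletons and is 1 for identical sets", {
  dag <- toyDag()
  expect_equal(genePairSimilarity(dag, c("GO:C", "GO:D"), c("GO:C", "GO:D")), 1)
  expect_equal(genePairSimilarity(dag, "GO:A", "GO:B"),
               termSimilarity(dag, "GO:A", "GO:B"))
  expect_equal(genePairSimilarity(dag, character(), "GO:A"), NA_real_)
})

test_that("best-match average matches the exhaustive pair-matrix oracle", {
  dag <- toyDag()
  ta <- c("GO:C", "GO:E")
  tb <- c("GO:A", "GO:B", "GO:D")
  m <- outer(ta, tb, Vectorize(function(x, y) termSimilarity(dag, x, y)))
  oracle <- (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (2 + 3)
  expect_equal(genePairSimilarity(dag, ta, tb), oracle, tolerance = 1e-12)
  # symmetry
  expect_equal(genePairSimilarity(dag, tb, ta),
               genePairSimilarity(dag, ta, tb))
})

test_that("similarity stays in [0,1] and symmetric on the synthetic DAG", {
  sim <- cachedSim()
  dag <- sim$ontology$dag
  ann <- filterAnnotations(sim$ontology$annotations, dag)
  gt <- termsByGene(ann, "BPO")
  set.seed(7)
  genes <- sample(names(gt), 12)
  for (k in 1:10) {
    a <- sample(genes, 1); b <- sample(genes, 1)
    if (a == b) next
    s <- genePairSimilarity(dag, gt[[a]], gt[[b]])
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, genePairSimilarity(dag, gt[[b]], gt[[a]]))
  }
})

test_that("replacing a term by a more distant one never raises the score on a chain DAG", {
  # chain root -> c1 -> c2 -> c3 -> c4
  ids <- c("GO:0008150", paste0("GO:c", 1:4))
  parents <- c(list(data.frame(parent = character(), relation = character())),
               lapply(seq_len(4), function(i) data.frame(
                 parent = ids[i], relation = "is_a")))
  dag <- TADfunc:::.makeGoDag(ids, rep("BPO", 5), parents)
  ref <- "GO:c4"
  sims <- vapply(paste0("GO:c", 3:1), function(t)
    genePairSimilarity(dag, ref, t), numeric(1))
  expect_true(all(diff(sims) < 0))   # monotone decreasing with distance
})

test_that("OBO and GAF round-trip through the writers and readers", {
  sim <- cachedSim()
  dir <- withr::local_tempdir()
  writeObo(sim$ontology$dag, file.path(dir, "go.obo"))
  writeGaf(sim$ontology$annotations, file.path(dir, "ann.gaf"))
  dag2 <- readObo(file.path(dir, "go.obo"))
  expect_setequal(goTerms(dag2), goTerms(sim$ontology$dag))
  expect_equal(dag2@namespace[goTerms(dag2)],
               sim$ontology$dag@namespace[goTerms(dag2)])
  # parent links preserved -> same similarity values
  expect_equal(termSimilarity(dag2, goTerms(dag2)[20], goTerms(dag2)[25]),
               termSimilarity(sim$ontology$dag, goTerms(dag2)[20],
                              goTerms(dag2)[25]))
  gaf <- readGaf(file.path(dir, "ann.gaf"))
  expect_equal(nrow(gaf), nrow(sim$ontology$annotations))
  expect_equal(sort(unique(gaf$evidence)),
               sort(unique(sim$ontology$annotations$evidence)))
})

test_that("obsolete terms, alt_ids and unknown relations are handled by the OBO reader", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: bp root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000001", "name: a", "namespace: biological_process",
    "alt_id: GO:0099999", "is_a: GO:0008150 ! root", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: biological_process",
    "relationship: regulates GO:0008150", "",
    "[Term]", "id: GO:0000003", "name: dead", "namespace: biological_process",
    "is_obsolete: true", ""
  ), file.path(dir, "t.obo"))
  dag <- readObo(file.path(dir, "t.obo"))
  expect_setequal(goTerms(dag), c("GO:0008150", "GO:0000001", "GO:0000002"))
  # alt id resolves to primary
  expect_equal(termSimilarity(dag, "GO:0099999", "GO:0000001"), 1)
  # unknown relation collapsed to is_a: term 2 reaches the root
  expect_equal(dag@parents[["GO:0000002"]]$relation, "is_a")
})
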