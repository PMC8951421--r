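# Generator contracts: reproducibility, planted structure, and emitted
# file formats.

test_that("generation is reproducible from the master seed", {
  s1 <- simulateStudy(simConfig(seed = 3))
  s2 <- simulateStudy(simConfig(seed = 3))
  expect_identical(as.data.frame(s1$genome$genes), as.data.frame(s2$genome$genes))
  expect_identical(s1$ontology$annotations, s2$ontology$annotations)
  expect_identical(contactEntries(s1$contacts$raw), contactEntries(s2$contacts$raw))
  expect_identical(s1$expression, s2$expression)
  s3 <- simulateStudy(simConfig(seed = 4))
  expect_false(identical(s1$expression, s3$expression))
})

test_that("TADs are sorted, non-overlapping and domain counts honored", {
  sim <- cachedSim()
  tads <- sim$genome$tads
  expect_length(tads, simConfig()$nTads)
  s <- GenomicRanges::start(tads); e <- GenomicRanges::end(tads)
  expect_false(is.unsorted(s))
  expect_true(all(s[-1] > e[-length(e)]))  # scan oracle: no overlap
  expect_true(all(e <= simConfig()$chromLength))
  # some boundary-spanning genes exist and get excluded on assignment
  part <- assignGenes(sim$genome$genes, domainPartition(tads))
  a <- geneAssignment(part)
  expect_gt(sum(a$reason == "spans a domain boundary", na.rm = TRUE), 0)
  expect_gt(sum(a$status == "assigned"), 100)
})

test_that("every ontology term reaches its namespace root and no annotation is left on a root after filtering", {
  sim <- cachedSim()
  dag <- sim$ontology$dag
  # path oracle: walk parents to exhaustion
  for (t in sample(goTerms(dag), 25)) {
    seen <- character(); frontier <- t
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(lapply(dag@parents[frontier],
                                        function(p) p$parent)), seen)
    }
    root <- goRoots(dag)[dag@namespace[t]]
    expect_true(root %in% seen, info = t)
  }
  ann <- filterAnnotations(sim$ontology$annotations, dag)
  expect_false(any(ann$term_id %in% goRoots(dag)))
  # the raw annotations do exercise the filters
  expect_true(any(sim$ontology$annotations$evidence %in% c("IEA", "ISS")))
  expect_true(any(sim$ontology$annotations$term_id %in% goRoots(dag)))
})

test_that("genes carry their own module's terms at close to the configured rate", {
  cfg <- simConfig(seed = 12)
  genome <- makeGenome(cfg)
  ont <- makeOntologyAndAnnotations(cfg, genome)
  mods <- S4Vectors::mcols(genome$genes)$module
  inModule <- mods > 0
  hasOwn <- vapply(which(inModule), function(gi) {
    gid <- S4Vectors::mcols(genome$genes)$gene_id[gi]
    own <- ont$moduleTerms[[mods[gi]]]
    any(ont$annotations$term_id[ont$annotations$gene_id == gid] %in% own)
  }, logical(1))
  expect_equal(mean(hasOwn), cfg$pIntra, tolerance = 0.07)
})

test_that("contacts are symmetric by construction, decay with distance and are TAD-enriched", {
  sim <- cachedSim()
  e <- contactEntries(sim$contacts$raw)
  expect_true(all(e$bin1 <= e$bin2))   # canonical upper triangle
  res <- contactResolution(sim$contacts$raw)
  d <- (e$bin2 - e$bin1) / res
  # binned regression of log count on log distance has negative slope
  fit <- stats::lm(log(count) ~ log(d), data = data.frame(count = e$count, d = d)[d > 0, ])
  expect_lt(stats::coef(fit)[2], 0)
  # within-TAD mean exceeds cross-TAD mean at matched distances (5-10 bins)
  tads <- sim$genome$tads
  binTad <- rep(NA_integer_, simConfig()$chromLength / res)
  for (i in seq_along(tads)) {
    b <- seq(floor((GenomicRanges::start(tads[i]) - 1) / res),
             floor((GenomicRanges::end(tads[i]) - 1) / res))
    binTad[b + 1] <- i
  }
  t1 <- binTad[e$bin1 / res + 1]; t2 <- binTad[e$bin2 / res + 1]
  sameTad <- !is.na(t1) & !is.na(t2) & t1 == t2
  mid <- d >= 5 & d <= 10
  expect_gt(mean(e$count[mid & sameTad]), 2 * mean(e$count[mid & !sameTad]))
  # normalized map is the configured global rescaling
  en <- contactEntries(sim$contacts$norm)
  expect_equal(en$count, e$count * sim$config$normScale)
})

test_that("same-module pairs have higher expected GESS than cross-module pairs", {
  sim <- cachedSim()
  ec <- sim$expression
  expect_true(all(ec >= 0))
  real <- stats::setNames(sim$ontology$realizedModule,
                          S4Vectors::mcols(sim$genome$genes)$gene_id)
  gids <- names(real)[real > 0]
  set.seed(8)
  mx <- max(ec); mn <- min(ec)
  sameG <- c(); crossG <- c()
  while (length(sameG) < 200 || length(crossG) < 200) {
    p <- sample(gids, 2)
    g <- gess(ec[p[1]], ec[p[2]], mx, mn)
    if (real[p[1]] == real[p[2]]) sameG <- c(sameG, g) else crossG <- c(crossG, g)
  }
  expect_gt(mean(sameG), mean(crossG))
})

test_that("planted duplicate pairs are exactly the rows the filter removes", {
  sim <- cachedSim()
  idt <- sim$identity
  expect_equal(sum(idt$planted), simConfig()$nDupPairs)
  pairs <- idt[, c("geneA", "geneB")]
  kept <- filterDuplicates(pairs, idt)
  expect_equal(nrow(kept), sum(!idt$planted))
  keptKeys <- paste(kept$geneA, kept$geneB)
  expect_setequal(keptKeys, paste(idt$geneA, idt$geneB)[!idt$planted])
})

test_that("written files load back through the format readers", {
  sim <- cachedSim()
  dir <- withr::local_tempdir()
  writeSimData(sim, dir)
  tads <- readTadBed(file.path(dir, "tads.bed"))
  expect_equal(GenomicRanges::start(tads), GenomicRanges::start(sim$genome$tads))
  genes <- readGeneBed(file.path(dir, "genes.bed"))
  expect_equal(S4Vectors::mcols(genes)$gene_id,
               S4Vectors::mcols(sim$genome$genes)$gene_id)
  cm <- readContacts(file.path(dir, "contacts_raw.tsv"), "chrS", 40e3)
  expect_equal(contactEntries(cm), contactEntries(sim$contacts$raw),
               ignore_attr = TRUE)
  ec <- readExpressionTable(file.path(dir, "expression.tsv"))
  expect_equal(unname(ec), unname(sim$expression))
  idt <- readIdentityTable(file.path(dir, "identity.tsv"))
  expect_equal(nrow(idt), nrow(sim$identity))
  pw <- readGmt(file.path(dir, "pathways.gmt"))
  expect_equal(pw, sim$pathways, ignore_attr = TRUE)
})
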