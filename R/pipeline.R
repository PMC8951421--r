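# End-to-end orchestration: one config drives simulation (or file input),
# domain assignment, the intra/inter pair analysis, FSN communities, the
# spatial networks with the autoencoder repeats, neighbor-voting inference
# and long-range region detection, writing one TSV per stage. All
# randomness flows from the master seed through deriveSeed().

#' Default pipeline run configuration
#'
#' @param seed master seed.
#' @param ontology namespace used for functional similarity.
#' @param nPairs intra/inter pairs analysed per arm (downsampled to the
#'   smaller arm after duplicate filtering).
#' @param fsnThreshold FSN similarity threshold (0.5 by default; 0.7 and 1
#'   are the other settings of interest).
#' @param contactMin,distMin HiC-GGSI thresholds (raw contacts; bp).
#' @param gaeRepeats autoencoder repeats for the mean +/- CI report.
#' @param gaeDim,gaeLr,gaeEpochs autoencoder settings.
#' @param confMin reconstruction-confidence threshold for inference.
#' @param longrangeDistMin distance threshold for long-range region pairs.
#' @param strongMin,weakMax,simMin long-range thresholds.
#' @param sim a [simConfig()] for the synthetic inputs.
#' @export
runConfig <- function(seed = 1L, ontology = "BPO", nPairs = 200,
                      fsnThreshold = 0.5,
                      contactMin = 40, distMin = 800e3,
                      gaeRepeats = 10, gaeDim = 128, gaeLr = 0.001,
                      gaeEpochs = 200,
                      confMin = 0.6,
                      longrangeDistMin = 3.2e6, strongMin = 10,
                      weakMax = 0.2, simMin = 0.5,
                      sim = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim)) cfg$sim <- simConfig(seed = deriveSeed(seed, "sim"))
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [runConfig()] arguments; a `sim:` block mirrors
#' [simConfig()].
#'
#' @param path YAML path.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim
  y$sim <- NULL
  cfg <- do.call(runConfig, y)
  if (!is.null(simArgs)) cfg$sim <- do.call(simConfig, simArgs)
  cfg
}

.writeTsv <- function(d, dir, name) {
  utils::write.table(d, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis on synthetic data
#'
#' Deterministic given the config's master seed. Writes per-stage TSVs to
#' `outDir` and returns the stage results.
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created; pass `NULL` to skip writing).
#' @return list with the per-stage results (`partition`, `pairs`, `fsn`,
#'   `ggsi`, `gae`, `inference`, `longrange`).
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  sim <- simulateStudy(config$sim)
  genes <- sim$genome$genes
  dag <- sim$ontology$dag
  ann <- filterAnnotations(sim$ontology$annotations, dag)
  geneTerms <- termsByGene(ann, config$ontology)

  # domains
  partition <- assignGenes(genes, domainPartition(sim$genome$tads))
  if (!is.null(outDir)) writeAssignment(partition, file.path(outDir, "assignment.tsv"))

  # intra/inter pair analysis with duplicate filtering and re-balancing
  intra <- enumerateIntraPairs(partition, "tad")
  intra <- downsamplePairs(intra, min(nrow(intra), config$nPairs),
                           deriveSeed(config$seed, "intra"))
  inter <- sampleInterPairs(partition, "tad", nrow(intra),
                            deriveSeed(config$seed, "inter"))
  intra <- filterDuplicates(intra, sim$identity)
  inter <- filterDuplicates(inter, sim$identity)
  nBal <- min(nrow(intra), nrow(inter))
  intra <- downsamplePairs(intra, nBal, deriveSeed(config$seed, "balance", 1L))
  inter <- downsamplePairs(inter, nBal, deriveSeed(config$seed, "balance", 2L))
  intra <- genePairSimilarities(dag, intra, geneTerms)
  inter <- genePairSimilarities(dag, inter, geneTerms)
  wilcox <- compareDistributions(intra$sim[!is.na(intra$sim)],
                                 inter$sim[!is.na(inter$sim)])
  intra <- pairGess(intra, sim$expression)
  inter <- pairGess(inter, sim$expression)
  corIntra <- correlateScores(intra$sim, intra$gess)
  pairsOut <- rbind(intra[, c("geneA", "geneB", "relation", "sim", "gess")],
                    inter[, c("geneA", "geneB", "relation", "sim", "gess")])
  if (!is.null(outDir)) .writeTsv(pairsOut, outDir, "pairs.tsv")

  # FSN communities over all pairs of TAD-assigned genes with BPO terms
  a <- geneAssignment(partition)
  fsnGenes <- intersect(a$gene_id[a$status == "assigned" & a$kind == "tad"],
                        names(geneTerms))
  idx <- utils::combn(length(fsnGenes), 2)
  simTable <- genePairSimilarities(
    dag, data.frame(geneA = fsnGenes[idx[1, ]], geneB = fsnGenes[idx[2, ]],
                    stringsAsFactors = FALSE), geneTerms)
  fsn <- buildFsn(simTable, config$fsnThreshold)
  comm <- detectCommunities(fsn)
  commReport <- communityReport(comm, partition)
  rnd <- randomCommunities(fsn, commReport$size,
                           deriveSeed(config$seed, "random-communities"))
  rndRatios <- vapply(rnd, function(m)
    suppressMessages(sameTadRatio(m, partition)), numeric(1))
  if (!is.null(outDir)) {
    .writeTsv(data.frame(community_id = rep(seq_along(comm),
                                            lengths(comm)),
                         gene_id = unlist(comm)), outDir, "communities.tsv")
    .writeTsv(cbind(commReport, random_ratio = rndRatios), outDir,
              "community_ratios.tsv")
  }

  # spatial networks + autoencoder repeats
  contactTable <- genePairContacts(sim$contacts$raw, genes)
  ggsi <- buildHicGgsi(contactTable, genes, config$contactMin, config$distMin)
  tadGgsi <- buildHicTadGgsi(ggsi, partition, genes, config$distMin)
  gaeSeed <- deriveSeed(config$seed, "gae")
  resGgsi <- runGaeExperiment(ggsi, repeats = config$gaeRepeats,
                              seed = gaeSeed, dim = config$gaeDim,
                              lr = config$gaeLr, epochs = config$gaeEpochs)
  resTad <- runGaeExperiment(tadGgsi, repeats = config$gaeRepeats,
                             seed = gaeSeed, dim = config$gaeDim,
                             lr = config$gaeLr, epochs = config$gaeEpochs)
  gaeReport <- data.frame(
    network = c("HiC-GGSI", "HiC-TAD-GGSI"),
    genes = c(length(networkNodes(ggsi)), length(networkNodes(tadGgsi))),
    auc = c(resGgsi$auc$mean, resTad$auc$mean),
    auc_ci = c(resGgsi$auc$halfWidth, resTad$auc$halfWidth),
    ap = c(resGgsi$ap$mean, resTad$ap$mean),
    ap_ci = c(resGgsi$ap$halfWidth, resTad$ap$halfWidth)
  )
  if (!is.null(outDir)) {
    writeNetwork(ggsi, file.path(outDir, "hic_ggsi.tsv"))
    writeNetwork(tadGgsi, file.path(outDir, "hic_tad_ggsi.tsv"))
    .writeTsv(gaeReport, outDir, "gae_performance.tsv")
  }

  # inference on reconstructed networks (one representative split per type)
  inference <- lapply(list(ggsi = ggsi, tadGgsi = tadGgsi), function(net) {
    A <- adjacencyMatrix(net)
    split <- splitEdges(A, seed = gaeSeed)
    model <- trainGae(split, networkNodes(net), dim = config$gaeDim,
                      lr = config$gaeLr, epochs = config$gaeEpochs,
                      seed = gaeSeed)
    recon <- thresholdReconstruction(model, config$confMin)
    uni <- unionNetwork(net, recon)
    cache <- new.env(parent = emptyenv())
    vapply(list(original = net, reconstructed = recon, union = uni),
           function(nw) vapply(c(1, 4), function(k)
             tryCatch(evaluateTopK(nw, geneTerms, geneTerms, dag, k,
                                   cache = cache)$mean,
                      error = function(e) NA_real_), numeric(1)),
           numeric(2))
  })
  if (!is.null(outDir)) {
    infTab <- do.call(rbind, lapply(names(inference), function(nm) {
      m <- inference[[nm]]
      data.frame(network = nm, k = c(1, 4),
                 original = m[, "original"],
                 reconstructed = m[, "reconstructed"],
                 union = m[, "union"])
    }))
    .writeTsv(infTab, outDir, "inference_scores.tsv")
  }

  # long-range interactive regions
  regions <- classifyRegionPairs(sim$contacts$norm, config$longrangeDistMin,
                                 config$strongMin, config$weakMax)
  strong <- regions[regions$label == "strong", , drop = FALSE]
  similar <- reportSimilarPairs(strong, genes,
                                contactResolution(sim$contacts$norm),
                                dag, geneTerms, config$simMin)
  if (!is.null(outDir)) .writeTsv(similar, outDir, "longrange_similar.tsv")

  list(sim = sim, partition = partition,
       pairs = list(intra = intra, inter = inter, wilcox = wilcox,
                    corIntra = corIntra),
       fsn = list(network = fsn, communities = comm, report = commReport,
                  randomRatios = rndRatios),
       ggsi = list(ggsi = ggsi, tadGgsi = tadGgsi),
       gae = list(ggsi = resGgsi, tadGgsi = resTad, report = gaeReport),
       inference = inference,
       longrange = list(regions = regions, similar = similar))
}
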