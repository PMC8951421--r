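# Seeded generators for every input the pipeline consumes, with planted
# structure: TADs with (sometimes zero-length) gaps, genes inside domains
# plus a boundary-spanning fraction, a small GO DAG with one coherent term
# clique per functional module, module-coherent annotations, distance-decay
# Hi-C with TAD enrichment and planted long-range loops, module-correlated
# expression, and planted duplicate gene pairs.
#
# The defaults describe a desk-scale positive control: a 10 Mbp chromosome
# with 10 TADs (~0.75 Mbp each), ~300 genes, 40 kbp bins, strong within-TAD
# annotation coherence (pIntra 0.8 vs pInter 0.05) and a long-range loop
# between TADs 2 and 8 whose genes share a functional module.

#' Simulation configuration
#'
#' `pIntra` is the probability that a gene draws an annotation term from its
#' own TAD's module clique; `pInter` is the same probability for each other
#' module, so `pIntra == pInter` removes the TAD-function association
#' entirely (negative control) while `beta = 1` removes the Hi-C TAD
#' enrichment.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param chromName,chromLength chromosome label and length (bp).
#' @param resolution Hi-C bin size (bp); must divide `chromLength`.
#' @param nTads number of TADs.
#' @param tadLengthMedian,tadLengthSdlog TAD lengths are lognormal with this
#'   median (bp) and log-scale sd, giving the heavy right tail real TAD
#'   calls show (most domains near the median, a few spanning 1.5-2 Mbp);
#'   the median sits below the ~1 Mbp genome-wide average so ten TADs and
#'   their gaps fit a 10 Mbp toy chromosome, and lengths are rescaled
#'   proportionally if a draw does not fit.
#' @param zeroGapFrac fraction of inter-TAD gaps with zero length (abutting
#'   TADs), mirroring the ~54% seen in real TAD calls.
#' @param gapLengthMean mean length of non-zero gaps (bp).
#' @param genesPerTad,genesPerGap expected gene counts per domain.
#' @param boundaryGenes number of genes planted across TAD boundaries to
#'   exercise exclusion.
#' @param geneLengthRange min/max gene-body length (bp).
#' @param moduleTermCount GO terms per functional-module clique.
#' @param nBackgroundTerms unstructured leaf terms per namespace.
#' @param pIntra,pInter module-draw probabilities (see above).
#' @param termsPerGeneBackground expected background term draws per gene.
#' @param hicBase expected raw contacts between adjacent bins.
#' @param alpha distance-decay exponent (counts ~ d^-alpha).
#' @param beta within-TAD contact enrichment factor (> 1 for the positive
#'   control).
#' @param dispersion Gamma-Poisson overdispersion of raw counts (larger =
#'   closer to Poisson).
#' @param loops list of `list(tadA, tadB, strength)` long-range loops; the
#'   strength is the added expected raw count per bin pair, and the two
#'   TADs' genes share one functional module.
#' @param normScale global scaling from raw to normalized counts.
#' @param exprNoiseSd log2-scale expression noise around the module base.
#' @param nDupPairs planted duplicate gene pairs (identity > 90, e < 0.01).
#' @param nBackgroundIdentity background identity-table rows (kept by the
#'   duplicate filter).
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      chromName = "chrS", chromLength = 10e6,
                      resolution = 40e3,
                      nTads = 10, tadLengthMedian = 750e3, tadLengthSdlog = 0.4,
                      zeroGapFrac = 0.5, gapLengthMean = 120e3,
                      genesPerTad = 25, genesPerGap = 4, boundaryGenes = 8,
                      geneLengthRange = c(2e3, 40e3),
                      moduleTermCount = 5, nBackgroundTerms = 120,
                      pIntra = 0.8, pInter = 0.02,
                      termsPerGeneBackground = 1,
                      hicBase = 60, alpha = 1.0, beta = 4, dispersion = 8,
                      loops = list(list(tadA = 2, tadB = 8, strength = 60)),
                      normScale = 0.2,
                      exprNoiseSd = 1.0,
                      nDupPairs = 12, nBackgroundIdentity = 100) {
  cfg <- as.list(environment())
  if (cfg$chromLength %% cfg$resolution != 0)
    stop("config error: resolution must divide chromLength")
  if (cfg$pIntra < 0 || cfg$pIntra > 1 || cfg$pInter < 0 || cfg$pInter > 1)
    stop("config error: probabilities must be in [0, 1]")
  class(cfg) <- "SimConfig"
  cfg
}

#' Deterministic per-stage seed derived from a master seed
#'
#' Polynomial string hash of (stage, index) folded into the master seed,
#' kept below 2^31.
#'
#' @param seed master seed (integer).
#' @param stage stage name.
#' @param index repeat index (default 0).
#' @export
deriveSeed <- function(seed, stage, index = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h * 31 + index) %% 2147483647)
}

#' Generate TADs, gaps and genes
#'
#' TADs are laid left to right with a leading gap and inter-TAD gaps that
#' are zero-length with probability `zeroGapFrac`. Genes are placed fully
#' inside domains, plus `boundaryGenes` genes spanning TAD start boundaries
#' (these should be excluded by assignment). Each TAD carries a functional
#' module label; TADs joined by a configured loop share a module.
#'
#' @param config a [simConfig()].
#' @return list with `tads` (`GRanges`), `genes` (`GRanges` with `gene_id`
#'   and a generator-truth `module` column) and `moduleOfTad` (integer per
#'   TAD).
#' @export
makeGenome <- function(config) {
  set.seed(deriveSeed(config$seed, "genome"))
  n <- config$nTads
  tadLen <- pmax(config$resolution * 2,
                 round(stats::rlnorm(n, log(config$tadLengthMedian),
                                     config$tadLengthSdlog) / 1e4) * 1e4)
  gapLen <- c(
    round(stats::rexp(1, 1 / config$gapLengthMean) / 1e4) * 1e4 + 2e4,
    ifelse(stats::runif(n - 1) < config$zeroGapFrac, 0,
           round(stats::rexp(n - 1, 1 / config$gapLengthMean) / 1e4) * 1e4 + 2e4)
  )
  # rescale TADs proportionally if the draw does not fit the chromosome
  room <- config$chromLength - sum(gapLen)
  if (room <= n * 2 * config$resolution)
    stop("config error: gaps leave no room for TADs")
  if (sum(tadLen) > room)
    tadLen <- pmax(config$resolution * 2,
                   floor(tadLen * room / sum(tadLen) / 1e4) * 1e4)
  starts <- cumsum(gapLen) + c(0, cumsum(tadLen))[seq_len(n)]   # 0-based
  tads <- GenomicRanges::GRanges(
    config$chromName, IRanges::IRanges(starts + 1, starts + tadLen))

  moduleOfTad <- seq_len(n)
  for (lp in config$loops) moduleOfTad[lp$tadB] <- moduleOfTad[lp$tadA]

  placeGenes <- function(domStart0, domEnd0, count, module) {
    count <- stats::rpois(1, count)
    if (count == 0) return(NULL)
    len <- round(stats::runif(count, config$geneLengthRange[1],
                              min(config$geneLengthRange[2],
                                  (domEnd0 - domStart0) / 2)))
    s0 <- floor(stats::runif(count, domStart0, domEnd0 - len))
    data.frame(start0 = s0, end0 = s0 + len, module = module)
  }

  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <-
      placeGenes(starts[i], starts[i] + tadLen[i], config$genesPerTad,
                 moduleOfTad[i])
  }
  gapStart0 <- c(0, (starts + tadLen)[-n])
  gapEnd0 <- starts
  for (i in seq_len(n)) {
    if (gapEnd0[i] - gapStart0[i] >= 4e4)
      rows[[length(rows) + 1]] <-
        placeGenes(gapStart0[i], gapEnd0[i], config$genesPerGap, 0L)
  }
  # boundary-spanning genes across TAD start boundaries
  bIdx <- sample(seq_len(n), config$boundaryGenes, replace = TRUE)
  bLen <- round(stats::runif(config$boundaryGenes, 2e4, 6e4))
  rows[[length(rows) + 1]] <- data.frame(
    start0 = starts[bIdx] - floor(bLen / 2),
    end0 = starts[bIdx] + ceiling(bLen / 2),
    module = 0L
  )
  g <- do.call(rbind, rows)
  g <- g[g$start0 >= 0 & g$end0 <= config$chromLength, ]
  g <- g[order(g$start0, g$end0), ]
  ids <- sprintf("g%04d", seq_len(nrow(g)))
  genes <- GenomicRanges::GRanges(
    config$chromName, IRanges::IRanges(g$start0 + 1, g$end0))
  S4Vectors::mcols(genes)$gene_id <- ids
  S4Vectors::mcols(genes)$module <- g$module
  names(genes) <- ids
  list(tads = tads, genes = genes, moduleOfTad = moduleOfTad)
}

.SIM_NS <- data.frame(
  ns = c("BPO", "CCO", "MFO"),
  root = unname(.GO_ROOTS[c("BPO", "CCO", "MFO")]),
  prefix = c("GO:1", "GO:2", "GO:3"),
  stringsAsFactors = FALSE
)

#' Generate a toy GO DAG and module-coherent gene annotations
#'
#' Each namespace gets a root, branch terms and leaf terms; each functional
#' module owns a clique of `moduleTermCount` BPO leaves under a dedicated
#' branch. A gene draws a term from its own module's clique with
#' probability `pIntra` and from each other module's clique with
#' probability `pInter`, plus background terms; evidence codes mix
#' experimental and non-experimental so filtering has something to do.
#'
#' @param config a [simConfig()].
#' @param genome output of [makeGenome()].
#' @return list with `dag` ([GoDag-class]), `annotations` (raw data.frame
#'   `gene_id`, `term_id`, `evidence`, `aspect`) and `moduleTerms` (list of
#'   BPO term vectors per module).
#' @export
makeOntologyAndAnnotations <- function(config, genome) {
  set.seed(deriveSeed(config$seed, "ontology"))
  K <- max(genome$moduleOfTad)
  ids <- character(); ns <- character(); parents <- list()
  addTerm <- function(id, namespace, parentIds, relations) {
    ids <<- c(ids, id); ns <<- c(ns, namespace)
    parents[[length(parents) + 1]] <<- data.frame(
      parent = parentIds, relation = relations, stringsAsFactors = FALSE)
  }
  moduleTerms <- vector("list", K)
  leavesByNs <- list()
  for (r in seq_len(nrow(.SIM_NS))) {
    nsName <- .SIM_NS$ns[r]; root <- .SIM_NS$root[r]; pre <- .SIM_NS$prefix[r]
    addTerm(root, nsName, character(), character())
    nBranch <- if (nsName == "BPO") K + 4 else 4
    branches <- sprintf("%s0%05d", pre, seq_len(nBranch))
    for (b in branches) addTerm(b, nsName, root, "is_a")
    nLeaf <- if (nsName == "BPO") config$nBackgroundTerms else
      config$nBackgroundTerms %/% 2
    leaves <- sprintf("%s1%05d", pre, seq_len(nLeaf))
    for (i in seq_along(leaves)) {
      br <- if (nsName == "BPO") branches[K + 1 + (i %% (nBranch - K))]
            else branches[1 + (i %% nBranch)]
      rel <- if (i %% 4 == 0) "part_of" else "is_a"
      addTerm(leaves[i], nsName, br, rel)
    }
    if (nsName == "BPO") {
      # each module clique is an is_a chain under its branch (a series of
      # increasingly specific terms), so within-module term pairs are
      # semantically close and cross-module pairs share only the root
      for (m in seq_len(K)) {
        mt <- sprintf("%s2%02d%03d", pre, m, seq_len(config$moduleTermCount))
        for (ti in seq_along(mt))
          addTerm(mt[ti], "BPO", if (ti == 1) branches[m] else mt[ti - 1],
                  "is_a")
        moduleTerms[[m]] <- mt
      }
    }
    leavesByNs[[nsName]] <- leaves
  }
  dag <- .makeGoDag(ids, ns, parents)

  genes <- genome$genes
  gids <- S4Vectors::mcols(genes)$gene_id
  mods <- S4Vectors::mcols(genes)$module
  evPool <- c(.EXP_CODES, "IEA", "ISS")
  evProb <- c(rep(0.85 / 6, 6), 0.1, 0.05)
  drawEv <- function(k) sample(evPool, k, replace = TRUE, prob = evProb)
  rows <- list()
  aspectOf <- c(BPO = "P", CCO = "C", MFO = "F")
  realizedModule <- integer(length(gids))
  for (gi in seq_along(gids)) {
    terms <- character()
    for (m in seq_len(K)) {
      own <- !is.na(mods[gi]) && mods[gi] == m
      p <- if (own) config$pIntra else config$pInter
      if (stats::runif(1) < p) {
        # a module draw yields two terms of the module chain (a specific
        # term plus a related one); the draw process is identical for own
        # and background modules so pIntra == pInter removes all structure
        terms <- c(terms, sample(moduleTerms[[m]], 2))
        if (own) realizedModule[gi] <- m
      }
    }
    nBg <- 1 + stats::rpois(1, config$termsPerGeneBackground - 1)
    terms <- unique(c(terms,
                      sample(leavesByNs$BPO, min(nBg, length(leavesByNs$BPO)))))
    terms <- c(terms,
               sample(leavesByNs$CCO, 1 + stats::rpois(1, 0.5)),
               sample(leavesByNs$MFO, 1 + stats::rpois(1, 0.5)))
    if (stats::runif(1) < 0.05) terms <- c(terms, .GO_ROOTS["BPO"])
    nsOf <- dag@namespace[terms]
    rows[[gi]] <- data.frame(
      gene_id = gids[gi], term_id = unname(terms),
      evidence = drawEv(length(terms)),
      aspect = unname(aspectOf[nsOf]), stringsAsFactors = FALSE)
  }
  list(dag = dag, annotations = do.call(rbind, rows),
       moduleTerms = moduleTerms, realizedModule = realizedModule)
}

#' Generate raw and normalized Hi-C contact matrices
#'
#' Expected raw counts decay as `hicBase * d^-alpha` in bin distance d,
#' multiplied by `beta` for bin pairs inside one TAD, plus the configured
#' loop blocks; raw counts are Gamma-Poisson draws and the normalized map
#' is a global rescaling by `normScale`.
#'
#' @param config a [simConfig()].
#' @param genome output of [makeGenome()].
#' @return list with `raw` and `norm` [ContactMatrix-class] objects.
#' @export
makeContacts <- function(config, genome) {
  set.seed(deriveSeed(config$seed, "contacts"))
  res <- config$resolution
  B <- config$chromLength / res
  binOfTad <- function(tad) {
    s0 <- GenomicRanges::start(tad) - 1; e0 <- GenomicRanges::end(tad)
    seq(floor(s0 / res), floor((e0 - 1) / res))
  }
  tadBins <- lapply(seq_along(genome$tads), function(i) binOfTad(genome$tads[i]))
  binTad <- rep(NA_integer_, B)
  for (i in seq_along(tadBins)) binTad[tadBins[[i]] + 1] <- i

  idx <- which(upper.tri(matrix(0, B, B), diag = FALSE), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d <- j - i
  lambda <- config$hicBase / d^config$alpha
  sameTad <- !is.na(binTad[i]) & !is.na(binTad[j]) & binTad[i] == binTad[j]
  lambda[sameTad] <- lambda[sameTad] * config$beta
  for (lp in config$loops) {
    inLoop <- (binTad[i] %in% lp$tadA & binTad[j] %in% lp$tadB) |
              (binTad[i] %in% lp$tadB & binTad[j] %in% lp$tadA)
    inLoop[is.na(inLoop)] <- FALSE
    lambda[inLoop] <- lambda[inLoop] + lp$strength
  }
  # Gamma-Poisson: overdispersed counts, variance lambda * (1 + lambda/disp)
  shape <- config$dispersion
  mix <- stats::rgamma(length(lambda), shape = shape, rate = shape)
  counts <- stats::rpois(length(lambda), lambda * mix)
  keep <- counts > 0
  entries <- data.frame(bin1 = (i[keep] - 1) * res, bin2 = (j[keep] - 1) * res,
                        count = counts[keep])
  raw <- contactMatrix(entries, config$chromName, res, normalized = FALSE)
  normEntries <- entries
  normEntries$count <- entries$count * config$normScale
  norm <- contactMatrix(normEntries, config$chromName, res, normalized = TRUE)
  list(raw = raw, norm = norm)
}

#' Generate module-correlated mean expression counts
#'
#' Each module has a base expression level; a gene that actually carries
#' its module's annotation draws its mean count from the module base times
#' log-normal noise, while other genes get their own random base. Coupling
#' the expression to the *realized* module annotation makes functionally
#' similar pairs also expression-similar (and leaves decoupled pairs
#' behind), which is what drives a positive similarity-GESS correlation.
#'
#' @param config a [simConfig()].
#' @param genome output of [makeGenome()].
#' @param realizedModule per-gene realized module from
#'   [makeOntologyAndAnnotations()] (0 = carries no own-module term);
#'   falls back to the positional module labels when `NULL`.
#' @return named numeric vector of mean counts per gene.
#' @export
makeExpression <- function(config, genome, realizedModule = NULL) {
  set.seed(deriveSeed(config$seed, "expression"))
  K <- max(genome$moduleOfTad)
  base <- 2^stats::runif(K, 4, 10)
  gids <- S4Vectors::mcols(genome$genes)$gene_id
  mods <- if (is.null(realizedModule)) S4Vectors::mcols(genome$genes)$module
          else realizedModule
  b <- ifelse(mods > 0, base[pmax(mods, 1)], 2^stats::runif(length(gids), 4, 10))
  ec <- b * 2^stats::rnorm(length(gids), 0, config$exprNoiseSd)
  stats::setNames(ec, gids)
}

#' Generate a pairwise sequence-identity table with planted duplicates
#'
#' `nDupPairs` random gene pairs get identity > 90% and e-value < 0.01 (the
#' duplicate filter must remove them); background rows sit below both
#' cutoffs.
#'
#' @param config a [simConfig()].
#' @param genome output of [makeGenome()].
#' @return data.frame `geneA`, `geneB`, `identity`, `evalue` with a
#'   `planted` logical column (generator truth).
#' @export
makeIdentityTable <- function(config, genome) {
  set.seed(deriveSeed(config$seed, "identity"))
  gids <- S4Vectors::mcols(genome$genes)$gene_id
  nTotal <- config$nDupPairs + config$nBackgroundIdentity
  seen <- character(); a <- character(); b <- character()
  while (length(a) < nTotal) {
    i <- sample(gids, 1); j <- sample(gids, 1)
    if (i == j) next
    key <- .pairKey(i, j)
    if (key %in% seen) next
    seen <- c(seen, key); a <- c(a, min(i, j)); b <- c(b, max(i, j))
  }
  planted <- seq_len(nTotal) <= config$nDupPairs
  data.frame(
    geneA = a, geneB = b,
    identity = ifelse(planted, stats::runif(nTotal, 91, 100),
                      stats::runif(nTotal, 25, 85)),
    evalue = ifelse(planted, 10^stats::runif(nTotal, -50, -5),
                    10^stats::runif(nTotal, -1.5, 1)),
    planted = planted, stringsAsFactors = FALSE
  )
}

#' Pathway membership derived from the planted modules
#'
#' One pathway per functional module containing that module's genes (the
#' generator-truth modules), so mutual-pathway checks have signal.
#'
#' @param config a [simConfig()].
#' @param genome output of [makeGenome()].
#' @return named list pathway id -> gene ids.
#' @export
makePathways <- function(config, genome) {
  mods <- S4Vectors::mcols(genome$genes)$module
  gids <- S4Vectors::mcols(genome$genes)$gene_id
  out <- split(gids, mods)
  out <- out[names(out) != "0"]
  stats::setNames(out, paste0("PATH", names(out)))
}

#' Generate a full synthetic study
#'
#' Runs all generators off one config and returns every input the pipeline
#' consumes, in memory.
#'
#' @param config a [simConfig()].
#' @return list with `config`, `genome`, `ontology`, `contacts`,
#'   `expression`, `identity`, `pathways`.
#' @export
simulateStudy <- function(config = simConfig()) {
  genome <- makeGenome(config)
  ontology <- makeOntologyAndAnnotations(config, genome)
  list(
    config = config,
    genome = genome,
    ontology = ontology,
    contacts = makeContacts(config, genome),
    expression = makeExpression(config, genome, ontology$realizedModule),
    identity = makeIdentityTable(config, genome),
    pathways = makePathways(config, genome)
  )
}

#' Write a synthetic study to disk in the formats the readers consume
#'
#' Emits `tads.bed`, `genes.bed` (0-based half-open BED), `go.obo` (OBO
#' 1.2), `annotations.gaf` (GAF 2.2), `expression.tsv`, `identity.tsv`,
#' `contacts_raw.tsv` / `contacts_norm.tsv` (bin1, bin2, count) and
#' `pathways.gmt`.
#'
#' @param sim output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- function(gr, path, ids = NULL) {
    d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr))
    if (!is.null(ids)) d$name <- ids
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  bed(sim$genome$tads, file.path(dir, "tads.bed"))
  bed(sim$genome$genes, file.path(dir, "genes.bed"),
      S4Vectors::mcols(sim$genome$genes)$gene_id)
  writeObo(sim$ontology$dag, file.path(dir, "go.obo"))
  writeGaf(sim$ontology$annotations, file.path(dir, "annotations.gaf"))
  utils::write.table(
    data.frame(gene_id = names(sim$expression), mean_count = sim$expression),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    sim$identity[, c("geneA", "geneB", "identity", "evalue")],
    file.path(dir, "identity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeContactTsv <- function(cm, path)
    utils::write.table(contactEntries(cm), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  writeContactTsv(sim$contacts$raw, file.path(dir, "contacts_raw.tsv"))
  writeContactTsv(sim$contacts$norm, file.path(dir, "contacts_norm.tsv"))
  gmt <- vapply(names(sim$pathways), function(p)
    paste(c(p, "synthetic module pathway", sim$pathways[[p]]),
          collapse = "\t"), "")
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  invisible(dir)
}

#' Write a GoDag as OBO 1.2
#'
#' @param dag a [GoDag-class].
#' @param path output path.
#' @export
writeObo <- function(dag, path) {
  nsLong <- c(BPO = "biological_process", CCO = "cellular_component",
              MFO = "molecular_function")
  out <- c("format-version: 1.2", "")
  for (id in dag@terms) {
    p <- dag@parents[[id]]
    lines <- c("[Term]", paste0("id: ", id),
               paste0("name: term ", id),
               paste0("namespace: ", nsLong[dag@namespace[id]]))
    if (nrow(p)) {
      isa <- p$parent[p$relation == "is_a"]
      po <- p$parent[p$relation == "part_of"]
      lines <- c(lines, paste0("is_a: ", isa),
                 if (length(po)) paste0("relationship: part_of ", po))
    }
    out <- c(out, lines, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write annotations as GAF 2.2
#'
#' @param annotations data.frame `gene_id`, `term_id`, `evidence`, `aspect`.
#' @param path output path.
#' @export
writeGaf <- function(annotations, path) {
  a <- annotations
  row <- paste("SIM", a$gene_id, a$gene_id, "", a$term_id, "SIM:ref",
               a$evidence, "", a$aspect, "", "", "gene", "taxon:0000",
               "20260101", "SIM", "", "", sep = "\t")
  writeLines(c("!gaf-version: 2.2", row), path)
  invisible(path)
}
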