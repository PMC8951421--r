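# Shared fixtures: a hand-sized GO DAG with known structure, a toy domain
# partition, and a cached small synthetic study.

# DAG:  BPO root -- A, B; A -- C, D; B -- E (part_of); MFO root -- M1.
# Child counts: root 2, A 2, B 1.
toyDag <- function() {
  ids <- c("GO:0008150", "GO:A", "GO:B", "GO:C", "GO:D", "GO:E",
           "GO:0003674", "GO:M1")
  ns <- c("BPO", "BPO", "BPO", "BPO", "BPO", "BPO", "MFO", "MFO")
  parents <- list(
    data.frame(parent = character(), relation = character()),
    data.frame(parent = "GO:0008150", relation = "is_a"),
    data.frame(parent = "GO:0008150", relation = "is_a"),
    data.frame(parent = "GO:A", relation = "is_a"),
    data.frame(parent = "GO:A", relation = "is_a"),
    data.frame(parent = "GO:B", relation = "part_of"),
    data.frame(parent = character(), relation = character()),
    data.frame(parent = "GO:0003674", relation = "is_a")
  )
  TADfunc:::.makeGoDag(ids, ns, parents)
}

# independent S-value oracle: enumerate every upward path explicitly and
# take the max product of edge weights per ancestor
oracleSValues <- function(dag, term, weights = "topology") {
  edgeW <- function(parent, relation) {
    if (weights == "wang") {
      if (relation == "part_of") 0.6 else 0.8
    } else {
      nc <- max(1L, dag@children[[parent]])
      1 / (0.67 + nc) + if (relation == "part_of") 0.3 else 0.4
    }
  }
  sv <- new.env()
  recurse <- function(t, val) {
    cur <- sv[[t]]
    if (is.null(cur) || val > cur) sv[[t]] <- val
    p <- dag@parents[[t]]
    if (nrow(p)) for (k in seq_len(nrow(p)))
      recurse(p$parent[k], val * edgeW(p$parent[k], p$relation[k]))
  }
  recurse(term, 1)
  out <- unlist(as.list(sv))
  out
}

oracleTermSim <- function(dag, t1, t2, weights = "topology") {
  s1 <- oracleSValues(dag, t1, weights)
  s2 <- oracleSValues(dag, t2, weights)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

toyGRanges <- function(starts0, ends0, chrom = "chr1", ids = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts0 + 1, ends0))
  if (!is.null(ids)) {
    S4Vectors::mcols(gr)$gene_id <- ids
    names(gr) <- ids
  }
  gr
}

# Two TADs [0,100) and [150,300), derived gap [100,150); genes placed to
# exercise assignment cases.
toyPartition <- function() {
  tads <- toyGRanges(c(0, 150), c(100, 300))
  genes <- toyGRanges(
    c(10, 40, 60, 160, 200, 95, 120, 400),
    c(20, 50, 90, 170, 250, 155, 130, 450),
    ids = c("gA", "gB", "gC", "gD", "gE", "gSpan", "gGap", "gOut")
  )
  assignGenes(genes, domainPartition(tads))
}

toyPartitionGenes <- function() {
  toyGRanges(
    c(10, 40, 60, 160, 200, 95, 120, 400),
    c(20, 50, 90, 170, 250, 155, 130, 450),
    ids = c("gA", "gB", "gC", "gD", "gE", "gSpan", "gGap", "gOut")
  )
}

# cached small synthetic study shared across test files
.simCache <- new.env()
cachedSim <- function() {
  if (is.null(.simCache$sim)) .simCache$sim <- simulateStudy(simConfig(seed = 0))
  .simCache$sim
}
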