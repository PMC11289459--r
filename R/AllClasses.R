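#' @import methods
#' @importFrom stats cor qnorm pnorm plogis rbinom rnorm runif median quantile
#'   sd complete.cases p.adjust prcomp fisher.test glm.fit binomial uniroot
#'   setNames dt pt var rgamma ave
#' @importFrom utils read.delim write.table head combn
NULL

# ---- central data containers -------------------------------------------------

#' Sample-by-SNP minor-allele dosage matrix
#'
#' Dosages count copies of the effect (minor) allele, so values are 0, 1, 2 or
#' NA (missing call). Per-SNP metadata (identifier, chromosome, 1-based
#' position, effect/other allele, minor-allele frequency) travels alongside.
#'
#' @slot dosage numeric matrix, samples in rows, SNPs in columns.
#' @slot snpInfo data.frame with columns snp_id, chrom, pos, effect_allele,
#'   other_allele, maf; one row per SNP, positions sorted within chromosome.
#' @slot metadata list for provenance (simulation ground truth, QC reports).
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", snpInfo = "data.frame", metadata = "list"),
  prototype(metadata = list()))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  info <- object@snpInfo
  msg <- character()
  if (ncol(d) != nrow(info))
    msg <- c(msg, "number of SNPs in dosage and snpInfo differ")
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "maf")
  if (!all(need %in% names(info)))
    msg <- c(msg, paste("snpInfo must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(info$snp_id)) msg <- c(msg, "duplicate snp ids")
    if (!is.null(colnames(d)) && !identical(colnames(d), as.character(info$snp_id)))
      msg <- c(msg, "dosage column names do not match snpInfo$snp_id")
    if (is.unsorted(order(info$chrom, info$pos)) ||
        any(unlist(tapply(info$pos, info$chrom, is.unsorted))))
      msg <- c(msg, "positions must be sorted within chromosome")
    if (any(info$maf <= 0 | info$maf > 0.5))
      msg <- c(msg, "maf must be in (0, 0.5]")
  }
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Sample-by-CpG methylation beta-value matrix
#'
#' Beta values are per-CpG methylation fractions in [0, 1]. Probe coordinates
#' (1-based bp) are required for probe clustering and region detection.
#'
#' @slot beta numeric matrix, samples in rows, CpG probes in columns.
#' @slot probeInfo data.frame with columns probe_id, chrom, pos; positions
#'   sorted within chromosome, probe ids unique.
#' @slot metadata list for provenance.
#' @export
setClass("MethylationMatrix",
  representation(beta = "matrix", probeInfo = "data.frame", metadata = "list"),
  prototype(metadata = list()))

setValidity("MethylationMatrix", function(object) {
  b <- object@beta
  info <- object@probeInfo
  msg <- character()
  if (ncol(b) != nrow(info))
    msg <- c(msg, "number of probes in beta and probeInfo differ")
  if (!all(c("probe_id", "chrom", "pos") %in% names(info)))
    msg <- c(msg, "probeInfo must have columns probe_id, chrom, pos")
  else {
    if (anyDuplicated(info$probe_id)) msg <- c(msg, "duplicate probe ids")
    if (any(unlist(tapply(info$pos, info$chrom, is.unsorted))))
      msg <- c(msg, "probe positions must be sorted within chromosome")
  }
  v <- b[!is.na(b)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "beta values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Gene-by-sample log-scale expression matrix
#'
#' @slot exprs numeric matrix, genes in rows, samples in columns; row names
#'   are gene identifiers.
#' @slot metadata list for provenance.
#' @export
setClass("ExpressionMatrix",
  representation(exprs = "matrix", metadata = "list"),
  prototype(metadata = list()))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (is.null(rownames(object@exprs))) msg <- c(msg, "exprs must have gene row names")
  else if (anyDuplicated(rownames(object@exprs))) msg <- c(msg, "duplicate gene ids")
  if (length(msg)) msg else TRUE
})

#' Per-sample phenotype and covariate table
#'
#' Holds the disease-course label (e.g. PPMS / BOMS / HC) and the covariates
#' the models adjust for: age, sex, smoking, batch, cell-fraction PCs and
#' ancestry PCs.
#'
#' @slot data data.frame with at least sample_id and group columns.
#' @slot metadata list for provenance.
#' @export
setClass("PhenotypeTable",
  representation(data = "data.frame", metadata = "list"),
  prototype(metadata = list()))

setValidity("PhenotypeTable", function(object) {
  msg <- character()
  if (!all(c("sample_id", "group") %in% names(object@data)))
    msg <- c(msg, "phenotype table needs sample_id and group columns")
  else if (anyDuplicated(object@data$sample_id))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

# ---- derived structures ------------------------------------------------------

#' Linkage-disequilibrium block partition
#'
#' Greedy significance-seeded clumping assigns every SNP to exactly one block;
#' each member has r-squared above the threshold with its block seed.
#'
#' @slot blocks named list of character vectors (member snp ids), names are
#'   the seed snp ids.
#' @slot r2Threshold squared-correlation threshold used for clumping.
#' @export
setClass("LDBlockSet",
  representation(blocks = "list", r2Threshold = "numeric"))

setValidity("LDBlockSet", function(object) {
  all_ids <- unlist(object@blocks, use.names = FALSE)
  msg <- character()
  if (anyDuplicated(all_ids)) msg <- c(msg, "blocks must be disjoint")
  if (any(lengths(object@blocks) == 0L)) msg <- c(msg, "empty block")
  if (!all(names(object@blocks) %in% all_ids))
    msg <- c(msg, "every seed must be a member of its block")
  if (length(msg)) msg else TRUE
})

#' Gene-gene correlation network
#'
#' Edges are unordered gene pairs with Spearman rho, an empirical permutation
#' p-value and a Benjamini-Hochberg q-value.
#'
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns node_a, node_b, rho, p, q.
#' @export
setClass("CorrelationNetwork",
  representation(nodes = "character", edges = "data.frame"))

setValidity("CorrelationNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("node_a", "node_b", "rho") %in% names(e)))
    msg <- c(msg, "edges need node_a, node_b, rho columns")
  else {
    if (any(e$node_a == e$node_b)) msg <- c(msg, "self-edges are not allowed")
    if (nrow(e) && (min(e$rho) < -1 || max(e$rho) > 1))
      msg <- c(msg, "rho must lie in [-1, 1]")
    key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    if (!all(c(e$node_a, e$node_b) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Planar maximally filtered graph
#'
#' The densest planar subgraph reachable by inserting edges in decreasing
#' |rho| order; carries at most 3(n - 2) edges.
#'
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns node_a, node_b, rho, weight (|rho|).
#' @export
setClass("PMFG",
  representation(nodes = "character", edges = "data.frame"))

setValidity("PMFG", function(object) {
  n <- length(object@nodes)
  m <- nrow(object@edges)
  msg <- character()
  if (n >= 3 && m > 3 * (n - 2)) msg <- c(msg, "more than 3(n - 2) edges")
  idx <- cbind(match(object@edges$node_a, object@nodes),
               match(object@edges$node_b, object@nodes))
  if (anyNA(idx)) msg <- c(msg, "edge endpoints must be listed nodes")
  else if (!isPlanar(idx, n)) msg <- c(msg, "graph is not planar")
  if (length(msg)) msg else TRUE
})

#' Nested module hierarchy over a network
#'
#' Produced by recursive silhouette-guided k-medoids on shortest-path
#' distances. Leaf modules partition the clustered nodes; internal nodes
#' retain the multiscale structure.
#'
#' @slot nodes data.frame with columns id, parent (NA for the root), size,
#'   silhouette (NA where no split was attempted), leaf (logical).
#' @slot members named list mapping module id to its gene ids.
#' @export
setClass("ModuleTree",
  representation(nodes = "data.frame", members = "list"))

setValidity("ModuleTree", function(object) {
  nd <- object@nodes
  msg <- character()
  if (!all(c("id", "parent", "size", "leaf") %in% names(nd)))
    msg <- c(msg, "nodes needs id, parent, size, leaf columns")
  leaves <- nd$id[nd$leaf]
  leaf_members <- unlist(object@members[leaves], use.names = FALSE)
  root <- nd$id[is.na(nd$parent)]
  if (length(root) < 1) msg <- c(msg, "no root module")
  else {
    universe <- sort(unique(unlist(object@members[root], use.names = FALSE)))
    if (anyDuplicated(leaf_members))
      msg <- c(msg, "leaf modules overlap")
    if (!identical(sort(leaf_members), universe))
      msg <- c(msg, "leaf modules do not cover all clustered nodes")
  }
  if (length(msg)) msg else TRUE
})
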