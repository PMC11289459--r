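# Constructors, accessors and show methods for the data containers.

#' Construct a GenotypeMatrix
#'
#' @param dosage samples x SNPs matrix of minor-allele dosages (0/1/2/NA).
#' @param snpInfo data.frame with snp_id, chrom, pos, effect_allele,
#'   other_allele, maf.
#' @param metadata optional provenance list.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosage, snpInfo, metadata = list()) {
  dosage <- as.matrix(dosage)
  colnames(dosage) <- as.character(snpInfo$snp_id)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("sample_%03d", seq_len(nrow(dosage)))
  new("GenotypeMatrix", dosage = dosage, snpInfo = as.data.frame(snpInfo),
      metadata = metadata)
}

#' Construct a MethylationMatrix
#' @param beta samples x CpGs matrix of beta values in [0, 1].
#' @param probeInfo data.frame with probe_id, chrom, pos.
#' @param metadata optional provenance list.
#' @return A [MethylationMatrix-class] object.
#' @export
MethylationMatrix <- function(beta, probeInfo, metadata = list()) {
  beta <- as.matrix(beta)
  colnames(beta) <- as.character(probeInfo$probe_id)
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("sample_%03d", seq_len(nrow(beta)))
  new("MethylationMatrix", beta = beta, probeInfo = as.data.frame(probeInfo),
      metadata = metadata)
}

#' Construct an ExpressionMatrix
#' @param exprs genes x samples matrix of log-scale expression with gene row
#'   names.
#' @param metadata optional provenance list.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(exprs, metadata = list()) {
  exprs <- as.matrix(exprs)
  if (is.null(colnames(exprs)))
    colnames(exprs) <- sprintf("sample_%03d", seq_len(ncol(exprs)))
  new("ExpressionMatrix", exprs = exprs, metadata = metadata)
}

#' Construct a PhenotypeTable
#' @param data data.frame with at least sample_id and group.
#' @param metadata optional provenance list.
#' @return A [PhenotypeTable-class] object.
#' @export
PhenotypeTable <- function(data, metadata = list()) {
  new("PhenotypeTable", data = as.data.frame(data), metadata = metadata)
}

#' @rdname GenotypeMatrix
#' @param x object to extract from.
#' @export
dosages <- function(x) x@dosage

#' @rdname GenotypeMatrix
#' @export
snpInfo <- function(x) x@snpInfo

#' @rdname MethylationMatrix
#' @param x object to extract from.
#' @export
betaValues <- function(x) x@beta

#' @rdname MethylationMatrix
#' @export
probeInfo <- function(x) x@probeInfo

#' @rdname ExpressionMatrix
#' @param x object to extract from.
#' @export
exprValues <- function(x) x@exprs

#' @rdname PhenotypeTable
#' @param x object to extract from.
#' @export
phenoData <- function(x) x@data

#' Sample identifiers of a data container
#' @param x a GenotypeMatrix, MethylationMatrix, ExpressionMatrix or
#'   PhenotypeTable.
#' @return character vector of sample ids.
#' @export
sampleIds <- function(x) {
  if (is(x, "GenotypeMatrix")) rownames(x@dosage)
  else if (is(x, "MethylationMatrix")) rownames(x@beta)
  else if (is(x, "ExpressionMatrix")) colnames(x@exprs)
  else if (is(x, "PhenotypeTable")) as.character(x@data$sample_id)
  else stop("no sample ids for this class")
}

#' Provenance metadata of a container
#' @param x a container with a metadata slot.
#' @return the metadata list.
#' @export
simMetadata <- function(x) x@metadata

#' Subset a GenotypeMatrix by samples and/or SNPs
#' @param x GenotypeMatrix.
#' @param i sample index (logical, integer or names).
#' @param j SNP index (logical, integer, names or snp ids).
#' @param ... ignored.
#' @param drop ignored; the class is always preserved.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  if (is.character(j)) j <- match(j, x@snpInfo$snp_id)
  GenotypeMatrix(x@dosage[i, j, drop = FALSE],
                 x@snpInfo[j, , drop = FALSE],
                 metadata = x@metadata)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "SNPs\n")
  cat("  missing calls:", sum(is.na(object@dosage)), "\n")
  cat("  chromosomes:", paste(unique(object@snpInfo$chrom), collapse = ", "), "\n")
})

setMethod("show", "MethylationMatrix", function(object) {
  cat("MethylationMatrix:", nrow(object@beta), "samples x",
      ncol(object@beta), "CpG probes\n")
  rng <- range(object@beta, na.rm = TRUE)
  cat(sprintf("  beta range: %.3f-%.3f\n", rng[1], rng[2]))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object@exprs), "genes x",
      ncol(object@exprs), "samples (log scale)\n")
})

setMethod("show", "PhenotypeTable", function(object) {
  cat("PhenotypeTable:", nrow(object@data), "samples\n")
  print(table(object@data$group))
})

setMethod("show", "LDBlockSet", function(object) {
  cat("LDBlockSet:", length(object@blocks), "blocks over",
      length(unlist(object@blocks)), "SNPs (r2 >", object@r2Threshold, ")\n")
})

#' @rdname LDBlockSet
#' @param x an LDBlockSet.
#' @export
ldBlocks <- function(x) x@blocks

#' Number of LD blocks
#' @param x an LDBlockSet.
#' @export
nBlocks <- function(x) length(x@blocks)

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork:", length(object@nodes), "genes,",
      nrow(object@edges), "edges\n")
})

#' @rdname CorrelationNetwork
#' @param x a CorrelationNetwork or PMFG.
#' @export
networkEdges <- function(x) x@edges

#' @rdname CorrelationNetwork
#' @export
networkNodes <- function(x) x@nodes

setMethod("show", "PMFG", function(object) {
  n <- length(object@nodes)
  cat("PMFG:", n, "nodes,", nrow(object@edges), "edges (max",
      max(0L, 3L * (n - 2L)), ")\n")
})

setMethod("show", "ModuleTree", function(object) {
  nd <- object@nodes
  cat("ModuleTree:", sum(nd$leaf), "leaf modules,", nrow(nd),
      "modules in total\n")
  cat("  leaf sizes:", paste(sort(nd$size[nd$leaf], decreasing = TRUE),
                             collapse = " "), "\n")
})

#' Leaf-module membership of a ModuleTree
#' @param x a ModuleTree.
#' @return named character vector mapping each clustered node to its leaf
#'   module id.
#' @export
leafModules <- function(x) {
  leaves <- x@nodes$id[x@nodes$leaf]
  out <- rep(leaves, times = lengths(x@members[leaves]))
  names(out) <- unlist(x@members[leaves], use.names = FALSE)
  out
}

#' All modules of a ModuleTree
#' @param x a ModuleTree.
#' @return the named member list (module id -> gene ids).
#' @export
moduleMembers <- function(x) x@members
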