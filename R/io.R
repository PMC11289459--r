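# Readers and writers for the TSV interchange formats (plus a minimal
# biallelic-GT VCF reader) with domain validation, and the BED exporter for
# detected regions.

#' Read a methylation beta matrix from TSV
#'
#' Expects probes in rows (row-id column `probe_id`, then chrom and pos) and
#' samples in columns; beta values outside [0, 1] are rejected with the
#' offending probe and sample named.
#'
#' @param path matrix TSV (probe_id, chrom, pos, one column per sample).
#' @return a [MethylationMatrix-class].
#' @export
readMethylation <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("malformed methylation TSV: need columns ", paste(need, collapse = ", "))
  samples <- setdiff(names(df), need)
  b <- t(as.matrix(df[, samples, drop = FALSE]))
  colnames(b) <- df$probe_id
  bad <- which(b < 0 | b > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value %g out of [0,1] at probe '%s', sample '%s'",
                 b[bad[1, 1], bad[1, 2]], colnames(b)[bad[1, 2]],
                 rownames(b)[bad[1, 1]]))
  MethylationMatrix(b, df[, need], metadata = list(source = path))
}

#' Write a methylation matrix as TSV
#' @param meth a [MethylationMatrix-class].
#' @param path output file.
#' @param header optional comment lines (written prefixed with '# ').
#' @export
writeMethylation <- function(meth, path, header = character()) {
  df <- cbind(probeInfo(meth)[c("probe_id", "chrom", "pos")],
              as.data.frame(t(betaValues(meth)), check.names = FALSE))
  .writeTsv(df, path, header)
}

#' Read an expression matrix from TSV (genes in rows, `gene_id` first column)
#' @param path expression TSV.
#' @return an [ExpressionMatrix-class].
#' @export
readExpression <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "gene_id") stop("malformed expression TSV: first column must be gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  ExpressionMatrix(m, metadata = list(source = path))
}

#' Write an expression matrix as TSV
#' @param expr an [ExpressionMatrix-class].
#' @param path output file.
#' @param header optional comment lines.
#' @export
writeExpression <- function(expr, path, header = character()) {
  df <- cbind(data.frame(gene_id = rownames(exprValues(expr))),
              as.data.frame(exprValues(expr), check.names = FALSE))
  .writeTsv(df, path, header)
}

#' Read a phenotype/covariate table from TSV
#' @param path phenotype TSV (needs sample_id and group columns).
#' @return a [PhenotypeTable-class].
#' @export
readPhenotype <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  PhenotypeTable(df, metadata = list(source = path))
}

#' Write a phenotype table as TSV
#' @param pheno a [PhenotypeTable-class].
#' @param path output file.
#' @param header optional comment lines.
#' @export
writePhenotype <- function(pheno, path, header = character()) {
  .writeTsv(phenoData(pheno), path, header)
}

#' Read genotypes from dosage TSV or minimal VCF
#'
#' The TSV dialect has one row per SNP with columns snp_id, chrom, pos,
#' effect_allele, other_allele (optionally maf) followed by one dosage column
#' per sample; dosages must be 0, 1, 2 or NA. The VCF path accepts a
#' biallelic GT-only VCF: "0/0", "0/1", "1/1" (or phased) map to dosages
#' 0/1/2 of the ALT allele and "./." to missing.
#'
#' @param path input file.
#' @param format "tsv" or "vcf"; guessed from the extension by default.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") return(.readVcfDosage(path))
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(need %in% names(df)))
    stop("malformed dosage TSV: need columns ", paste(need, collapse = ", "))
  meta_cols <- intersect(c(need, "maf", "block"), names(df))
  samples <- setdiff(names(df), meta_cols)
  d <- t(as.matrix(df[, samples, drop = FALSE]))
  colnames(d) <- df$snp_id
  bad <- which(!is.na(d) & !(d %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("dosage %g not in {0,1,2,NA} at SNP '%s', sample '%s'",
                 d[bad[1, 1], bad[1, 2]], colnames(d)[bad[1, 2]],
                 rownames(d)[bad[1, 1]]))
  info <- df[, meta_cols, drop = FALSE]
  if (!"maf" %in% names(info)) {
    af <- colMeans(d, na.rm = TRUE) / 2
    info$maf <- pmax(pmin(af, 1 - af), 1e-6)
  }
  GenotypeMatrix(d, info, metadata = list(source = path))
}

.readVcfDosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  }
  d <- t(apply(gt, c(1, 2), alt_count))   # samples x SNPs
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- colMeans(d, na.rm = TRUE) / 2
  info <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                     pos = as.numeric(fix$POS),
                     effect_allele = fix$ALT, other_allele = fix$REF,
                     maf = pmax(pmin(af, 1 - af), 1e-6),
                     stringsAsFactors = FALSE)
  GenotypeMatrix(d, info, metadata = list(source = path))
}

#' Write genotypes as a dosage TSV (VCF-like SNP metadata, one row per SNP)
#' @param geno a [GenotypeMatrix-class].
#' @param path output file.
#' @param header optional comment lines.
#' @export
writeGenotypes <- function(geno, path, header = character()) {
  df <- cbind(snpInfo(geno)[c("snp_id", "chrom", "pos", "effect_allele",
                              "other_allele", "maf")],
              as.data.frame(t(dosages(geno)), check.names = FALSE))
  .writeTsv(df, path, header)
}

.writeTsv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export detected regions as a BED file
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' start = first probe position - 1 and end = last probe position. The score
#' column is -log10(fwer_p) capped at `scoreCap`. Lines are sorted by
#' (chrom, start). Every region must span at least 2 probes.
#'
#' @param dmrs GRanges from [dmrScan()].
#' @param path output BED path.
#' @param scoreCap score cap (default 100).
#' @export
writeRegionsBed <- function(dmrs, path, scoreCap = 100) {
  stopifnot(all(dmrs$n_probes >= 2))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dmrs)),
    start = GenomicRanges::start(dmrs) - 1L,
    end = GenomicRanges::end(dmrs),
    name = sprintf("dmr_%d", seq_along(dmrs)),
    score = pmin(scoreCap, round(-log10(dmrs$fwer_p), 3)))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
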