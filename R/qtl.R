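# meQTL/eQTL scanning with additive dosage linear models, genomic window
# selection, and the three-layer direction-of-effect concordance triage
# (disease risk x methylation x expression).

#' Additive-dosage QTL scan
#'
#' For each SNP-feature pair, ordinary least squares of the feature (CpG beta
#' or gene expression) on minor-allele dosage plus covariates; the reported
#' beta is the effect per minor-allele copy. Multiple testing is adjusted
#' over the number of tests actually performed in the scan (Bonferroni by
#' default, Benjamini-Hochberg optionally), or per feature when
#' \code{perFeature}.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param features a [MethylationMatrix-class], an [ExpressionMatrix-class],
#'   or a samples x features matrix.
#' @param covariates optional samples x covariates numeric matrix.
#' @param pairs optional data.frame (snp, feature) of pairs to test, by id or
#'   index; default tests all SNP x feature combinations.
#' @param adjust "bonferroni" (default) or "BH".
#' @param perFeature adjust within each feature instead of over the whole
#'   scan.
#' @return data.frame: snp_id, feature_id, beta, se, t, p, p_adj, n.
#' @export
linearQtlScan <- function(geno, features, covariates = NULL, pairs = NULL,
                          adjust = c("bonferroni", "BH"), perFeature = FALSE) {
  adjust <- match.arg(adjust)
  d <- dosages(geno)
  F <- if (is(features, "MethylationMatrix")) betaValues(features)
       else if (is(features, "ExpressionMatrix")) t(exprValues(features))
       else as.matrix(features)
  if (nrow(F) != nrow(d)) stop("features and genotypes must share samples")
  snp_ids <- snpInfo(geno)$snp_id
  feat_ids <- colnames(F)
  if (is.null(pairs)) {
    pairs <- expand.grid(snp = snp_ids, feature = feat_ids,
                         stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(
      snp = if (is.numeric(pairs$snp)) snp_ids[pairs$snp] else as.character(pairs$snp),
      feature = if (is.numeric(pairs$feature)) feat_ids[pairs$feature]
                else as.character(pairs$feature),
      stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0) stop("no SNP-feature pairs to test")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    x <- d[, match(pairs$snp[k], snp_ids)]
    y <- F[, match(pairs$feature[k], feat_ids)]
    ok <- !is.na(x) & !is.na(y)
    X <- cbind(1, x[ok], if (!is.null(C)) C[ok, , drop = FALSE])
    fit <- .olsScan(X, matrix(y[ok], ncol = 1), which = 2L)
    data.frame(snp_id = pairs$snp[k], feature_id = pairs$feature[k],
               beta = fit$coef, se = fit$se, t = fit$t, p = fit$p,
               n = sum(ok), stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, res)
  if (perFeature) {
    res$p_adj <- ave(res$p, res$feature_id,
                     FUN = function(p) p.adjust(p, method = adjust))
  } else {
    res$p_adj <- p.adjust(res$p, method = adjust)
  }
  res
}

#' Select SNPs in a window around a region
#'
#' Keeps SNPs whose position lies in [start - flank, end + flank], inclusive
#' on both bounds, on the region's chromosome.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param chrom,start,end the center region (1-based inclusive).
#' @param flank window half-width in bp (default 500 kb).
#' @return the subsetted [GenotypeMatrix-class] (possibly with zero SNPs).
#' @export
selectWindow <- function(geno, chrom, start, end, flank = 5e5) {
  info <- snpInfo(geno)
  keep <- info$chrom == chrom & info$pos >= start - flank &
    info$pos <= end + flank
  geno[, which(keep)]
}

#' Direction-of-effect concordance triage
#'
#' Classifies each SNP (and optionally each LD block through its seed SNP) by
#' the joint directions of its disease association (risk OR > 1 vs protective
#' OR < 1), its methylation-QTL effect sign and its expression-QTL effect
#' sign per gene. The canonical repressive pattern -- risk allele, higher
#' methylation, lower expression -- is labelled "concordant-repressive"; the
#' mirrored protective pattern "concordant-protective"; complete but
#' non-matching patterns "discordant"; any missing or non-significant layer
#' gives "incomplete". Labels depend on signs and significance only, never on
#' effect magnitudes.
#'
#' @param assoc data.frame from [logisticAssoc()] (snp_id, or, p).
#' @param meqtl data.frame from [linearQtlScan()] on methylation (snp_id,
#'   beta, and p_adj or p).
#' @param eqtl external expression-QTL records: data.frame with snp_id,
#'   gene, effect (sign or normalized effect score) and optionally a logical
#'   `significant` column.
#' @param blocks optional [LDBlockSet-class]; when given, block-level rows
#'   (one per seed SNP) are appended with block ids.
#' @param alphaAssoc,alphaQtl significance thresholds for the disease and QTL
#'   layers.
#' @return list with `records` (one row per SNP x gene: directions and label)
#'   and `summary` (counts per label).
#' @export
concordanceTriage <- function(assoc, meqtl, eqtl, blocks = NULL,
                              alphaAssoc = 0.05, alphaQtl = 0.05) {
  dir_disease <- function(sid) {
    i <- match(sid, assoc$snp_id)
    if (is.na(i) || is.na(assoc$p[i]) || assoc$p[i] >= alphaAssoc) return(NA_character_)
    if (assoc$or[i] > 1) "risk" else if (assoc$or[i] < 1) "protective" else NA_character_
  }
  mp <- if ("p_adj" %in% names(meqtl)) meqtl$p_adj else meqtl$p
  dir_meqtl <- function(sid) {
    i <- match(sid, meqtl$snp_id)
    if (is.na(i) || is.na(mp[i]) || mp[i] >= alphaQtl) return(NA_character_)
    if (meqtl$beta[i] > 0) "+" else if (meqtl$beta[i] < 0) "-" else NA_character_
  }
  esig <- if ("significant" %in% names(eqtl)) eqtl$significant else
    rep(TRUE, nrow(eqtl))
  label_of <- function(dd, dm, de) {
    if (is.na(dd) || is.na(dm) || is.na(de)) return("incomplete")
    if (dd == "risk" && dm == "+" && de == "-") return("concordant-repressive")
    if (dd == "protective" && dm == "-" && de == "+") return("concordant-protective")
    "discordant"
  }
  snps <- unique(c(assoc$snp_id, meqtl$snp_id, eqtl$snp_id))
  rec <- list()
  for (sid in snps) {
    dd <- dir_disease(sid)
    dm <- dir_meqtl(sid)
    rows <- which(eqtl$snp_id == sid)
    if (length(rows) == 0) {
      rec[[length(rec) + 1]] <- data.frame(
        snp_id = sid, gene = NA_character_, disease = dd, meqtl = dm,
        eqtl = NA_character_, label = label_of(dd, dm, NA_character_),
        stringsAsFactors = FALSE)
    } else {
      for (r in rows) {
        de <- if (!esig[r] || is.na(eqtl$effect[r]) || eqtl$effect[r] == 0)
          NA_character_ else if (eqtl$effect[r] > 0) "+" else "-"
        rec[[length(rec) + 1]] <- data.frame(
          snp_id = sid, gene = eqtl$gene[r], disease = dd, meqtl = dm,
          eqtl = de, label = label_of(dd, dm, de), stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rec)
  if (!is.null(blocks)) {
    seeds <- names(ldBlocks(blocks))
    brec <- records[records$snp_id %in% seeds, , drop = FALSE]
    if (nrow(brec)) {
      brec$block <- match(brec$snp_id, seeds)
      records$block <- match(records$snp_id, seeds)
      attr(records, "blockRecords") <- brec
    }
  }
  list(records = records,
       summary = as.data.frame(table(label = records$label),
                               stringsAsFactors = FALSE))
}
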