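# Genotype QC, case-control logistic association, LD computation and
# significance-seeded block clumping, block-wise Bonferroni thresholds, and
# inverse-variance meta-analysis of odds ratios.

#' Filter SNPs by genotyping call rate
#'
#' Removes SNPs whose fraction of non-missing calls is below \code{minRate}
#' (default 0.98, i.e. excluding SNPs with less than 98\% genotyping rate).
#'
#' @param geno a [GenotypeMatrix-class].
#' @param minRate minimum non-missing fraction.
#' @return the filtered [GenotypeMatrix-class]; the exclusion report (snp_id,
#'   call_rate) is stored in \code{simMetadata(x)$callRateExclusions}.
#' @export
filterCallRate <- function(geno, minRate = 0.98) {
  d <- dosages(geno)
  rate <- colMeans(!is.na(d))
  drop <- rate < minRate
  report <- data.frame(snp_id = snpInfo(geno)$snp_id[drop],
                       call_rate = rate[drop], row.names = NULL)
  out <- geno[, which(!drop)]
  out@metadata$callRateExclusions <- report
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test conditional on the allele counts: the p-value is the summed
#' probability of all heterozygote counts (with the observed allele totals)
#' that are no more probable than the observed one.
#'
#' @param nAA,nAa,naa genotype counts (major homozygote, heterozygote, minor
#'   homozygote).
#' @return list with p.value, the observed heterozygote count, and a
#'   monomorphic flag (monomorphic SNPs return p = 1 by convention).
#' @examples
#' hweExactTest(50, 0, 50)$p.value    # extreme departure, ~1e-29
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("no genotypes")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0)
    return(list(p.value = 1, het = nAa, monomorphic = TRUE))
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | allele counts) up to a common constant
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- (n - h - hom_rare)
    h * log(2) - lfactorial(hom_rare) - lfactorial(h) - lfactorial(hom_common)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  list(p.value = min(1, sum(pr[pr <= obs * (1 + 1e-9)])), het = nAa,
       monomorphic = FALSE)
}

#' Per-SNP case-control logistic association
#'
#' Fits, for every SNP, a logistic regression of case status on minor-allele
#' dosage plus covariates (iteratively reweighted least squares via
#' \code{glm.fit}). Non-converged fits, including separated ones, are flagged
#' and their estimates withheld.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param phenotype binary vector (1 = case), one per genotype sample, or a
#'   [PhenotypeTable-class] together with `case`.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @param case,ref group labels used when `phenotype` is a PhenotypeTable.
#' @return data.frame (one row per SNP): snp_id, beta, se, or, z, p, n_cases,
#'   n_controls, converged.
#' @export
logisticAssoc <- function(geno, phenotype, covariates = NULL,
                          case = "PPMS", ref = "BOMS") {
  d <- dosages(geno)
  if (is(phenotype, "PhenotypeTable")) {
    pd <- phenoData(phenotype)
    keep <- pd$group %in% c(case, ref)
    y <- as.numeric(pd$group[keep] == case)
    d <- d[keep, , drop = FALSE]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  } else {
    y <- as.numeric(phenotype)
  }
  if (length(unique(y)) < 2) stop("phenotype is constant")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  info <- snpInfo(geno)
  out <- lapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    ok <- !is.na(x)
    Xj <- cbind(intercept = 1, dosage = x[ok],
                if (!is.null(C)) C[ok, , drop = FALSE])
    yj <- y[ok]
    fit <- suppressWarnings(glm.fit(Xj, yj, family = binomial()))
    cf <- fit$coefficients
    # Wald covariance (X'WX)^-1 at the converged IRLS weights
    cov <- tryCatch(solve(crossprod(Xj * sqrt(fit$weights))),
                    error = function(e) NULL)
    se <- if (is.null(cov)) NA_real_ else sqrt(diag(cov))[2L]
    b <- cf[2L]
    conv <- isTRUE(fit$converged) && !is.null(cov) && is.finite(se) &&
      abs(b) < 15 && se < 15
    if (!conv) {
      b <- NA_real_; se <- NA_real_
    }
    z <- b / se
    data.frame(snp_id = info$snp_id[j], beta = b, se = se, or = exp(b),
               z = z, p = 2 * pnorm(-abs(z)),
               n_cases = sum(yj == 1), n_controls = sum(yj == 0),
               converged = conv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Squared dosage correlation between two SNPs
#'
#' Pearson r-squared over pairwise-complete samples; undefined (NA) when
#' fewer than 2 complete pairs remain or either SNP is monomorphic in the
#' overlap.
#'
#' @param x,y dosage vectors.
#' @return r-squared in [0, 1], or NA.
#' @export
ldR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Pairwise r-squared matrix of a GenotypeMatrix
#' @param geno a [GenotypeMatrix-class].
#' @return symmetric matrix of squared correlations (NA where undefined).
#' @export
ldMatrix <- function(geno) {
  suppressWarnings(cor(dosages(geno), use = "pairwise.complete.obs")^2)
}

#' Greedy significance-seeded LD block clumping
#'
#' Repeatedly takes the most significant unassigned SNP as a block seed and
#' assigns to its block every unassigned SNP with r-squared above the
#' threshold against the seed. Ties in significance are broken by
#' (chromosome, position, snp id).
#'
#' @param geno a [GenotypeMatrix-class].
#' @param assoc association results (data.frame with snp_id and p) used for
#'   seeding order.
#' @param r2Threshold clumping threshold (default 0.8).
#' @return an [LDBlockSet-class].
#' @export
clusterLdBlocks <- function(geno, assoc, r2Threshold = 0.8) {
  info <- snpInfo(geno)
  p <- assoc$p[match(info$snp_id, assoc$snp_id)]
  p[is.na(p)] <- Inf
  ord <- order(p, info$chrom, info$pos, info$snp_id)
  r2 <- ldMatrix(geno)
  assigned <- rep(FALSE, nrow(info))
  blocks <- list()
  for (i in ord) {
    if (assigned[i]) next
    members <- which(!assigned & !is.na(r2[i, ]) & r2[i, ] > r2Threshold)
    members <- union(i, members)
    assigned[members] <- TRUE
    blocks[[info$snp_id[i]]] <- info$snp_id[members]
  }
  new("LDBlockSet", blocks = blocks, r2Threshold = r2Threshold)
}

#' Block-wise Bonferroni threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param nBlocks number of LD blocks (or an [LDBlockSet-class]).
#' @return list with `threshold` (full precision) and `threshold2sf`
#'   (2 significant figures).
#' @examples
#' bonferroniByBlocks(0.05, 69)$threshold2sf   # 7.2e-4
#' @export
bonferroniByBlocks <- function(alpha = 0.05, nBlocks) {
  if (is(nBlocks, "LDBlockSet")) nBlocks <- length(nBlocks@blocks)
  if (nBlocks < 1) stop("nBlocks must be >= 1")
  thr <- alpha / nBlocks
  list(threshold = thr, threshold2sf = signif(thr, 2))
}

#' Reconstruct the standard error of a log odds ratio from OR and p
#'
#' Inverts the two-sided Wald test: SE = |ln OR| / qnorm(1 - p/2). Used to
#' meta-analyse published per-cohort odds ratios and p-values.
#'
#' @param or odds ratio(s), positive and different from 1.
#' @param p two-sided p-value(s) in (0, 1).
#' @return standard error(s) of log(or).
#' @examples
#' seFromOrP(2.03, 0.0005)   # ~0.203
#' @export
seFromOrP <- function(or, p) {
  if (any(or <= 0)) stop("OR must be > 0")
  if (any(or == 1)) stop("OR = 1: z is undefined, SE cannot be reconstructed")
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  abs(log(or)) / qnorm(1 - p / 2)
}

#' Inverse-variance meta-analysis of log odds ratios
#'
#' Fixed-effect pooling with weights 1/SE^2; the random-effects model adds
#' the DerSimonian-Laird between-study variance. Cochran's Q and I-squared
#' are always reported.
#'
#' @param logOR per-study log odds ratios.
#' @param se per-study standard errors (> 0).
#' @param model "fixed" (default) or "random".
#' @return one-row data.frame: k, logOR, se, or, z, p, Q, I2, tau2, model.
#' @examples
#' se <- seFromOrP(c(2.03, 1.58), c(0.0005, 0.0633))
#' metaAnalyze(log(c(2.03, 1.58)), se)
#' @export
metaAnalyze <- function(logOR, se, model = c("fixed", "random")) {
  model <- match.arg(model)
  k <- length(logOR)
  if (k == 0) stop("no studies")
  if (length(se) != k || any(se <= 0)) stop("need one positive SE per study")
  w <- 1 / se^2
  bF <- sum(w * logOR) / sum(w)
  Q <- sum(w * (logOR - bF)^2)
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  tau2 <- 0
  if (model == "random" && k > 1) {
    cQ <- sum(w) - sum(w^2) / sum(w)
    tau2 <- if (cQ > 0) max(0, (Q - (k - 1)) / cQ) else 0
    w <- 1 / (se^2 + tau2)
  }
  b <- sum(w * logOR) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- b / pse
  data.frame(k = k, logOR = b, se = pse, or = exp(b), z = z,
             p = 2 * pnorm(-abs(z)), Q = Q, I2 = I2, tau2 = tau2,
             model = model, stringsAsFactors = FALSE)
}

#' Meta-analyse published per-cohort odds ratios and p-values
#'
#' Convenience wrapper reconstructing per-cohort SEs with [seFromOrP()] and
#' pooling with [metaAnalyze()].
#'
#' @param or per-cohort odds ratios.
#' @param p per-cohort two-sided p-values.
#' @param model passed to [metaAnalyze()].
#' @return see [metaAnalyze()].
#' @examples
#' metaFromOrP(c(2.03, 1.58), c(0.0005, 0.0633))   # pooled OR ~1.84
#' @export
metaFromOrP <- function(or, p, model = "fixed") {
  metaAnalyze(log(or), seFromOrP(or, p), model = model)
}
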