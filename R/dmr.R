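# Differentially methylated region detection: covariate-adjusted probe-wise
# linear models, gap-based probe clustering, candidate-region (bump)
# detection, and family-wise error control by Freedman-Lane residual
# resampling. Plus the per-CpG replication machinery (rank-based transform,
# Mann-Whitney U).

#' Build a case-contrast design matrix from a phenotype table
#'
#' Restricts to the case and reference groups, codes the contrast 0/1 and
#' appends the requested covariate columns (factors and characters are
#' expanded to dummies).
#'
#' @param pheno a [PhenotypeTable-class].
#' @param case group label coded 1.
#' @param ref group label(s) coded 0; defaults to all other groups.
#' @param covariates character vector of covariate column names.
#' @return list with `X` (design matrix: intercept, group, covariates) and
#'   `samples` (the retained sample ids).
#' @export
dmrDesign <- function(pheno, case = "PPMS", ref = NULL,
                      covariates = character()) {
  pd <- phenoData(pheno)
  if (is.null(ref)) ref <- setdiff(unique(pd$group), case)
  keep <- pd$group %in% c(case, ref)
  pd <- pd[keep, , drop = FALSE]
  X <- cbind(intercept = 1, group = as.numeric(pd$group == case))
  for (cv in covariates) {
    v <- pd[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv)
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(v)[-1])
      X <- cbind(X, mm)
    } else {
      X <- cbind(X, setNames(data.frame(v), cv))
    }
  }
  X <- as.matrix(X)
  rownames(X) <- pd$sample_id
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  list(X = X, samples = pd$sample_id)
}

#' Probe-wise covariate-adjusted linear fit
#'
#' Ordinary least squares of every probe's beta values on the design; the
#' returned coefficient is the case-contrast (group) effect in beta units,
#' with covariates partialled out.
#'
#' @param meth a [MethylationMatrix-class].
#' @param design the list returned by [dmrDesign()] (or any list with a
#'   full-rank matrix `X` whose second column is the group indicator and row
#'   names identify samples).
#' @return data.frame with one row per probe: coef, se, t, p.
#' @export
fitProbewise <- function(meth, design) {
  X <- design$X
  Y <- betaValues(meth)[rownames(X), , drop = FALSE]
  .olsScan(X, Y, which = 2L)
}

#' Cluster probes by genomic gap
#'
#' Maximal runs of consecutive probes whose inter-probe gap is at most
#' \code{maxGap}, per chromosome.
#'
#' @param chrom chromosome of each probe.
#' @param pos 1-based position of each probe, sorted within chromosome.
#' @param maxGap largest allowed gap in bp (default 500).
#' @return integer vector of cluster ids, one per probe.
#' @export
clusterProbes <- function(chrom, pos, maxGap = 500) {
  if (any(unlist(tapply(pos, chrom, is.unsorted))))
    stop("positions must be sorted within chromosome")
  n <- length(pos)
  newc <- c(TRUE, chrom[-1] != chrom[-n] | diff(pos) > maxGap)
  cumsum(newc)
}

#' Detect candidate regions (bumps)
#'
#' Within each probe cluster, maximal runs of length at least 2 whose
#' (optionally smoothed) coefficients all exceed +cutoff or all fall below
#' -cutoff.
#'
#' @param coef per-probe coefficients (beta units).
#' @param clusters integer cluster ids from [clusterProbes()].
#' @param cutoff positive coefficient cutoff.
#' @param smooth apply a running mean of width `k` within clusters first.
#' @param k running-mean width (odd, default 3).
#' @return data.frame with one row per candidate: cluster, idx_start,
#'   idx_end, n_probes, value (mean coefficient), area (sum of absolute
#'   coefficients).
#' @export
detectBumps <- function(coef, clusters, cutoff, smooth = FALSE, k = 3) {
  stopifnot(length(coef) == length(clusters), cutoff > 0)
  if (smooth) coef <- .smoothWithin(coef, clusters, k)
  sgn <- integer(length(coef))
  sgn[coef > cutoff] <- 1L
  sgn[coef < -cutoff] <- -1L
  # run breaks at cluster changes or sign changes
  n <- length(coef)
  if (n == 0L)
    return(data.frame(cluster = integer(), idx_start = integer(),
                      idx_end = integer(), n_probes = integer(),
                      value = numeric(), area = numeric()))
  brk <- c(TRUE, clusters[-1] != clusters[-n] | sgn[-1] != sgn[-n])
  run <- cumsum(brk)
  keep <- sgn != 0L
  if (!any(keep))
    return(data.frame(cluster = integer(), idx_start = integer(),
                      idx_end = integer(), n_probes = integer(),
                      value = numeric(), area = numeric()))
  idx <- which(keep)
  rid <- run[idx]
  starts <- tapply(idx, rid, min)
  ends <- tapply(idx, rid, max)
  len <- ends - starts + 1L
  sel <- len >= 2L
  starts <- as.integer(starts[sel]); ends <- as.integer(ends[sel])
  if (length(starts) == 0L)
    return(data.frame(cluster = integer(), idx_start = integer(),
                      idx_end = integer(), n_probes = integer(),
                      value = numeric(), area = numeric()))
  out <- data.frame(
    cluster = clusters[starts],
    idx_start = starts, idx_end = ends,
    n_probes = ends - starts + 1L,
    value = vapply(seq_along(starts),
                   function(i) mean(coef[starts[i]:ends[i]]), numeric(1)),
    area = vapply(seq_along(starts),
                  function(i) sum(abs(coef[starts[i]:ends[i]])), numeric(1)))
  out[order(-out$area), , drop = FALSE]
}

.smoothWithin <- function(coef, clusters, k = 3) {
  half <- (k - 1) / 2
  out <- coef
  for (cl in unique(clusters)) {
    i <- which(clusters == cl)
    if (length(i) < 2) next
    x <- coef[i]
    sm <- vapply(seq_along(x), function(j) {
      mean(x[max(1, j - half):min(length(x), j + half)])
    }, numeric(1))
    out[i] <- sm
  }
  out
}

# max |area| of candidate runs for a null coefficient vector (resampling)
.maxArea <- function(coef, clusters, cutoff) {
  sgn <- integer(length(coef))
  sgn[coef > cutoff] <- 1L
  sgn[coef < -cutoff] <- -1L
  n <- length(coef)
  brk <- c(TRUE, clusters[-1] != clusters[-n] | sgn[-1] != sgn[-n])
  run <- cumsum(brk)
  keep <- sgn != 0L
  if (!any(keep)) return(0)
  idx <- which(keep)
  a <- abs(coef[idx])
  rid <- run[idx]
  cnt <- tabulate(rid)
  sums <- vapply(split(a, rid), sum, numeric(1))
  len <- cnt[as.integer(names(sums))]
  ok <- len >= 2L
  if (!any(ok)) return(0)
  max(sums[ok])
}

#' Scan for differentially methylated regions with resampling FWER
#'
#' The full bump-hunting pipeline: probe-wise covariate-adjusted fits, probe
#' clustering by genomic gap, candidate-region detection above a coefficient
#' cutoff, and family-wise error control by resampling. The null draws use
#' Freedman-Lane residual permutation: residuals of the covariate-only model
#' are permuted and re-added to its fitted values, preserving the covariate
#' structure, and the whole candidate pipeline is re-run; the FWER p-value of
#' a region is the add-one fraction of resamples whose most extreme candidate
#' |area| reaches the observed one.
#'
#' @param meth a [MethylationMatrix-class].
#' @param design list from [dmrDesign()].
#' @param cutoff coefficient cutoff in beta units; \code{NULL} (default)
#'   picks the `cutoffQuantile` quantile of the absolute null coefficients
#'   pooled over the resamples, so the cutoff reflects what covariate-adjusted
#'   noise produces rather than the observed effects (an observed-coefficient
#'   quantile would mask any region spanning more than a few percent of the
#'   probes).
#' @param cutoffQuantile quantile used for the automatic cutoff
#'   (default 0.975).
#' @param maxGap probe clustering gap in bp.
#' @param B number of resamples (default 1000; a warning is raised below 100).
#' @param smooth,k optional running-mean smoothing of coefficients within
#'   clusters.
#' @param alpha FWER significance level used for the `significant` flag.
#' @return a [GenomicRanges::GRanges] with one range per candidate region
#'   (1-based inclusive probe coordinates) and metadata columns n_probes,
#'   value, area, fwer_p, significant, B; ordered by fwer_p then area.
#' @export
dmrScan <- function(meth, design, cutoff = NULL, maxGap = 500, B = 1000,
                    smooth = FALSE, k = 3, alpha = 0.05,
                    cutoffQuantile = 0.975) {
  if (B < 100) warning("B < 100 gives a very coarse FWER resolution")
  info <- probeInfo(meth)
  ord <- order(info$chrom, info$pos)
  if (!identical(ord, seq_len(nrow(info))))
    stop("probes must be ordered by chromosome and position")
  X <- design$X
  Y <- betaValues(meth)[rownames(X), , drop = FALSE]
  fit <- .olsScan(X, Y, which = 2L)
  coef_obs <- fit$coef
  clusters <- clusterProbes(info$chrom, info$pos, maxGap)

  # Freedman-Lane null: covariate-only model (drop the group column)
  X0 <- X[, -2L, drop = FALSE]
  qr0 <- qr(X0)
  fitted0 <- qr.fitted(qr0, Y)
  res0 <- Y - fitted0
  # group-contrast extractor row of (X'X)^-1 X'
  XtXinv <- chol2inv(qr.R(qr(X)))
  cvec <- (XtXinv %*% t(X))[2L, ]
  n <- nrow(Y)
  null_coefs <- function(nb) {
    out <- matrix(0, nb, length(coef_obs))
    for (b in seq_len(nb)) {
      Yb <- fitted0 + res0[sample.int(n), , drop = FALSE]
      coef_b <- as.numeric(cvec %*% Yb)
      if (smooth) coef_b <- .smoothWithin(coef_b, clusters, k)
      out[b, ] <- coef_b
    }
    out
  }
  if (is.null(cutoff)) {
    # the cutoff comes from its own resample batch: re-using the FWER
    # resamples couples the cutoff to the null maxima and inflates the
    # family-wise error rate
    cutoff <- quantile(abs(null_coefs(min(B, 200L))), cutoffQuantile,
                       names = FALSE)
  }
  cand <- detectBumps(coef_obs, clusters, cutoff, smooth = smooth, k = k)
  coef_null <- null_coefs(B)
  maxnull <- apply(coef_null, 1, .maxArea, clusters = clusters,
                   cutoff = cutoff)
  fwer <- vapply(cand$area, function(a) (1 + sum(maxnull >= a)) / (B + 1),
                 numeric(1))
  gr <- GenomicRanges::GRanges(
    seqnames = info$chrom[cand$idx_start],
    ranges = IRanges::IRanges(start = info$pos[cand$idx_start],
                              end = info$pos[cand$idx_end]))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    n_probes = cand$n_probes, value = cand$value, area = cand$area,
    fwer_p = fwer, significant = fwer < alpha, B = rep(B, nrow(cand)),
    idx_start = cand$idx_start, idx_end = cand$idx_end)
  gr[order(gr$fwer_p, -gr$area)]
}

#' Mann-Whitney U test for a single CpG
#'
#' Two-sided test of a location difference between two groups of beta values.
#' When n1 x n2 <= 400 the p-value is exact: the conditional permutation
#' distribution of the rank sum (average ranks for ties) is computed by
#' dynamic programming over the doubled mid-ranks, which is identical to full
#' enumeration of all arrangements. Larger samples use the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with statistic (U of group a), p.value, method, and per-group
#'   mean and SEM.
#' @examples
#' mannWhitneyCpG(c(1, 2, 3), c(4, 5, 6))$p.value   # exactly 0.1
#' @export
mannWhitneyCpG <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 * n2 <= 400) {
    p <- .exactRankSumP(r, n1)
    method <- "exact"
  } else {
    ties <- table(r)
    N <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(statistic = U, p.value = p, method = method,
       mean_a = mean(a), sem_a = sd(a) / sqrt(n1),
       mean_b = mean(b), sem_b = sd(b) / sqrt(n2))
}

# exact two-sided p for the rank-sum of group 1 (size n1) given pooled ranks r:
# DP over doubled mid-ranks counts, for each subset size, how many of the
# choose(N, n1) group assignments give each possible rank sum.
.exactRankSumP <- function(r, n1) {
  N <- length(r)
  r2 <- as.integer(round(2 * r))
  obs <- sum(r2[seq_len(n1)])
  S <- sum(r2)
  # f[j+1, s+1] = #subsets of size j with doubled-rank sum s
  f <- matrix(0, n1 + 1L, S + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(N)) {
    v <- r2[i]
    jmax <- min(i, n1)
    for (j in jmax:1) {
      nz <- which(f[j, ] > 0)
      if (length(nz))
        f[j + 1L, nz + v] <- f[j + 1L, nz + v] + f[j, nz]
    }
  }
  dist <- f[n1 + 1L, ]
  tot <- sum(dist)
  lo <- sum(dist[seq_len(obs + 1L)])          # P(sum <= obs)
  hi <- sum(dist[(obs + 1L):(S + 1L)])        # P(sum >= obs)
  min(1, 2 * min(lo, hi) / tot)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their (average, for ties) ranks:
#' value_i becomes qnorm((rank_i - 0.5) / n).
#'
#' @param x numeric vector with at least two distinct values.
#' @return transformed vector.
#' @examples
#' rankInverseNormal(c(5, 1, 9))   # 0, -0.967, 0.967
#' @export
rankInverseNormal <- function(x) {
  ok <- !is.na(x)
  if (length(unique(x[ok])) < 2) stop("need at least two distinct values")
  out <- rep(NA_real_, length(x))
  n <- sum(ok)
  out[ok] <- qnorm((rank(x[ok]) - 0.5) / n)
  out
}
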