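test_that("probe-wise fit matches hand-computed least squares", {
  # 5-sample toy, intercept-only covariates: coefficient is the group
  # mean difference 0.6 - 0.25 = 0.35
  X <- cbind(intercept = 1, group = c(0, 0, 1, 1, 1))
  rownames(X) <- paste0("s", 1:5)
  m <- MethylationMatrix(
    matrix(c(0.2, 0.3, 0.5, 0.6, 0.7), 5, 1,
           dimnames = list(paste0("s", 1:5), NULL)),
    data.frame(probe_id = "cg1", chrom = "1", pos = 100))
  fit <- fitProbewise(m, list(X = X))
  expect_equal(fit$coef, 0.35, tolerance = 1e-12)

  # response equal to a covariate column: group coefficient 0
  set.seed(1)
  cov1 <- rnorm(20)
  X2 <- cbind(intercept = 1, group = rep(0:1, 10), cov1 = cov1)
  rownames(X2) <- paste0("s", 1:20)
  m2 <- MethylationMatrix(
    matrix(.2 + 0.1 * (cov1 - min(cov1)) / diff(range(cov1)), 20, 1,
           dimnames = list(paste0("s", 1:20), NULL)),
    data.frame(probe_id = "cg1", chrom = "1", pos = 100))
  expect_lt(abs(fitProbewise(m2, list(X = X2))$coef), 1e-12)

  # duplicating every sample changes the SE exactly as closed-form OLS
  # variance predicts; cross-checked against lm()
  bd <- betaValues(m)[rep(1:5, 2), , drop = FALSE]
  rownames(bd) <- paste0("s", 1:10)
  mdup <- MethylationMatrix(bd, probeInfo(m))
  Xd <- X[rep(1:5, 2), ]
  rownames(Xd) <- paste0("s", 1:10)
  fd <- fitProbewise(mdup, list(X = Xd))
  ref <- summary(stats::lm(bd[, 1] ~ Xd[, "group"]))
  expect_equal(fd$se, ref$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(fd$coef, 0.35, tolerance = 1e-12)

  # fewer samples than design columns is an error
  expect_error(
    fitProbewise(MethylationMatrix(
      matrix(0.5, 2, 1, dimnames = list(paste0("s", 1:2), NULL)),
      data.frame(probe_id = "cg1", chrom = "1", pos = 1)),
      list(X = X[1:2, ])),
    "degrees of freedom|rank deficient")
})

test_that("probe clustering by gap matches a brute-force scan", {
  expect_identical(clusterProbes(rep("1", 3), c(100, 300, 5000), 500),
                   c(1L, 1L, 2L))
  expect_identical(clusterProbes("1", 42, 500), 1L)
  expect_error(clusterProbes(rep("1", 3), c(5, 1, 9)), "sorted")
  # random positions vs brute force
  set.seed(4)
  pos <- sort(sample(1:100000, 300))
  chrom <- rep(c("1", "2"), c(200, 100))
  got <- clusterProbes(chrom, c(sort(pos[1:200]), sort(pos[201:300])), 500)
  pos2 <- c(sort(pos[1:200]), sort(pos[201:300]))
  brute <- integer(300); brute[1] <- 1L
  for (i in 2:300) {
    brute[i] <- if (chrom[i] != chrom[i - 1] ||
                    pos2[i] - pos2[i - 1] > 500) brute[i - 1] + 1L
                else brute[i - 1]
  }
  expect_identical(got, brute)
})

test_that("bump detection finds signed runs of length >= 2", {
  cl <- rep(1L, 10)
  expect_identical(nrow(detectBumps(rep(0.01, 10), cl, 0.1)), 0L)
  co <- c(rep(0.01, 1), rep(0.3, 8), 0.01)
  b <- detectBumps(co, cl, 0.1)
  expect_identical(nrow(b), 1L)
  expect_identical(b$n_probes, 8L)
  # hand-built 3-probe run: area is the sum of |coefficients|
  co2 <- c(0.2, 0.25, 0.3, 0, 0)
  b2 <- detectBumps(co2, rep(1L, 5), 0.1)
  expect_equal(b2$area, 0.75)
  expect_equal(b2$value, 0.25)
  # opposite signs break a run
  co3 <- c(0.3, -0.3, 0.3, -0.3)
  expect_identical(nrow(detectBumps(co3, rep(1L, 4), 0.1)), 0L)
  # cluster boundaries break a run
  b4 <- detectBumps(rep(0.3, 4), c(1L, 1L, 2L, 2L), 0.1)
  expect_identical(b4$n_probes, c(2L, 2L))
})

test_that("planted region is detected and FWER p-values behave", {
  cfg <- simConfig(seed = 31)
  geno <- simulateGenotypes(cfg)
  pheno <- simulatePhenotype(geno, cfg)
  meth <- simulateMethylation(geno, pheno, cfg)
  des <- dmrDesign(pheno, case = "PPMS", ref = "HC",
                   covariates = c("age", "sex", "smoking", "cellPC1", "cellPC2"))
  set.seed(1)
  dmrs <- dmrScan(meth, des, B = 200)
  gt <- simMetadata(meth)$groundTruth$dmr
  expect_true(all(dmrs$n_probes >= 2))
  expect_true(all(dmrs$fwer_p >= 0 & dmrs$fwer_p <= 1))
  top <- dmrs[1]
  expect_lte(dmrs$fwer_p[1], 0.01)
  expect_equal(GenomicRanges::start(top), gt$start)
  expect_equal(GenomicRanges::end(top), gt$end)
  expect_identical(top$n_probes, 8L)

  # adding a constant to one probe's betas leaves fwer_p unchanged
  b2 <- betaValues(meth)
  b2[, 10] <- b2[, 10] - min(b2[, 10]) / 2   # constant shift, still in [0,1]
  meth2 <- MethylationMatrix(b2, probeInfo(meth))
  set.seed(1)
  dmrs2 <- dmrScan(meth2, des, B = 200)
  expect_equal(dmrs$fwer_p[1], dmrs2$fwer_p[1])

  # reordering samples leaves the verdict unchanged (Y rows follow the
  # design's sample ids, so permuting the design rows reorders both)
  des3 <- list(X = des$X[sample(nrow(des$X)), ])
  set.seed(2)
  dmrs3 <- dmrScan(meth, des3, B = 200)
  expect_equal(GenomicRanges::start(dmrs3[1]), gt$start)
  expect_lte(dmrs3$fwer_p[1], 0.01)
})

test_that("null probe-wise t statistics follow the t distribution", {
  cfg <- simConfig(seed = 33, nCpgs = 200,
                   meqtlTargets = data.frame(snp = 1, cpg = 30, shift = 0)[0, ],
                   dmrSpec = list(probes = 41:48, delta = 0))
  geno <- simulateGenotypes(cfg)
  pheno <- simulatePhenotype(geno, cfg)
  meth <- simulateMethylation(geno, pheno, cfg)
  des <- dmrDesign(pheno, case = "PPMS", ref = "HC",
                   covariates = c("age", "sex"))
  fit <- fitProbewise(meth, des)
  df <- nrow(des$X) - ncol(des$X)
  ks <- stats::ks.test(fit$t, function(q) stats::pt(q, df))
  expect_gt(ks$p.value, 0.01)
})

test_that("Mann-Whitney U matches enumeration and handles degenerate input", {
  r <- mannWhitneyCpG(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 0.1)
  expect_equal(mannWhitneyCpG(rep(1, 4), rep(1, 5))$p.value, 1)
  expect_error(mannWhitneyCpG(numeric(), 1:3), "non-empty")

  # exact path equals full enumeration for n <= 8 + 8, with and without ties
  set.seed(8)
  for (i in 1:12) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- sample(1:6, n1, replace = TRUE) + if (i %% 2) 0 else rnorm(n1, 0, 2)
    b <- sample(1:6, n2, replace = TRUE) + if (i %% 2) 0 else rnorm(n2, 0, 2)
    expect_equal(mannWhitneyCpG(a, b)$p.value, enumMannWhitneyP(a, b),
                 tolerance = 1e-10, info = paste("case", i))
  }
  # tie-free exact path agrees with wilcox.test's exact p
  set.seed(9)
  a <- rnorm(7); b <- rnorm(6)
  expect_equal(mannWhitneyCpG(a, b)$p.value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # normal approximation is close to enumeration at 4 vs 4
  set.seed(10)
  a <- rnorm(4); b <- rnorm(4) + 0.5
  exact_p <- mannWhitneyCpG(a, b)$p.value
  r <- rank(c(a, b))
  U <- sum(r[1:4]) - 10
  mu <- 8; s2 <- 4 * 4 * 9 / 12
  approx_p <- 2 * pnorm(-(abs(U - mu) - 0.5) / sqrt(s2))
  expect_lt(abs(approx_p - exact_p), 0.03)
})

test_that("rank-based inverse normal transform matches the closed form", {
  got <- rankInverseNormal(c(5, 1, 9))
  expect_equal(got, qnorm(c(3, 1, 5) / 6), tolerance = 1e-12)
  expect_equal(got[1], 0)
  # monotone in the input, mean zero for odd tie-free n
  set.seed(3)
  x <- rnorm(21)
  y <- rankInverseNormal(x)
  expect_identical(order(x), order(y))
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_error(rankInverseNormal(rep(2, 5)), "distinct")
})
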