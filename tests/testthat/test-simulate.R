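test_that("identical configurations give identical data (determinism)", {
  cfg <- simConfig(seed = 5)
  s1 <- simulateTrilayer(cfg)
  s2 <- simulateTrilayer(cfg)
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  expect_identical(betaValues(s1$methylation), betaValues(s2$methylation))
  expect_identical(exprValues(s1$expression), exprValues(s2$expression))
  expect_identical(phenoData(s1$phenotype), phenoData(s2$phenotype))
  s3 <- simulateTrilayer(simConfig(seed = 6))
  expect_false(identical(dosages(s1$genotypes), dosages(s3$genotypes)))
})

test_that("genotype generator respects MAF symmetry and block LD", {
  # independent SNPs at maf 0.5: mean dosage 1 by symmetry
  cfg <- simConfig(seed = 2, nPpms = 5000, nBoms = 4000, nHc = 1000,
                   nSnps = 10, ldBlocks = data.frame(size = rep(1, 10),
                                                     copyProb = 0),
                   mafRange = c(0.5, 0.5),
                   meqtlTargets = data.frame(snp = 1, cpg = 30, shift = 0.3),
                   riskSnps = data.frame(snp = 1, or = 1))
  g <- simulateGenotypes(cfg)
  expect_true(all(abs(colMeans(dosages(g)) - 1) < 0.05))
  r2 <- ldMatrix(g)
  expect_true(max(r2[upper.tri(r2)]) < 0.05)   # independent blocks

  # copy probability 0.95 inside blocks of 5 at n = 2000
  cfg2 <- simConfig(seed = 3, nPpms = 1000, nBoms = 500, nHc = 500)
  g2 <- simulateGenotypes(cfg2)
  r2 <- ldMatrix(g2)
  blk <- snpInfo(g2)$block
  within <- outer(blk, blk, "==") & upper.tri(r2)
  expect_gt(mean(r2[within]), 0.8)
  expect_lt(mean(r2[!within & upper.tri(r2)]), 0.05)
  expect_true(all(dosages(g2) %in% c(0, 1, 2)))
})

test_that("config invariants are enforced", {
  expect_error(simConfig(ldBlocks = data.frame(size = 7, copyProb = 0.9)),
               "sum to nSnps")
  expect_error(simConfig(triModalLevels = c(0.5, 0.2, 0.8)), "increasing")
  expect_error(simConfig(riskSnps = data.frame(snp = 1, or = -2)),
               "odds ratios")
  expect_error(simConfig(dmrSpec = list(probes = 5, delta = 0.2)),
               "at least 2 probes")
  expect_error(simConfig(mafRange = c(0.1, 0.7)), "mafRange")
})

test_that("phenotype generator calibrates the case fraction and plants ORs", {
  # null model: all ORs 1 -> case/control MAF equal within sampling error
  cfg <- simConfig(seed = 7, nPpms = 2500, nBoms = 2500, nHc = 10,
                   riskSnps = data.frame(snp = c(1, 6), or = c(1, 1)))
  g <- simulateGenotypes(cfg)
  ph <- simulatePhenotype(g, cfg)
  pd <- phenoData(ph)
  d <- dosages(g)
  for (j in c(1, 6, 11)) {
    maf_case <- mean(d[pd$group == "PPMS", j]) / 2
    maf_ctrl <- mean(d[pd$group == "BOMS", j]) / 2
    se <- sqrt(maf_case * (1 - maf_case) / (2 * sum(pd$group == "PPMS")) +
               maf_ctrl * (1 - maf_ctrl) / (2 * sum(pd$group == "BOMS")))
    expect_lt(abs(maf_case - maf_ctrl), 4 * se)
  }
  # intercept calibration: realized case fraction within 2 binomial SE
  target <- 0.5
  n_ms <- 5000
  frac <- mean(pd$group[1:n_ms] == "PPMS")
  expect_lt(abs(frac - target), 2 * sqrt(target * (1 - target) / n_ms))

  # planted OR 1.8 recovered from a dosage-stratified contingency table
  cfg2 <- simConfig(seed = 8, nPpms = 2000, nBoms = 2000, nHc = 10,
                    riskSnps = data.frame(snp = 1, or = 1.8))
  g2 <- simulateGenotypes(cfg2)
  pd2 <- phenoData(simulatePhenotype(g2, cfg2))
  d2 <- dosages(g2)[, 1]
  ms <- pd2$group != "HC"
  tab <- table(d2[ms] >= 1, pd2$group[ms] == "PPMS")
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  se <- sqrt(sum(1 / tab))
  # expected log-odds contrast for carriers (dosage 1 vs 0 dominates)
  expect_gt(lor + 2 * se, log(1.8) * 1)
  expect_lt(lor - 2 * se, log(1.8) * 2)
  expect_error(
    simulatePhenotype(g2, simConfig(riskSnps = data.frame(snp = 1, or = 0))),
    "odds ratios")
})

test_that("methylation generator hits tri-modal dosage means and the region shift", {
  cfg <- simConfig(seed = 9, nPpms = 500, nBoms = 300, nHc = 200,
                   meqtlTargets = data.frame(snp = 1, cpg = 30, shift = 0.3))
  g <- simulateGenotypes(cfg)
  ph <- simulatePhenotype(g, cfg)
  m <- simulateMethylation(g, ph, cfg)
  b <- betaValues(m)
  expect_true(all(b >= 0 & b <= 1))
  dos <- dosages(g)[, 1]
  for (dd in 0:2) {
    expect_lt(abs(mean(b[dos == dd, 30]) - c(0.2, 0.5, 0.8)[dd + 1]), 0.02)
  }
  # case-group shift on the planted region
  grp <- phenoData(ph)$group
  delta_hat <- mean(b[grp == "PPMS", 41:48]) - mean(b[grp == "HC", 41:48])
  expect_lt(abs(delta_hat - 0.24), 0.02)
  gt <- simMetadata(m)$groundTruth$dmr
  expect_identical(gt$probes, 41:48)
  expect_equal(gt$delta, 0.24)

  # null configuration: genotype groups have equal means
  cfg0 <- simConfig(seed = 10, nPpms = 500, nBoms = 300, nHc = 200,
                    meqtlTargets = data.frame(snp = 1, cpg = 30, shift = 0),
                    dmrSpec = list(probes = 41:48, delta = 0))
  m0 <- simulateMethylation(g, ph, cfg0)
  b0 <- betaValues(m0)
  expect_lt(abs(mean(b0[dos == 0, 30]) - mean(b0[dos == 2, 30])), 0.02)

  # group means must stay inside (0,1) before noise
  expect_error(
    simulateMethylation(g, ph, simConfig(
      seed = 9, nPpms = 500, nBoms = 300, nHc = 200,
      meqtlTargets = data.frame(snp = 1, cpg = 30, shift = 0.45))),
    "outside \\(0, 1\\)")
})

test_that("expression generator couples methylation and plants modules", {
  cfg <- simConfig(seed = 12, nPpms = 200, nBoms = 200, nHc = 100,
                   methToExpr = data.frame(cpg = 42, gene = 165, slope = -2))
  sim <- simulateTrilayer(cfg)
  b <- betaValues(sim$methylation)
  e <- exprValues(sim$expression)
  # negative slope link: CpG and gene negatively correlated at n = 500
  expect_lt(cor(b[, 42], e[165, ]), 0)

  # slope 0: no residual correlation
  cfg0 <- simConfig(seed = 12, nPpms = 200, nBoms = 200, nHc = 100,
                    methToExpr = data.frame(cpg = 42, gene = 165, slope = 0))
  sim0 <- simulateTrilayer(cfg0)
  expect_lt(abs(cor(betaValues(sim0$methylation)[, 42],
                    exprValues(sim0$expression)[165, ])), 0.1)

  # planted latent correlation 0.7 -> mean within-module Spearman in [0.4, 0.7]
  cfg2 <- simConfig(seed = 13, nPpms = 100, nBoms = 60, nHc = 40)
  sim2 <- simulateTrilayer(cfg2)
  E <- exprValues(sim2$expression)[1:40, ]
  rho <- cor(t(E), method = "spearman")
  mean_rho <- mean(rho[upper.tri(rho)])
  expect_gt(mean_rho, 0.4)
  expect_lt(mean_rho, 0.7)

  expect_error(
    simulateExpression(sim$methylation, sim$phenotype, simConfig(
      plantedModules = list(list(genes = integer(), cor = 0.5, trait = NA)))),
    "empty gene set")
})

test_that("missingness is injected at the configured rate", {
  cfg <- simConfig(seed = 14, missingRate = 0.05)
  g <- simulateGenotypes(cfg)
  rate <- mean(is.na(dosages(g)))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
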