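test_that("call-rate filter removes SNPs below the threshold", {
  d <- matrix(rep(c(0, 1, 2), length.out = 300), 100, 3)
  g <- toyGeno(d)
  expect_identical(ncol(dosages(filterCallRate(g))), 3L)   # nothing missing
  d2 <- d
  d2[1:3, 2] <- NA                                         # rate 0.97
  d2[1, 3] <- NA                                           # rate 0.99
  g2 <- toyGeno(d2)
  f <- filterCallRate(g2)
  expect_identical(snpInfo(f)$snp_id, c("s01", "s03"))
  rep <- simMetadata(f)$callRateExclusions
  expect_identical(rep$snp_id, "s02")
  expect_equal(rep$call_rate, 0.97)
})

test_that("exact HWE test matches full enumeration over heterozygote counts", {
  expect_lt(hweExactTest(50, 0, 50)$p.value, 1e-20)
  # enumeration oracle across assorted genotype tables
  cases <- list(c(50, 0, 50), c(25, 50, 25), c(10, 20, 5), c(3, 1, 7),
                c(40, 12, 2), c(7, 7, 7), c(0, 10, 0), c(12, 0, 1))
  for (cs in cases) {
    expect_equal(hweExactTest(cs[1], cs[2], cs[3])$p.value,
                 enumHweP(cs[1], cs[2], cs[3]),
                 tolerance = 1e-9, info = paste(cs, collapse = "/"))
  }
  # observed het count is never less probable than the reported tail implies:
  # p(obs) is included in its own tail
  h <- hweExactTest(25, 50, 25)
  expect_gte(h$p.value, 0)
  expect_true(hweExactTest(10, 0, 0)$monomorphic)
  expect_equal(hweExactTest(10, 0, 0)$p.value, 1)
})

test_that("logistic association recovers the contingency-table OR and is calibrated", {
  # binary dosage, no covariates: OR equals the cross-product ratio
  set.seed(5)
  x <- rbinom(400, 1, 0.3)
  y <- rbinom(400, 1, plogis(-0.5 + 0.8 * x))
  g <- toyGeno(matrix(x, ncol = 1))
  a <- logisticAssoc(g, y)
  tab <- table(x, y)
  expect_equal(a$or, (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1]),
               tolerance = 1e-6)
  expect_true(a$converged)

  # null SNPs at n = 5000: OR within [0.9, 1.1] for >= 95%
  set.seed(6)
  n <- 5000
  d <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
  y <- rbinom(n, 1, 0.5)
  a <- logisticAssoc(toyGeno(d), y)
  expect_gte(mean(a$or > 0.9 & a$or < 1.1), 0.95)

  # separation is flagged and estimates withheld
  xs <- c(rep(0, 20), rep(2, 20))
  ys <- c(rep(0, 20), rep(1, 20))
  as <- logisticAssoc(toyGeno(matrix(xs, ncol = 1)), ys)
  expect_false(as$converged)
  expect_true(is.na(as$beta))
  expect_error(logisticAssoc(toyGeno(matrix(xs, ncol = 1)), rep(1, 40)),
               "constant")
})

test_that("planted odds ratio is recovered by regression across replicates", {
  hits <- vapply(1:50, function(s) {
    cfg <- simConfig(seed = 100 + s, nPpms = 2000, nBoms = 2000, nHc = 10,
                     riskSnps = data.frame(snp = 1, or = 1.8))
    g <- simulateGenotypes(cfg)
    ph <- simulatePhenotype(g, cfg)
    a <- logisticAssoc(g[, 1], ph)
    abs(a$beta - log(1.8)) < 1.96 * a$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("dosage r-squared behaves and LD clumping matches hand greedy", {
  set.seed(7)
  x <- rbinom(5000, 2, 0.4)
  expect_equal(ldR2(x, x), 1)
  y <- rbinom(5000, 2, 0.4)
  expect_lt(ldR2(x, y), 0.01)
  expect_true(is.na(ldR2(x[1:5], rep(1, 5))))

  # generator ground truth: copied pairs exceed 0.8 at n = 2000
  cfg <- simConfig(seed = 8, nPpms = 1000, nBoms = 600, nHc = 400)
  g <- simulateGenotypes(cfg)
  d <- dosages(g)
  expect_gt(ldR2(d[, 1], d[, 2]), 0.8)

  # degenerate clumping cases
  dd <- matrix(rbinom(200, 2, 0.4), 100, 2)
  dd <- cbind(dd[, 1], dd[, 1], dd[, 2], dd[, 2])
  g2 <- toyGeno(dd)
  assoc <- data.frame(snp_id = snpInfo(g2)$snp_id, p = c(0.01, 0.5, 0.02, 0.9))
  bl <- clusterLdBlocks(g2, assoc)
  expect_identical(nBlocks(bl), 2L)
  expect_setequal(ldBlocks(bl)[["s01"]], c("s01", "s02"))
  expect_setequal(ldBlocks(bl)[["s03"]], c("s03", "s04"))

  # toy r2 structure vs a brute-force greedy clump over the same matrix
  set.seed(9)
  base <- matrix(rbinom(600 * 3, 2, 0.4), 600, 3)
  noisy <- function(v, flip) {
    i <- sample(length(v), flip)
    v[i] <- rbinom(flip, 2, 0.4)
    v
  }
  d6 <- cbind(base[, 1], noisy(base[, 1], 30), base[, 2],
              noisy(base[, 2], 20), base[, 3], noisy(base[, 3], 500))
  g6 <- toyGeno(d6)
  a6 <- data.frame(snp_id = snpInfo(g6)$snp_id,
                   p = c(0.001, 0.2, 0.005, 0.3, 0.0001, 0.5))
  got <- ldBlocks(clusterLdBlocks(g6, a6, 0.8))
  # hand-run greedy: seeds in p order (s05, s01, s03), members by r2 > 0.8
  r2 <- ldMatrix(g6)
  assigned <- rep(FALSE, 6)
  want <- list()
  for (i in c(5, 1, 3, 2, 4, 6)) {
    if (assigned[i]) next
    mem <- union(i, which(!assigned & r2[i, ] > 0.8))
    assigned[mem] <- TRUE
    want[[sprintf("s%02d", i)]] <- sprintf("s%02d", sort(mem))
  }
  expect_identical(lapply(got, sort), want[names(got)])
  expect_identical(sort(unlist(got, use.names = FALSE)),
                   sprintf("s%02d", 1:6))
})

test_that("block-wise Bonferroni threshold is exact and monotone", {
  expect_equal(bonferroniByBlocks(0.05, 1)$threshold, 0.05)
  t10 <- bonferroniByBlocks(0.05, 10)$threshold
  t20 <- bonferroniByBlocks(0.05, 20)$threshold
  expect_lt(t20, t10)
  expect_error(bonferroniByBlocks(0.05, 0), "nBlocks")
})

test_that("SE reconstruction from OR and p inverts the Wald test", {
  expect_equal(seFromOrP(2.03, 0.0005), abs(log(2.03)) / qnorm(0.99975),
               tolerance = 1e-12)
  expect_lt(abs(seFromOrP(2.03, 0.0005) - 0.203), 0.001)
  # roundtrip: p recomputed from (logOR, SE) equals the input
  for (or in c(0.4, 1.3, 2.8)) {
    for (p in c(0.0004, 0.01, 0.34)) {
      se <- seFromOrP(or, p)
      expect_equal(2 * pnorm(-abs(log(or) / se)), p, tolerance = 1e-4)
    }
  }
  expect_error(seFromOrP(1, 0.5), "OR = 1")
  expect_error(seFromOrP(-1, 0.5), "OR must be")
  expect_error(seFromOrP(2, 0), "p must be")
})

test_that("inverse-variance pooling matches closed forms and metafor", {
  # single study: identity
  m1 <- metaAnalyze(log(1.5), 0.2)
  expect_equal(m1$or, 1.5)
  expect_equal(m1$se, 0.2)
  # equal SEs: pooled logOR is the arithmetic mean
  m2 <- metaAnalyze(c(log(1.2), log(2)), c(0.3, 0.3))
  expect_equal(m2$logOR, mean(log(c(1.2, 2))), tolerance = 1e-12)
  # pooled estimate always lies between the inputs (convexity)
  set.seed(11)
  for (i in 1:20) {
    b <- rnorm(3); s <- runif(3, 0.05, 0.5)
    mf <- metaAnalyze(b, s)
    expect_gte(mf$logOR, min(b)); expect_lte(mf$logOR, max(b))
    # inverting all ORs flips the estimate but keeps the p-value
    mi <- metaAnalyze(-b, s)
    expect_equal(mi$p, mf$p, tolerance = 1e-12)
    expect_equal(mi$logOR, -mf$logOR, tolerance = 1e-12)
    # independent cross-check: metafor fixed and random effects
    rf <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(mf$logOR, as.numeric(rf$beta), tolerance = 1e-8)
    expect_equal(mf$se, rf$se, tolerance = 1e-8)
    expect_equal(mf$Q, rf$QE, tolerance = 1e-8)
    mr <- metaAnalyze(b, s, model = "random")
    rr <- metafor::rma(yi = b, sei = s, method = "DL")
    expect_equal(mr$logOR, as.numeric(rr$beta), tolerance = 1e-8)
    expect_equal(mr$tau2, rr$tau2, tolerance = 1e-8)
  }
  expect_error(metaAnalyze(numeric(), numeric()), "no studies")
})
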