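test_that("Spearman matrix equals rank-then-Pearson and is monotone-invariant", {
  set.seed(1)
  E <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  S <- spearmanMatrix(E)
  expect_equal(unname(diag(S)), rep(1, 5))
  expect_equal(S["g1", "g2"],
               cor(rank(E[1, ]), rank(E[2, ])), tolerance = 1e-12)
  # monotone transform leaves rho untouched
  E2 <- E; E2[1, ] <- exp(E[1, ])
  expect_equal(spearmanMatrix(E2), S, tolerance = 1e-12)
  expect_error(spearmanMatrix(E[, 1:2]), "3 samples")
  E3 <- rbind(E, g6 = rep(1, 10))
  expect_message(S3 <- spearmanMatrix(E3), "zero-variance")
  expect_identical(dim(S3), c(5L, 5L))
})

test_that("permutation edge filter is FDR-calibrated and recovers planted pairs", {
  # pure noise: retained-edge fraction at most ~2x the nominal FDR
  set.seed(2)
  frac <- vapply(1:10, function(i) {
    E <- matrix(rnorm(50 * 100), 50, 100,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
    net <- permutationEdgeFilter(E, B = 100, seed = 1000 + i)
    nrow(networkEdges(net)) / choose(50, 2)
  }, numeric(1))
  expect_lte(mean(frac), 0.1)

  # planted rho = 0.9 pairs at n = 50 are recovered
  set.seed(3)
  found <- vapply(1:5, function(i) {
    z <- matrix(rnorm(10 * 50), 10, 50)
    E <- rbind(z, z * sqrt(0.9 / 0.1) + matrix(rnorm(10 * 50), 10, 50)) /
      sqrt(1 + 0.9 / 0.1)
    # rows j and j+10 share correlation 0.9
    rownames(E) <- sprintf("g%02d", 1:20)
    net <- permutationEdgeFilter(E, B = 200, seed = 2000 + i)
    ed <- networkEdges(net)
    key <- paste(ed$node_a, ed$node_b)
    mean(paste(sprintf("g%02d", 1:10), sprintf("g%02d", 11:20)) %in% key)
  }, numeric(1))
  expect_gte(mean(found), 0.95)
  expect_warning(permutationEdgeFilter(matrix(rnorm(40), 4, 10), B = 50),
                 "coarse")
})

test_that("PMFG keeps the planar maximum on complete inputs", {
  mk <- function(n, seed) {
    set.seed(seed)
    ij <- t(combn(n, 2))
    data.frame(node_a = sprintf("n%02d", ij[, 1]),
               node_b = sprintf("n%02d", ij[, 2]),
               rho = runif(nrow(ij), -1, 1))
  }
  # K4: all 6 edges survive; K5: exactly 9 of 10
  p4 <- buildPmfg(mk(4, 1))
  expect_identical(nrow(networkEdges(p4)), 6L)
  p5 <- buildPmfg(mk(5, 2))
  expect_identical(nrow(networkEdges(p5)), 9L)
  # brute-force oracle for 5 nodes: the only non-planar subgraph of K5 is
  # K5 itself, so any 9-edge subgraph is planar and maximal
  expect_lt(nrow(networkEdges(p5)), 10L)
  # triangle passes through
  p3 <- buildPmfg(mk(3, 3))
  expect_identical(nrow(networkEdges(p3)), 3L)

  # edge-order invariance given the deterministic sort and tie-break
  ed <- mk(8, 4)
  pa <- buildPmfg(ed)
  pb <- buildPmfg(ed[sample(nrow(ed)), ])
  expect_identical(networkEdges(pa), networkEdges(pb))

  # result is planar by the independent networkx oracle
  nodes <- networkNodes(p5)
  g <- list(n = 5, edges = cbind(match(networkEdges(p5)$node_a, nodes),
                                 match(networkEdges(p5)$node_b, nodes)))
  expect_true(networkxPlanar(list(g)))
})

test_that("multiscale clustering separates disconnected cliques and partitions nodes", {
  ij <- t(combn(15, 2))
  ed <- rbind(
    data.frame(node_a = sprintf("a%02d", ij[, 1]),
               node_b = sprintf("a%02d", ij[, 2]), rho = 0.9),
    data.frame(node_a = sprintf("b%02d", ij[, 1]),
               node_b = sprintf("b%02d", ij[, 2]), rho = 0.9))
  pm <- buildPmfg(ed)
  tree <- multiscaleCluster(pm, minSize = 10)
  lm <- leafModules(tree)
  expect_identical(sum(tree@nodes$leaf), 2L)
  expect_identical(sort(names(lm)), sort(networkNodes(pm)))
  expect_identical(length(unique(lm[sprintf("a%02d", 1:15)])), 1L)
  expect_identical(length(unique(lm[sprintf("b%02d", 1:15)])), 1L)
  expect_error(multiscaleCluster(new("PMFG", nodes = character(),
                                     edges = data.frame())), "empty")
})

test_that("principal components match hand eigenvalues and the sign convention", {
  # x2 = x1 and x3 independent: correlation eigenvalues 2, 1, 0
  set.seed(4)
  x1 <- rnorm(200)
  x3 <- stats::resid(stats::lm(rnorm(200) ~ x1))   # exactly orthogonal
  m <- cbind(x1, x1, x3)
  pc <- principalComponents(m, k = 3)
  ev <- pc$varFrac * 3
  expect_equal(ev, c(2, 1, 0), tolerance = 1e-8)
  # rank-1 matrix: PC1 carries everything
  r1 <- outer(rnorm(30), c(1, 2, 3))
  expect_equal(principalComponents(r1, k = 1)$varFrac[1], 1, tolerance = 1e-10)
  # sign convention: corr(PC1, row-mean profile) >= 0
  for (i in 1:10) {
    mm <- matrix(rnorm(40 * 6), 40, 6) + rnorm(40)
    sc <- principalComponents(mm, k = 1)$scores[, 1]
    expect_gte(cor(sc, rowMeans(scale(mm))), 0)
  }
  expect_error(principalComponents(matrix(1, 5, 3)), "constant")
})

test_that("module-trait association flags the coupled module and is code-symmetric", {
  sim <- simulateTrilayer(networkConfig(77))
  net <- permutationEdgeFilter(sim$expression, B = 100, seed = 78)
  tree <- multiscaleCluster(buildPmfg(net))
  grp <- phenoData(sim$phenotype)$group
  traits <- data.frame(PPMS = as.integer(grp == "PPMS"))
  mta <- suppressMessages(
    moduleTraitAssociation(tree, sim$expression, traits))
  lm <- leafModules(tree)
  ppms_mod <- names(which.max(table(lm[sprintf("gene_%03d", 1:50)])))
  expect_true(mta$flagged[mta$module == ppms_mod])
  # flipping the coding flips the correlation, q unchanged
  traits2 <- data.frame(PPMS = 1L - traits$PPMS)
  mta2 <- suppressMessages(
    moduleTraitAssociation(tree, sim$expression, traits2))
  expect_equal(mta2$cor, -mta$cor, tolerance = 1e-12)
  expect_equal(mta2$q, mta$q, tolerance = 1e-12)
})

test_that("Fisher overlap matches hypergeometric enumeration", {
  r <- fisherOverlap(letters[1:5], letters[1:5], letters[1:20])
  expect_equal(r$p.value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(r$haldane)
  # overlap at expectation: OR close to 1 (and no zero cells at this size)
  u <- sprintf("u%03d", 1:100)
  r2 <- fisherOverlap(u[1:50], u[c(1:25, 51:75)], u)
  expect_false(r2$haldane)
  expect_equal(r2$or, 1, tolerance = 0.05)
  # enumeration oracle on assorted small tables
  set.seed(5)
  for (i in 1:20) {
    N <- sample(8:30, 1)
    u <- sprintf("x%02d", 1:N)
    a <- sample(u, sample(2:(N - 2), 1))
    b <- sample(u, sample(2:(N - 2), 1))
    got <- fisherOverlap(a, b, u)
    expect_equal(got$p.value,
                 enumFisherP(length(a), length(b), N,
                             length(intersect(a, b))),
                 tolerance = 1e-9, info = paste("case", i))
  }
  expect_error(fisherOverlap("a", "b", character()), "empty universe")
  expect_error(fisherOverlap("zz", "a", letters), "subsets")
})
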