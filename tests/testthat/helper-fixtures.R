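# shared fixtures built in code

# small complete-structure simulation reused across files
smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateTrilayer(simConfig(seed = 42))
    cache
  }
})

# network-scale configuration: four planted 50-gene modules covering all
# genes, latent correlation chosen so the realized within-module pairwise
# correlation is ~0.8 after expression noise
networkConfig <- function(seed) {
  simConfig(seed = seed, nPpms = 40, nBoms = 40, nHc = 20,
    plantedModules = list(
      list(genes = 1:50, cor = 0.872, trait = "PPMS"),
      list(genes = 51:100, cor = 0.872, trait = "BOMS"),
      list(genes = 101:150, cor = 0.872, trait = NA),
      list(genes = 151:200, cor = 0.872, trait = NA)),
    methToExpr = data.frame(cpg = integer(), gene = integer(),
                            slope = numeric()))
}

# toy genotype object from a dosage matrix
toyGeno <- function(d, chrom = "1", pos = NULL) {
  d <- as.matrix(d)
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 1000
  af <- colMeans(d, na.rm = TRUE) / 2
  GenotypeMatrix(d, data.frame(
    snp_id = sprintf("s%02d", seq_len(ncol(d))), chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    maf = pmax(pmin(af, 1 - af), 0.01)))
}

# planarity verdicts from networkx (independent oracle); one python call
# for a whole batch of graphs
networkxPlanar <- function(graphs) {
  gfile <- tempfile(fileext = ".txt")
  con <- file(gfile, "w")
  for (gr in graphs) {
    ed <- gr$edges
    cat(gr$n, ";", paste(apply(ed, 1, paste, collapse = ","), collapse = ";"),
        "\n", sep = "", file = con)
  }
  close(con)
  py <- c(
    "import sys, networkx as nx",
    "out = []",
    sprintf("f = open('%s')", gfile),
    "for line in f:",
    "    parts = line.strip().split(';')",
    "    n = int(parts[0])",
    "    G = nx.Graph(); G.add_nodes_from(range(1, n + 1))",
    "    for p in parts[1:]:",
    "        if p:",
    "            a, b = p.split(','); G.add_edge(int(a), int(b))",
    "    out.append('1' if nx.check_planarity(G)[0] else '0')",
    "print(''.join(out))")
  pfile <- tempfile(fileext = ".py")
  writeLines(py, pfile)
  res <- system2("python", pfile, stdout = TRUE)
  strsplit(res[length(res)], "")[[1]] == "1"
}

# brute-force two-sided Mann-Whitney p by full enumeration of group
# assignments (oracle for small n, ties allowed)
enumMannWhitneyP <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  r <- rank(x)
  obs <- sum(r[seq_len(n1)])
  combos <- combn(length(x), n1)
  sums <- apply(combos, 2, function(i) sum(rank(x)[i]))
  lo <- mean(sums <= obs + 1e-9)
  hi <- mean(sums >= obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# hypergeometric enumeration oracle for the two-sided Fisher overlap p
enumFisherP <- function(nA, nB, N, x) {
  xs <- max(0, nA + nB - N):min(nA, nB)
  pr <- stats::dhyper(xs, nA, N - nA, nB)
  sum(pr[pr <= pr[match(x, xs)] * (1 + 1e-9)])
}

# exact HWE enumeration oracle: probability of each heterozygote count
# conditional on allele counts, from the closed-form counting formula
enumHweP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (min(nA, na) - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}
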