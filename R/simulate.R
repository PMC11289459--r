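# Synthetic trilayer generator: LD-blocked genotypes, a logistic disease-course
# phenotype, genotype-controlled tri-modal methylation with a planted
# case-specific hypermethylated region, and methylation-repressed expression
# carrying trait-coupled co-expression modules. Ground truth is recorded so
# every downstream stage can be scored.

#' Simulation configuration
#'
#' Holds every knob of the synthetic trilayer generator. Defaults encode the
#' study conditions the pipeline is designed for: a hypermethylated region of
#' 8 consecutive CpG probes with a case-group beta shift of 0.24, CpGs whose
#' methylation clusters at three levels (0.2 / 0.5 / 0.8) under additive
#' genetic control, risk alleles with odds ratios in the 1.5-1.8 range, and
#' trait-coupled co-expression modules.
#'
#' @slot nPpms,nBoms,nHc group sizes (cases, bout-onset controls, healthy
#'   controls).
#' @slot nSnps number of SNPs.
#' @slot ldBlocks data.frame with columns size and copyProb; one row per LD
#'   block, sizes must sum to nSnps. Non-anchor SNPs copy the anchor
#'   haplotype-wise with probability copyProb.
#' @slot mafRange pair of minor-allele frequencies in (0, 0.5]; each block's
#'   anchor MAF is drawn uniformly from this range.
#' @slot nCpgs number of CpG probes.
#' @slot cpgChrom chromosome name of the probes.
#' @slot cpgPositions sorted 1-based probe positions (length nCpgs).
#' @slot meqtlTargets data.frame with columns snp, cpg, shift: per-allele
#'   beta shift of each planted methylation QTL.
#' @slot dmrSpec list with `probes` (integer index range, at least 2) and
#'   `delta` (case-group beta shift, default 0.24).
#' @slot triModalLevels three strictly increasing mean betas in (0, 1).
#' @slot riskSnps data.frame with columns snp and or (odds ratio per
#'   minor-allele copy).
#' @slot nGenes number of genes.
#' @slot plantedModules list of lists with elements genes (integer indices),
#'   cor (within-module latent correlation) and trait (group label the module
#'   tracks, or NA).
#' @slot methToExpr data.frame with columns cpg, gene, slope (expression
#'   change per unit beta).
#' @slot moduleAmp amplitude of the module component on the log-expression
#'   scale.
#' @slot noiseSd list with elements methylation and expression.
#' @slot missingRate completely-at-random missing-call rate for genotypes.
#' @slot logitNoise add methylation noise on the logit rather than beta scale.
#' @slot confoundCovariates couple age to the first risk SNP to exercise
#'   covariate adjustment under confounding.
#' @slot seed integer seed; all stage streams derive from it.
#' @export
setClass("SimConfig", representation(
  nPpms = "numeric", nBoms = "numeric", nHc = "numeric",
  nSnps = "numeric", ldBlocks = "data.frame", mafRange = "numeric",
  nCpgs = "numeric", cpgChrom = "character", cpgPositions = "numeric",
  meqtlTargets = "data.frame", dmrSpec = "list", triModalLevels = "numeric",
  riskSnps = "data.frame", nGenes = "numeric", plantedModules = "list",
  methToExpr = "data.frame", moduleAmp = "numeric", noiseSd = "list",
  missingRate = "numeric", logitNoise = "logical",
  confoundCovariates = "logical", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(object@nPpms, object@nBoms, object@nHc, object@nSnps,
           object@nCpgs, object@nGenes)
  if (any(cnt <= 0)) msg <- c(msg, "all counts must be > 0")
  if (length(object@mafRange) != 2 || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
    msg <- c(msg, "mafRange must be an increasing pair in (0, 0.5]")
  if (sum(object@ldBlocks$size) != object@nSnps)
    msg <- c(msg, "LD block sizes must sum to nSnps")
  if (any(object@ldBlocks$copyProb < 0 | object@ldBlocks$copyProb > 1))
    msg <- c(msg, "copy probabilities must be in [0, 1]")
  tm <- object@triModalLevels
  if (length(tm) != 3 || any(diff(tm) <= 0) || any(tm <= 0) || any(tm >= 1))
    msg <- c(msg, "triModalLevels must be strictly increasing in (0, 1)")
  if (length(object@dmrSpec$probes) < 2)
    msg <- c(msg, "the planted region must span at least 2 probes")
  if (any(object@dmrSpec$probes < 1 | object@dmrSpec$probes > object@nCpgs))
    msg <- c(msg, "dmrSpec probe indices out of range")
  if (any(diff(sort(object@dmrSpec$probes)) != 1))
    msg <- c(msg, "the planted region must be a consecutive probe run")
  if (nrow(object@riskSnps) && any(object@riskSnps$or <= 0))
    msg <- c(msg, "odds ratios must be > 0")
  if (nrow(object@riskSnps) && any(object@riskSnps$snp > object@nSnps))
    msg <- c(msg, "risk SNP index out of range")
  if (nrow(object@meqtlTargets) &&
      (any(object@meqtlTargets$snp > object@nSnps) ||
       any(object@meqtlTargets$cpg > object@nCpgs)))
    msg <- c(msg, "meQTL target index out of range")
  if (length(object@cpgPositions) != object@nCpgs)
    msg <- c(msg, "cpgPositions must have length nCpgs")
  if (is.unsorted(object@cpgPositions, strictly = TRUE))
    msg <- c(msg, "cpgPositions must be strictly increasing")
  if (length(object@plantedModules)) {
    g <- unlist(lapply(object@plantedModules, `[[`, "genes"))
    if (length(g) == 0) msg <- c(msg, "planted module with empty gene set")
    if (any(g < 1 | g > object@nGenes)) msg <- c(msg, "module gene index out of range")
    if (anyDuplicated(g)) msg <- c(msg, "planted modules must not overlap")
  }
  if (nrow(object@methToExpr) &&
      (any(object@methToExpr$cpg > object@nCpgs) ||
       any(object@methToExpr$gene > object@nGenes)))
    msg <- c(msg, "methToExpr index out of range")
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' All arguments have defaults encoding the study conditions (see
#' [SimConfig-class]); pass overrides as named arguments.
#'
#' @param nPpms,nBoms,nHc group sizes.
#' @param nSnps,ldBlocks,mafRange genotype layer.
#' @param nCpgs,cpgChrom,cpgPositions,meqtlTargets,dmrSpec,triModalLevels
#'   methylation layer.
#' @param riskSnps phenotype layer.
#' @param nGenes,plantedModules,methToExpr,moduleAmp expression layer.
#' @param noiseSd,missingRate,logitNoise,confoundCovariates,seed nuisance
#'   settings.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 7)
#' cfg
#' @export
simConfig <- function(nPpms = 60, nBoms = 60, nHc = 60,
                      nSnps = 60,
                      ldBlocks = data.frame(size = rep(5, 12),
                                            copyProb = 0.95),
                      mafRange = c(0.15, 0.5),
                      nCpgs = 100,
                      cpgChrom = "1",
                      cpgPositions = NULL,
                      meqtlTargets = data.frame(
                        snp = c(1, 6, 11, 16),
                        cpg = c(30, 31, 32, 33),
                        shift = c(0.30, 0.19, -0.15, 0.09)),
                      dmrSpec = list(probes = 41:48, delta = 0.24),
                      triModalLevels = c(0.2, 0.5, 0.8),
                      riskSnps = data.frame(snp = c(1, 6), or = c(1.8, 1.5)),
                      nGenes = 200,
                      plantedModules = list(
                        list(genes = 1:40, cor = 0.7, trait = "PPMS"),
                        list(genes = 41:80, cor = 0.7, trait = "BOMS"),
                        list(genes = 81:120, cor = 0.7, trait = NA),
                        list(genes = 121:160, cor = 0.7, trait = NA)),
                      methToExpr = data.frame(cpg = c(42, 45),
                                              gene = c(165, 166),
                                              slope = c(-2, -2)),
                      moduleAmp = 1,
                      noiseSd = list(methylation = 0.03, expression = 0.3),
                      missingRate = 0, logitNoise = FALSE,
                      confoundCovariates = FALSE, seed = 1) {
  if (is.null(cpgPositions)) {
    # probes fall in tight clusters of 10 (300 bp spacing) separated by 50 kb,
    # so the gap-based probe clustering has realistic structure to act on
    k <- ceiling(nCpgs / 10)
    cpgPositions <- as.vector(outer(0:9 * 300, 146000000 + (0:(k - 1)) * 50000,
                                    "+"))[seq_len(nCpgs)]
  }
  new("SimConfig", nPpms = nPpms, nBoms = nBoms, nHc = nHc, nSnps = nSnps,
      ldBlocks = as.data.frame(ldBlocks), mafRange = mafRange, nCpgs = nCpgs,
      cpgChrom = cpgChrom, cpgPositions = cpgPositions,
      meqtlTargets = as.data.frame(meqtlTargets), dmrSpec = dmrSpec,
      triModalLevels = triModalLevels, riskSnps = as.data.frame(riskSnps),
      nGenes = nGenes, plantedModules = plantedModules,
      methToExpr = as.data.frame(methToExpr), moduleAmp = moduleAmp,
      noiseSd = noiseSd, missingRate = missingRate, logitNoise = logitNoise,
      confoundCovariates = confoundCovariates, seed = seed)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nPpms, "PPMS /", object@nBoms, "BOMS /",
      object@nHc, "HC;", object@nSnps, "SNPs in", nrow(object@ldBlocks),
      "LD blocks;", object@nCpgs, "CpGs;", object@nGenes, "genes; seed",
      object@seed, "\n")
})

.nSamples <- function(config) config@nPpms + config@nBoms + config@nHc

#' Simulate LD-blocked genotypes
#'
#' Genotypes are generated haplotype-wise: each sample carries two independent
#' haplotypes; within an LD block the anchor SNP's haplotype alleles are drawn
#' Bernoulli(MAF) and every other SNP copies the anchor allele with the
#' block's copy probability (else redraws), so dosage-level linkage
#' disequilibrium arises mechanistically with r-squared close to the squared
#' copy probability.
#'
#' @param config a [SimConfig-class].
#' @return a [GenotypeMatrix-class]; block assignment is kept in
#'   \code{snpInfo$block} and simulation truth in the metadata.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(.stageSeed(config@seed, "genotypes"))
  n <- .nSamples(config)
  blocks <- config@ldBlocks
  dosage <- matrix(NA_real_, n, config@nSnps)
  block_id <- integer(config@nSnps)
  maf <- numeric(config@nSnps)
  col <- 0L
  for (b in seq_len(nrow(blocks))) {
    size <- blocks$size[b]
    cp <- blocks$copyProb[b]
    f <- runif(1, config@mafRange[1], config@mafRange[2])
    anchor <- matrix(rbinom(2L * n, 1L, f), n, 2L)   # two haplotypes
    for (s in seq_len(size)) {
      col <- col + 1L
      block_id[col] <- b
      maf[col] <- f
      if (s == 1L) {
        hap <- anchor
      } else {
        copy <- matrix(runif(2L * n) < cp, n, 2L)
        fresh <- matrix(rbinom(2L * n, 1L, f), n, 2L)
        hap <- ifelse(copy, anchor, fresh)
      }
      dosage[, col] <- rowSums(hap)
    }
  }
  if (config@missingRate > 0) {
    miss <- runif(length(dosage)) < config@missingRate
    dosage[miss] <- NA_real_
  }
  info <- data.frame(
    snp_id = sprintf("snp_%03d", seq_len(config@nSnps)),
    chrom = config@cpgChrom,
    pos = 146500000 + (seq_len(config@nSnps) - 1L) * 8000,
    effect_allele = "A", other_allele = "G",
    maf = maf, block = block_id,
    stringsAsFactors = FALSE)
  GenotypeMatrix(dosage, info,
                 metadata = list(groundTruth = list(ldBlocks = block_id)))
}

#' Simulate the disease-course phenotype and covariates
#'
#' Disease-course labels for the MS samples are drawn from a logistic model
#' whose log-odds are an intercept plus the sum of log(OR) x dosage over the
#' configured risk SNPs; the intercept is calibrated by root finding so the
#' expected case fraction equals nPpms / (nPpms + nBoms). The last nHc
#' samples are healthy controls. Covariates (age, sex, smoking, batch, cell
#' fractions and their first two PCs, two ancestry PCs) are drawn from simple
#' distributions, independent of genotype unless \code{confoundCovariates}.
#'
#' @param geno [GenotypeMatrix-class] from [simulateGenotypes()].
#' @param config the same [SimConfig-class].
#' @return a [PhenotypeTable-class].
#' @export
simulatePhenotype <- function(geno, config) {
  stopifnot(is(geno, "GenotypeMatrix"), is(config, "SimConfig"))
  if (nrow(config@riskSnps) && any(config@riskSnps$or <= 0))
    stop("odds ratios must be > 0")
  set.seed(.stageSeed(config@seed, "phenotype"))
  n <- .nSamples(config)
  n_ms <- config@nPpms + config@nBoms
  d <- dosages(geno)
  eta <- rep(0, n)
  if (nrow(config@riskSnps)) {
    for (k in seq_len(nrow(config@riskSnps))) {
      dk <- d[, config@riskSnps$snp[k]]
      dk[is.na(dk)] <- mean(dk, na.rm = TRUE)
      eta <- eta + log(config@riskSnps$or[k]) * dk
    }
  }
  target <- config@nPpms / n_ms
  eta_ms <- eta[seq_len(n_ms)]
  b0 <- uniroot(function(b) mean(plogis(b + eta_ms)) - target,
                c(-20, 20), tol = 1e-10)$root
  group <- rep("HC", n)
  is_case <- runif(n_ms) < plogis(b0 + eta_ms)
  group[seq_len(n_ms)] <- ifelse(is_case, "PPMS", "BOMS")

  cellfrac <- matrix(rgamma(6L * n, shape = c(8, 4, 3, 2, 1.5, 1)), n, 6L,
                     byrow = TRUE)
  cellfrac <- cellfrac / rowSums(cellfrac)
  colnames(cellfrac) <- paste0("cell", 1:6)
  cellpc <- prcomp(cellfrac, center = TRUE, scale. = TRUE)$x[, 1:2]
  age <- round(rnorm(n, 45, 10))
  if (config@confoundCovariates && nrow(config@riskSnps)) {
    d1 <- d[, config@riskSnps$snp[1]]
    d1[is.na(d1)] <- mean(d1, na.rm = TRUE)
    age <- age + 3 * d1
  }
  pd <- data.frame(
    sample_id = sampleIds(geno),
    group = group,
    age = age,
    sex = rbinom(n, 1, 0.5),
    smoking = rbinom(n, 1, 0.4),
    batch = sample(c("b1", "b2"), n, replace = TRUE),
    cellPC1 = cellpc[, 1], cellPC2 = cellpc[, 2],
    ancestryPC1 = rnorm(n), ancestryPC2 = rnorm(n),
    stringsAsFactors = FALSE)
  pd <- cbind(pd, as.data.frame(cellfrac))
  PhenotypeTable(pd, metadata = list(
    groundTruth = list(riskSnps = config@riskSnps, intercept = b0,
                       targetCaseFraction = target)))
}

#' Simulate genotype-controlled methylation with a planted region
#'
#' Each CpG gets a base level drawn from the tri-modal levels; methylation-QTL
#' target CpGs start at the lowest level and add shift x dosage per
#' minor-allele copy (a full-strength shift walks the three levels for
#' dosages 0/1/2). Probes of the planted region start at the lowest level and
#' gain the configured case-group beta shift in PPMS samples. Gaussian noise
#' is added on the beta scale (or logit scale when configured) and values are
#' clipped to (0.001, 0.999).
#'
#' @param geno [GenotypeMatrix-class].
#' @param pheno [PhenotypeTable-class].
#' @param config the same [SimConfig-class].
#' @return a [MethylationMatrix-class] with ground truth in the metadata.
#' @export
simulateMethylation <- function(geno, pheno, config) {
  stopifnot(is(geno, "GenotypeMatrix"), is(pheno, "PhenotypeTable"),
            is(config, "SimConfig"))
  set.seed(.stageSeed(config@seed, "methylation"))
  n <- .nSamples(config)
  p <- config@nCpgs
  lv <- config@triModalLevels
  base <- sample(lv, p, replace = TRUE)
  dmr_idx <- sort(config@dmrSpec$probes)
  base[dmr_idx] <- lv[1]
  qt <- config@meqtlTargets
  if (nrow(qt)) base[qt$cpg] <- ifelse(qt$shift >= 0, lv[1], lv[3])
  mu <- matrix(base, n, p, byrow = TRUE)
  d <- dosages(geno)
  if (nrow(qt)) {
    for (k in seq_len(nrow(qt))) {
      dk <- d[, qt$snp[k]]
      dk[is.na(dk)] <- mean(dk, na.rm = TRUE)
      mu[, qt$cpg[k]] <- base[qt$cpg[k]] + qt$shift[k] * dk
    }
  }
  is_case <- phenoData(pheno)$group == "PPMS"
  mu[is_case, dmr_idx] <- mu[is_case, dmr_idx] + config@dmrSpec$delta
  if (min(mu) <= 0 || max(mu) >= 1)
    stop("configuration error: group mean betas fall outside (0, 1) before noise")
  sdm <- config@noiseSd$methylation
  if (config@logitNoise) {
    eta <- log(mu / (1 - mu)) + rnorm(n * p, sd = sdm * 4)
    beta <- 1 / (1 + exp(-eta))
  } else {
    beta <- mu + rnorm(n * p, sd = sdm)
  }
  beta <- .clip(beta)
  info <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(p)),
    chrom = config@cpgChrom,
    pos = config@cpgPositions,
    stringsAsFactors = FALSE)
  gt <- list(
    dmr = list(chrom = config@cpgChrom,
               probes = dmr_idx,
               start = config@cpgPositions[dmr_idx[1]],
               end = config@cpgPositions[dmr_idx[length(dmr_idx)]],
               delta = config@dmrSpec$delta),
    meqtl = qt)
  MethylationMatrix(beta, info, metadata = list(groundTruth = gt))
  }

#' Simulate methylation-coupled expression with planted modules
#'
#' Gene values on the log scale are a gene baseline, plus slope x beta of any
#' linked CpG, plus a module component amp x (sqrt(r) x latent +
#' sqrt(1 - r) x gene noise) whose latent factor is shifted by one standard
#' deviation in samples carrying the module's coupled trait, plus Gaussian
#' noise. With the default amplitude and noise this yields within-module
#' pairwise correlations close to r x amp^2 / (amp^2 + noise^2).
#'
#' @param meth [MethylationMatrix-class].
#' @param pheno [PhenotypeTable-class].
#' @param config the same [SimConfig-class].
#' @return an [ExpressionMatrix-class] with ground truth in the metadata.
#' @export
simulateExpression <- function(meth, pheno, config) {
  stopifnot(is(meth, "MethylationMatrix"), is(pheno, "PhenotypeTable"),
            is(config, "SimConfig"))
  if (length(config@plantedModules) &&
      any(lengths(lapply(config@plantedModules, `[[`, "genes")) == 0))
    stop("configuration error: planted module with empty gene set")
  set.seed(.stageSeed(config@seed, "expression"))
  n <- .nSamples(config)
  g <- config@nGenes
  baseline <- rnorm(g, mean = 7, sd = 0.5)
  expr <- matrix(baseline, g, n) +
    matrix(rnorm(g * n, sd = config@noiseSd$expression), g, n)
  grp <- phenoData(pheno)$group
  truth_mod <- data.frame(gene = integer(), module = integer(),
                          trait = character(), stringsAsFactors = FALSE)
  for (m in seq_along(config@plantedModules)) {
    mod <- config@plantedModules[[m]]
    latent <- rnorm(n)
    if (!is.na(mod$trait)) latent <- latent + (grp == mod$trait)
    r <- mod$cor
    eps <- matrix(rnorm(length(mod$genes) * n), length(mod$genes), n)
    comp <- config@moduleAmp *
      (sqrt(r) * matrix(latent, length(mod$genes), n, byrow = TRUE) +
       sqrt(1 - r) * eps)
    expr[mod$genes, ] <- expr[mod$genes, ] + comp
    truth_mod <- rbind(truth_mod, data.frame(
      gene = mod$genes, module = m,
      trait = ifelse(is.na(mod$trait), NA_character_, mod$trait)))
  }
  b <- betaValues(meth)
  links <- config@methToExpr
  if (nrow(links)) {
    for (k in seq_len(nrow(links))) {
      expr[links$gene[k], ] <- expr[links$gene[k], ] +
        links$slope[k] * b[, links$cpg[k]]
    }
  }
  rownames(expr) <- sprintf("gene_%03d", seq_len(g))
  colnames(expr) <- sampleIds(pheno)
  ExpressionMatrix(expr, metadata = list(groundTruth = list(
    modules = truth_mod, methToExpr = links)))
}

#' Simulate a complete trilayer dataset
#'
#' Runs the four layer generators in dependency order and collects their
#' ground-truth records.
#'
#' @param config a [SimConfig-class].
#' @return list with elements genotypes, phenotype, methylation, expression
#'   and groundTruth.
#' @examples
#' sim <- simulateTrilayer(simConfig(seed = 1))
#' sim$genotypes
#' @export
simulateTrilayer <- function(config = simConfig()) {
  geno <- simulateGenotypes(config)
  pheno <- simulatePhenotype(geno, config)
  meth <- simulateMethylation(geno, pheno, config)
  expr <- simulateExpression(meth, pheno, config)
  list(genotypes = geno, phenotype = pheno, methylation = meth,
       expression = expr,
       groundTruth = c(simMetadata(geno)$groundTruth,
                       simMetadata(pheno)$groundTruth,
                       simMetadata(meth)$groundTruth,
                       simMetadata(expr)$groundTruth))
}
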