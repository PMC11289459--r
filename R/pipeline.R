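# Seeded end-to-end orchestration: simulate -> dmr -> qc/assoc -> meta ->
# meqtl -> triage -> network, with a YAML-configured run directory and a
# manifest of inputs, parameters and per-file hashes.

.defaultRunConfig <- function() {
  list(
    seed = 1,
    out = "trilayer_run",
    stages = c("simulate", "dmr", "assoc", "meta", "meqtl", "triage",
               "network"),
    sim = list(),                       # overrides passed to simConfig()
    dmr = list(B = 200, maxGap = 500, cutoff = NULL,
               covariates = c("age", "sex", "smoking", "cellPC1", "cellPC2")),
    assoc = list(case = "PPMS", ref = "BOMS", r2Threshold = 0.8,
                 alpha = 0.05,
                 covariates = c("sex", "ancestryPC1", "ancestryPC2")),
    meqtl = list(flank = 5e5, adjust = "bonferroni",
                 covariates = c("age", "sex")),
    triage = list(alphaAssoc = 0.05, alphaQtl = 0.05),
    network = list(B = 200, fdr = 0.05, minSize = 10, kMax = 8))
}

#' Read and validate a pipeline run configuration
#'
#' YAML keys mirror [.defaultRunConfig()]: seed, out, stages and one section
#' per stage. Unknown keys are rejected.
#'
#' @param path YAML file (NULL for the defaults).
#' @param overrides named list merged on top.
#' @return validated config list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .defaultRunConfig()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_into <- function(base, new, where) {
    unknown <- setdiff(names(new), names(base))
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    for (nm in names(new)) {
      if (is.list(base[[nm]]) && is.list(new[[nm]]) && nm != "sim")
        base[[nm]] <- merge_into(base[[nm]], new[[nm]], paste0(where, "$", nm))
      else base[[nm]] <- new[[nm]]
    }
    base
  }
  cfg <- merge_into(cfg, user, "config")
  cfg <- merge_into(cfg, overrides, "overrides")
  cfg
}

#' Run the full pipeline on synthetic data
#'
#' Executes the requested stages in dependency order against one simulated
#' trilayer dataset, writes every result table as TSV (with the run seed in a
#' header comment) into the output directory, and records a JSON manifest
#' with parameters, the seed and per-file MD5 hashes. A fixed seed yields
#' bit-identical tables.
#'
#' @param config list from [readRunConfig()] (or NULL for defaults).
#' @param seed optional override of \code{config$seed}.
#' @param out optional override of the output directory.
#' @return (invisibly) a list with the in-memory stage results and the run
#'   directory.
#' @export
runPipeline <- function(config = NULL, seed = NULL, out = NULL) {
  if (is.null(config)) config <- readRunConfig()
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(out)) config$out <- out
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("seed=%d", as.integer(config$seed))
  results <- list()
  written <- character()

  save_tsv <- function(df, name) {
    p <- file.path(config$out, name)
    .writeTsv(df, p, header = hdr)
    written <<- c(written, p)
    p
  }

  stages <- config$stages
  need <- function(stage, what, dep) {
    if (is.null(results[[what]]))
      stop("stage '", stage, "' needs missing upstream output '", what,
           "' (stage '", dep, "')")
  }

  if ("simulate" %in% stages) {
    sim_args <- c(config$sim, list(seed = config$seed))
    sim <- simulateTrilayer(do.call(simConfig, sim_args))
    results$sim <- sim
    writeGenotypes(sim$genotypes, file.path(config$out, "genotypes.tsv"), hdr)
    writeMethylation(sim$methylation, file.path(config$out, "methylation.tsv"), hdr)
    writeExpression(sim$expression, file.path(config$out, "expression.tsv"), hdr)
    writePhenotype(sim$phenotype, file.path(config$out, "phenotype.tsv"), hdr)
    written <- c(written, file.path(config$out, c(
      "genotypes.tsv", "methylation.tsv", "expression.tsv", "phenotype.tsv")))
    jsonlite::write_json(sim$groundTruth,
                         file.path(config$out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    written <- c(written, file.path(config$out, "ground_truth.json"))
  }

  if ("dmr" %in% stages) {
    need("dmr", "sim", "simulate")
    pars <- config$dmr
    des <- dmrDesign(results$sim$phenotype, case = "PPMS",
                     covariates = pars$covariates)
    dmrs <- dmrScan(results$sim$methylation, des, cutoff = pars$cutoff,
                    maxGap = pars$maxGap, B = pars$B)
    results$dmrs <- dmrs
    df <- as.data.frame(dmrs)
    save_tsv(df, "dmr.tsv")
    if (length(dmrs)) {
      writeRegionsBed(dmrs, file.path(config$out, "dmr.bed"))
      written <- c(written, file.path(config$out, "dmr.bed"))
    }
  }

  if ("assoc" %in% stages) {
    need("assoc", "sim", "simulate")
    pars <- config$assoc
    geno <- filterCallRate(results$sim$genotypes)
    pd <- phenoData(results$sim$phenotype)
    covs <- as.matrix(pd[, pars$covariates, drop = FALSE])
    assoc <- logisticAssoc(geno, results$sim$phenotype, covariates = covs,
                           case = pars$case, ref = pars$ref)
    blocks <- clusterLdBlocks(geno, assoc, r2Threshold = pars$r2Threshold)
    thr <- bonferroniByBlocks(pars$alpha, blocks)
    assoc$significant <- !is.na(assoc$p) & assoc$p < thr$threshold
    results$assoc <- assoc
    results$blocks <- blocks
    results$threshold <- thr
    save_tsv(assoc, "assoc.tsv")
    save_tsv(data.frame(
      seed_snp = names(ldBlocks(blocks)),
      members = vapply(ldBlocks(blocks), paste, "", collapse = ","),
      row.names = NULL), "ld_blocks.tsv")
  }

  if ("meta" %in% stages) {
    # the two genotyping batches are analysed separately and pooled
    need("meta", "sim", "simulate")
    pars <- config$assoc
    pd <- phenoData(results$sim$phenotype)
    metas <- list()
    for (snp in snpInfo(results$sim$genotypes)$snp_id) {
      per <- lapply(c("b1", "b2"), function(bt) {
        keep <- which(pd$batch == bt & pd$group %in% c(pars$case, pars$ref))
        a <- tryCatch(
          logisticAssoc(results$sim$genotypes[keep, snp],
                        as.numeric(pd$group[keep] == pars$case)),
          error = function(e) NULL)
        if (is.null(a) || !a$converged[1]) NULL else a
      })
      per <- Filter(Negate(is.null), per)
      if (length(per) == 0) next
      eff <- do.call(rbind, per)
      mr <- metaAnalyze(eff$beta, eff$se)
      mr$snp_id <- snp
      metas[[snp]] <- mr
    }
    meta <- do.call(rbind, metas)
    results$meta <- meta
    save_tsv(meta, "meta.tsv")
  }

  if ("meqtl" %in% stages) {
    need("meqtl", "sim", "simulate")
    need("meqtl", "dmrs", "dmr")
    pars <- config$meqtl
    dmrs <- results$dmrs
    if (length(dmrs) == 0) {
      results$meqtl <- NULL
    } else {
      top <- dmrs[1]
      geno_w <- selectWindow(results$sim$genotypes,
                             as.character(GenomicRanges::seqnames(top)),
                             GenomicRanges::start(top),
                             GenomicRanges::end(top), flank = pars$flank)
      pd <- phenoData(results$sim$phenotype)
      covs <- as.matrix(pd[, pars$covariates, drop = FALSE])
      probes <- probeInfo(results$sim$methylation)$probe_id[
        top$idx_start:top$idx_end]
      qtl <- linearQtlScan(geno_w, results$sim$methylation, covariates = covs,
                           pairs = expand.grid(
                             snp = snpInfo(geno_w)$snp_id,
                             feature = probes, stringsAsFactors = FALSE),
                           adjust = pars$adjust)
      results$meqtl <- qtl
      save_tsv(qtl, "meqtl.tsv")
    }
  }

  if ("triage" %in% stages) {
    need("triage", "assoc", "assoc")
    need("triage", "meqtl", "meqtl")
    pars <- config$triage
    gt <- results$sim$groundTruth
    # external expression-QTL annotation derived from the simulated
    # methylation->expression couplings (sign of slope x meQTL direction)
    links <- gt$methToExpr
    qtl_best <- results$meqtl[order(results$meqtl$p), ]
    qtl_best <- qtl_best[!duplicated(qtl_best$snp_id), ]
    eqtl <- do.call(rbind, lapply(seq_len(nrow(links)), function(k) {
      data.frame(snp_id = qtl_best$snp_id,
                 gene = sprintf("gene_%03d", links$gene[k]),
                 effect = sign(links$slope[k]) * sign(qtl_best$beta),
                 significant = qtl_best$p_adj < pars$alphaQtl,
                 stringsAsFactors = FALSE)
    }))
    tri <- concordanceTriage(results$assoc, qtl_best, eqtl,
                             blocks = results$blocks,
                             alphaAssoc = pars$alphaAssoc,
                             alphaQtl = pars$alphaQtl)
    results$triage <- tri
    save_tsv(tri$records, "triage.tsv")
    save_tsv(tri$summary, "triage_summary.tsv")
  }

  if ("network" %in% stages) {
    need("network", "sim", "simulate")
    pars <- config$network
    net <- permutationEdgeFilter(results$sim$expression, B = pars$B,
                                 qThreshold = pars$fdr,
                                 seed = .stageSeed(config$seed, "network"))
    pmfg <- buildPmfg(net)
    tree <- multiscaleCluster(pmfg, minSize = pars$minSize, kMax = pars$kMax)
    grp <- phenoData(results$sim$phenotype)$group
    traits <- data.frame(PPMS = as.integer(grp == "PPMS"),
                         BOMS = as.integer(grp == "BOMS"),
                         HC = as.integer(grp == "HC"))
    mta <- moduleTraitAssociation(tree, results$sim$expression, traits,
                                  qThreshold = pars$fdr)
    results$network <- net
    results$pmfg <- pmfg
    results$modules <- tree
    results$moduleTrait <- mta
    save_tsv(networkEdges(pmfg), "pmfg_edges.tsv")
    lm <- leafModules(tree)
    save_tsv(data.frame(gene = names(lm), module = unname(lm)),
             "modules.tsv")
    save_tsv(mta, "module_trait.tsv")
  }

  manifest <- list(
    seed = config$seed,
    stages = stages,
    parameters = config[setdiff(names(config), c("seed", "out", "stages"))],
    files = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(results, list(runDir = config$out)))
}
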