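# Co-expression network pipeline: Spearman correlation matrix, permutation-FDR
# edge filtering, planar maximally filtered graph, multiscale non-overlapping
# module detection, module-eigengene trait association, and Fisher overlap
# enrichment.

#' Gene-gene Spearman correlation matrix
#'
#' Symmetric matrix of Spearman rank correlations over samples, with average
#' ranks for ties; genes with zero variance are excluded with a message.
#'
#' @param expr an [ExpressionMatrix-class] or genes x samples matrix.
#' @return correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(expr) {
  E <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  if (ncol(E) < 3) stop("need at least 3 samples")
  if (is.null(rownames(E))) rownames(E) <- sprintf("gene_%03d", seq_len(nrow(E)))
  v <- apply(E, 1, var)
  if (any(v == 0)) {
    message("excluding ", sum(v == 0), " zero-variance gene(s)")
    E <- E[v > 0, , drop = FALSE]
  }
  cor(t(E), method = "spearman")
}

#' Permutation-FDR edge filter
#'
#' Builds the null distribution of |rho| by B sample-label permutations
#' (each gene's values permuted independently, pooled across all gene pairs),
#' assigns every pair an add-one empirical p-value, adjusts across all pairs
#' by Benjamini-Hochberg, and keeps edges with q below the threshold.
#'
#' @param expr an [ExpressionMatrix-class] or genes x samples matrix.
#' @param B number of permutations (>= 100; default 1000).
#' @param qThreshold FDR threshold (default 0.05).
#' @param seed optional seed for the permutation stream.
#' @return a [CorrelationNetwork-class] of the retained edges.
#' @export
permutationEdgeFilter <- function(expr, B = 1000, qThreshold = 0.05,
                                  seed = NULL) {
  if (B < 100) warning("B < 100 gives a very coarse permutation resolution")
  if (!is.null(seed)) set.seed(seed)
  E <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  if (is.null(rownames(E))) rownames(E) <- sprintf("gene_%03d", seq_len(nrow(E)))
  rho <- spearmanMatrix(E)
  genes <- rownames(rho)
  g <- length(genes)
  ut <- upper.tri(rho)
  obs <- abs(rho[ut])
  npair <- length(obs)
  obs_sorted <- sort(obs)
  n <- ncol(E)
  # ranks once; permuting ranks = permuting samples per gene
  R <- t(apply(E[genes, , drop = FALSE], 1, rank))
  R <- (R - rowMeans(R)) / sqrt(rowSums((R - rowMeans(R))^2))
  exceed <- numeric(npair)   # for each obs, how many null |rho| >= it
  for (b in seq_len(B)) {
    Rp <- t(apply(R, 1, function(r) r[sample.int(n)]))
    nullr <- abs(tcrossprod(Rp)[ut])
    # count null values >= each observed value via the sorted observed grid
    cnt <- length(nullr) - findInterval(obs_sorted - 1e-9, sort(nullr))
    exceed <- exceed + cnt[match(obs, obs_sorted)]
  }
  p <- (1 + exceed) / (npair * B + 1)
  q <- p.adjust(p, method = "BH")
  ij <- which(ut, arr.ind = TRUE)
  keep <- q < qThreshold
  edges <- data.frame(node_a = genes[ij[keep, 1]],
                      node_b = genes[ij[keep, 2]],
                      rho = rho[ut][keep], p = p[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  new("CorrelationNetwork", nodes = genes, edges = edges)
}

#' Planar maximally filtered graph
#'
#' Sorts candidate edges by decreasing |rho| (ties broken by lexicographic
#' node pair) and inserts each one iff the graph stays planar, stopping at
#' the planar bound of 3(n - 2) edges. Planarity is checked with the
#' left-right test ([isPlanar()]); edges joining different connected
#' components are accepted without a test since they cannot break planarity.
#'
#' @param network a [CorrelationNetwork-class] (or data.frame with node_a,
#'   node_b, rho).
#' @return a [PMFG-class].
#' @export
buildPmfg <- function(network) {
  if (is(network, "CorrelationNetwork")) {
    nodes <- networkNodes(network)
    ed <- networkEdges(network)
  } else {
    ed <- as.data.frame(network)
    nodes <- sort(unique(c(ed$node_a, ed$node_b)))
  }
  n <- length(nodes)
  if (n < 3) stop("need at least 3 nodes")
  a <- pmin(ed$node_a, ed$node_b)
  b <- pmax(ed$node_a, ed$node_b)
  ord <- order(-abs(ed$rho), a, b)
  ia <- match(a, nodes)[ord]
  ib <- match(b, nodes)[ord]
  rho <- ed$rho[ord]
  maxe <- 3L * (n - 2L)
  acc <- matrix(0L, maxe, 2L)
  acc_rho <- numeric(maxe)
  m <- 0L
  parent <- seq_len(n)                 # union-find for the bridge shortcut
  for (k in seq_along(ia)) {
    if (m >= maxe) break
    u <- ia[k]; v <- ib[k]
    ru <- .ufFind(parent, u); rv <- .ufFind(parent, v)
    if (ru != rv) {
      ok <- TRUE                       # joins two components: always planar
    } else {
      ok <- isPlanar(rbind(acc[seq_len(m), , drop = FALSE], c(u, v)), n)
    }
    if (ok) {
      m <- m + 1L
      acc[m, ] <- c(u, v)
      acc_rho[m] <- rho[k]
      parent[ru] <- rv
    }
  }
  edges <- data.frame(node_a = nodes[acc[seq_len(m), 1]],
                      node_b = nodes[acc[seq_len(m), 2]],
                      rho = acc_rho[seq_len(m)],
                      weight = abs(acc_rho[seq_len(m)]),
                      stringsAsFactors = FALSE)
  new("PMFG", nodes = nodes, edges = edges)
}

#' Multiscale module detection on a PMFG
#'
#' Recursive partitioning: connected components are handled independently;
#' any module with at least 2 x minSize nodes is split by k-medoids
#' (partitioning around medoids) on all-pairs shortest-path distances with
#' edge length 1 - |rho| + 1e-6, choosing k in 2..kMax by maximum mean
#' silhouette width; the split is kept (and recursed into) only if the best
#' mean silhouette reaches \code{silhouetteMin}. Leaves form the
#' non-overlapping module set; internal levels are retained.
#'
#' @param pmfg a [PMFG-class] (any CorrelationNetwork-like edge list works).
#' @param minSize smallest module worth splitting further (default 10).
#' @param kMax largest number of children per split (default 8).
#' @param silhouetteMin minimum mean silhouette to accept a split. The
#'   default 0.5 follows the classic silhouette interpretation (mean width
#'   above 0.5 indicating reasonable structure); permissive values near 0.2
#'   recursively shatter genuinely cohesive modules on sparse planar graphs.
#' @return a [ModuleTree-class].
#' @export
multiscaleCluster <- function(pmfg, minSize = 10, kMax = 8,
                              silhouetteMin = 0.5) {
  nodes <- networkNodes(pmfg)
  ed <- networkEdges(pmfg)
  if (length(nodes) == 0) stop("empty graph")
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$node_a, to = ed$node_b,
               weight = 1 - abs(ed$rho) + 1e-6),
    directed = FALSE, vertices = nodes)
  D <- igraph::distances(g)
  tree_nodes <- data.frame(id = character(), parent = character(),
                           size = integer(), silhouette = numeric(),
                           leaf = logical(), stringsAsFactors = FALSE)
  members <- list()
  add_node <- function(id, parent, genes, sil, leaf) {
    tree_nodes <<- rbind(tree_nodes, data.frame(
      id = id, parent = parent, size = length(genes), silhouette = sil,
      leaf = leaf, stringsAsFactors = FALSE))
    members[[id]] <<- genes
  }
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("M%03d", counter)
  }
  recurse <- function(genes, parent) {
    id <- next_id()
    # split disconnected parts first
    Dsub <- D[genes, genes, drop = FALSE]
    comp_ids <- .componentsOf(Dsub)
    if (max(comp_ids) > 1L) {
      add_node(id, parent, genes, NA_real_, leaf = FALSE)
      for (cc in seq_len(max(comp_ids)))
        recurse(genes[comp_ids == cc], id)
      return(invisible())
    }
    if (length(genes) < 2 * minSize) {
      add_node(id, parent, genes, NA_real_, leaf = TRUE)
      return(invisible())
    }
    best <- NULL
    best_sil <- -Inf
    for (k in 2:min(kMax, length(genes) - 1)) {
      fit <- cluster::pam(stats::as.dist(Dsub), k = k, diss = TRUE,
                          pamonce = 5)
      sw <- fit$silinfo$avg.width
      if (sw > best_sil) {
        best_sil <- sw
        best <- fit$clustering
      }
    }
    if (best_sil >= silhouetteMin) {
      add_node(id, parent, genes, best_sil, leaf = FALSE)
      for (k in sort(unique(best)))
        recurse(genes[best == k], id)
    } else {
      add_node(id, parent, genes, best_sil, leaf = TRUE)
    }
    invisible()
  }
  recurse(nodes, NA_character_)
  new("ModuleTree", nodes = tree_nodes, members = members)
}

# connected components from a (possibly Inf-valued) distance matrix
.componentsOf <- function(D) {
  n <- nrow(D)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    comp[is.finite(D[i, ])] <- cur
  }
  comp
}

#' Principal components with a fixed sign convention
#'
#' Standardizes the columns, computes the top-k principal components and
#' fixes the sign of PC1 so that its correlation with the row-wise mean
#' profile is non-negative.
#'
#' @param m observations x variables matrix.
#' @param k number of components (default 2).
#' @return list with `scores` (observations x k), `varFrac` (variance
#'   fractions) and `center`/`scale` used.
#' @export
principalComponents <- function(m, k = 2) {
  m <- as.matrix(m)
  v <- apply(m, 2, var)
  if (all(v == 0)) stop("constant matrix")
  if (any(v == 0)) m <- m[, v > 0, drop = FALSE]
  k <- min(k, nrow(m) - 1L, ncol(m))
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  profile <- rowMeans(scale(m))
  if (sd(scores[, 1]) > 0 && sd(profile) > 0 &&
      cor(scores[, 1], profile) < 0) {
    scores[, 1] <- -scores[, 1]
  }
  list(scores = scores, varFrac = varfrac[seq_len(k)])
}

#' Module eigengene-trait association
#'
#' For every leaf module with at least 2 genes, computes the first principal
#' component of its gene x sample submatrix (the module eigengene) and its
#' Spearman correlation with each binary trait indicator; p-values are
#' adjusted by Benjamini-Hochberg across all module x trait tests.
#'
#' @param tree a [ModuleTree-class].
#' @param expr an [ExpressionMatrix-class].
#' @param traits data.frame of 0/1 indicator columns, one row per sample (in
#'   the expression column order).
#' @param method correlation method, "spearman" (default) or "pearson".
#' @param qThreshold flag threshold (default 0.05).
#' @return data.frame: module, trait, pc1_var, cor, p, q, flagged.
#' @export
moduleTraitAssociation <- function(tree, expr, traits, method = "spearman",
                                   qThreshold = 0.05) {
  E <- exprValues(expr)
  traits <- as.data.frame(traits)
  stopifnot(nrow(traits) == ncol(E))
  mem <- moduleMembers(tree)
  leaves <- tree@nodes$id[tree@nodes$leaf]
  rows <- list()
  for (mod in leaves) {
    genes <- intersect(mem[[mod]], rownames(E))
    if (length(genes) < 2) {
      message("module ", mod, " has fewer than 2 genes; skipped")
      next
    }
    pc <- principalComponents(t(E[genes, , drop = FALSE]), k = 1)
    eig <- pc$scores[, 1]
    for (tr in names(traits)) {
      ct <- suppressWarnings(
        stats::cor.test(eig, traits[[tr]], method = method, exact = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        module = mod, trait = tr, pc1_var = pc$varFrac[1],
        cor = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$flagged <- out$q < qThreshold
  out
}

#' Fisher exact overlap test between two gene sets
#'
#' Cross-classifies the universe by membership in A and B, reports the
#' two-sided Fisher exact p-value and the sample odds ratio (with Haldane's
#' 0.5 correction if and only if the table has a zero cell, flagged).
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return list: nA, nB, universe, overlap, or, p.value, haldane.
#' @examples
#' fisherOverlap(letters[1:5], letters[1:5], letters[1:20])$p.value
#' @export
fisherOverlap <- function(setA, setB, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  x <- length(intersect(setA, setB))
  tab <- matrix(c(x, length(setA) - x,
                  length(setB) - x,
                  length(universe) - length(setA) - length(setB) + x), 2L)
  p <- fisher.test(tab)$p.value
  haldane <- any(tab == 0)
  tt <- if (haldane) tab + 0.5 else tab
  or <- tt[1, 1] * tt[2, 2] / (tt[1, 2] * tt[2, 1])
  list(nA = length(setA), nB = length(setB), universe = length(universe),
       overlap = x, or = or, p.value = p, haldane = haldane)
}
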