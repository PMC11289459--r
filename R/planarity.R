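#' Test whether an undirected graph is planar
#'
#' Left-right planarity test (Brandes' formulation of the
#' de Fraysseix--Rosenstiehl criterion). The test runs in O(n + m) per call
#' and is the predicate behind [buildPmfg()].
#'
#' @param edges two-column integer matrix of undirected edges (vertex indices
#'   in \code{1..n}); parallel edges and self-loops are not allowed.
#' @param n number of vertices. Isolated vertices are irrelevant to planarity
#'   but must be counted for the Euler bound.
#' @return \code{TRUE} if the graph admits a planar embedding.
#' @details Graphs with fewer than 9 edges are always planar (the smallest
#'   non-planar graphs, K5 and K3,3, have 10 and 9 edges); graphs with
#'   \code{m > 3n - 6} never are. Both shortcuts are applied before the full
#'   two-pass DFS test.
#' @examples
#' k4 <- t(combn(4, 2))
#' isPlanar(k4, 4)          # TRUE
#' k5 <- t(combn(5, 2))
#' isPlanar(k5, 5)          # FALSE
#' @export
isPlanar <- function(edges, n) {
  edges <- .asEdgeMatrix(edges)
  m <- nrow(edges)
  if (m <= 8L) return(TRUE)
  if (n >= 3L && m > 3L * n - 6L) return(FALSE)
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed")
  .lrPlanarityCpp(edges, as.integer(n))
}

.asEdgeMatrix <- function(edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) return(matrix(integer(), 0L, 2L))
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "integer"
  edges
}

# Pure-R reference implementation of the same left-right test; the package
# calls the compiled version, this one backs the cross-implementation tests.
.lrPlanarityR <- function(n, edges) {
  m <- nrow(edges)

  nbr <- vector("list", n)
  eid <- vector("list", n)
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), n)
  for (v in seq_len(n)) {
    nbr[[v]] <- integer(deg[v])
    eid[[v]] <- integer(deg[v])
  }
  fill <- integer(n)
  for (k in seq_len(m)) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    fill[a] <- fill[a] + 1L; nbr[[a]][fill[a]] <- b; eid[[a]][fill[a]] <- k
    fill[b] <- fill[b] + 1L; nbr[[b]][fill[b]] <- a; eid[[b]][fill[b]] <- k
  }

  height <- rep(NA_integer_, n)
  parentEdge <- integer(n)            # 0 = none
  oriented <- logical(m)
  esrc <- integer(m); edst <- integer(m)
  lowpt <- integer(m); lowpt2 <- integer(m); nesting <- integer(m)

  dfs1 <- function(v) {
    e <- parentEdge[v]
    hv <- height[v]
    ws <- nbr[[v]]; ids <- eid[[v]]
    for (k in seq_along(ws)) {
      id <- ids[k]
      if (oriented[id]) next
      w <- ws[k]
      oriented[id] <<- TRUE
      esrc[id] <<- v; edst[id] <<- w
      lowpt[id] <<- hv; lowpt2[id] <<- hv
      if (is.na(height[w])) {              # tree edge
        parentEdge[w] <<- id
        height[w] <<- hv + 1L
        dfs1(w)
      } else {                             # back edge
        lowpt[id] <<- height[w]
      }
      nesting[id] <<- 2L * lowpt[id] + (lowpt2[id] < hv)
      if (e > 0L) {
        if (lowpt[id] < lowpt[e]) {
          lowpt2[e] <<- min(lowpt[e], lowpt2[id])
          lowpt[e] <<- lowpt[id]
        } else if (lowpt[id] > lowpt[e]) {
          lowpt2[e] <<- min(lowpt2[e], lowpt[id])
        } else {
          lowpt2[e] <<- min(lowpt2[e], lowpt2[id])
        }
      }
    }
  }

  roots <- integer(0)
  for (v in seq_len(n)) {
    if (is.na(height[v]) && deg[v] > 0L) {
      height[v] <- 0L
      roots <- c(roots, v)
      dfs1(v)
    }
  }

  # outgoing adjacency sorted by nesting depth
  orderedAdj <- vector("list", n)
  for (id in order(nesting[seq_len(m)])) {
    v <- esrc[id]
    orderedAdj[[v]] <- c(orderedAdj[[v]], id)
  }

  # conflict-pair stack: columns Llow, Lhigh, Rlow, Rhigh + serial id
  cap <- m + 4L
  S <- matrix(0L, nrow = 4L, ncol = cap)
  Sid <- integer(cap)
  sp <- 0L
  serial <- 0L
  ref <- integer(m)
  lowptEdge <- integer(m)
  stackBottom <- integer(m)

  push <- function(ll, lh, rl, rh) {
    sp <<- sp + 1L
    serial <<- serial + 1L
    S[1L, sp] <<- ll; S[2L, sp] <<- lh; S[3L, sp] <<- rl; S[4L, sp] <<- rh
    Sid[sp] <<- serial
  }
  topId <- function() if (sp > 0L) Sid[sp] else 0L

  conflicting <- function(lo, hi, b) {
    hi != 0L && lowpt[hi] > lowpt[b]
  }
  lowestTop <- function() {
    ll <- S[1L, sp]; rl <- S[3L, sp]
    if (ll == 0L && S[2L, sp] == 0L) {
      if (rl == 0L) return(-1L)            # fully empty pair: no return point
      return(lowpt[rl])
    }
    if (rl == 0L && S[4L, sp] == 0L) return(lowpt[ll])
    min(lowpt[ll], lowpt[rl])
  }

  addConstraints <- function(ei, e) {
    Pll <- 0L; Plh <- 0L; Prl <- 0L; Prh <- 0L
    # merge return edges of ei into the right interval of P
    repeat {
      Qll <- S[1L, sp]; Qlh <- S[2L, sp]; Qrl <- S[3L, sp]; Qrh <- S[4L, sp]
      sp <<- sp - 1L
      if (!(Qll == 0L && Qlh == 0L)) {
        tmp <- Qll; Qll <- Qrl; Qrl <- tmp
        tmp <- Qlh; Qlh <- Qrh; Qrh <- tmp
      }
      if (!(Qll == 0L && Qlh == 0L)) return(FALSE)   # not planar
      if (lowpt[Qrl] > lowpt[e]) {
        if (Prl == 0L && Prh == 0L) Prh <- Qrh else ref[Prl] <<- Qrh
        Prl <- Qrl
      } else {                                       # align
        ref[Qrl] <<- lowptEdge[e]
      }
      if (topId() == stackBottom[ei]) break
    }
    # merge conflicting return edges of earlier siblings into the left side
    while (sp > 0L &&
           (conflicting(S[1L, sp], S[2L, sp], ei) ||
            conflicting(S[3L, sp], S[4L, sp], ei))) {
      Qll <- S[1L, sp]; Qlh <- S[2L, sp]; Qrl <- S[3L, sp]; Qrh <- S[4L, sp]
      sp <<- sp - 1L
      if (conflicting(Qrl, Qrh, ei)) {
        tmp <- Qll; Qll <- Qrl; Qrl <- tmp
        tmp <- Qlh; Qlh <- Qrh; Qrh <- tmp
      }
      if (conflicting(Qrl, Qrh, ei)) return(FALSE)   # not planar
      if (Prl != 0L) ref[Prl] <<- Qrh                # merge below lowpt(ei)
      if (Qrl != 0L) Prl <- Qrl
      if (Pll == 0L && Plh == 0L) Plh <- Qlh else ref[Pll] <<- Qlh
      Pll <- Qll
    }
    if (!(Pll == 0L && Plh == 0L && Prl == 0L && Prh == 0L))
      push(Pll, Plh, Prl, Prh)
    TRUE
  }

  removeBackEdges <- function(e) {
    u <- esrc[e]
    # drop conflict pairs whose lowest return point is u
    while (sp > 0L && lowestTop() == height[u]) sp <<- sp - 1L
    if (sp > 0L) {                                   # trim the next pair
      Pll <- S[1L, sp]; Plh <- S[2L, sp]; Prl <- S[3L, sp]; Prh <- S[4L, sp]
      pid <- Sid[sp]                                 # keep identity on re-push
      sp <<- sp - 1L
      while (Plh != 0L && edst[Plh] == u) Plh <- ref[Plh]
      if (Plh == 0L && Pll != 0L) {                  # left just emptied
        ref[Pll] <<- Prl
        Pll <- 0L
      }
      while (Prh != 0L && edst[Prh] == u) Prh <- ref[Prh]
      if (Prh == 0L && Prl != 0L) {                  # right just emptied
        ref[Prl] <<- Pll
        Prl <- 0L
      }
      sp <<- sp + 1L
      S[1L, sp] <<- Pll; S[2L, sp] <<- Plh; S[3L, sp] <<- Prl; S[4L, sp] <<- Prh
      Sid[sp] <<- pid
    }
    # the side of e follows the highest remaining return edge
    if (lowpt[e] < height[u] && sp > 0L) {
      hl <- S[2L, sp]; hr <- S[4L, sp]
      if (hl != 0L && (hr == 0L || lowpt[hl] > lowpt[hr])) ref[e] <<- hl
      else ref[e] <<- hr
    }
  }

  dfs2 <- function(v) {
    e <- parentEdge[v]
    oa <- orderedAdj[[v]]
    for (k in seq_along(oa)) {
      ei <- oa[k]
      stackBottom[ei] <<- topId()
      w <- edst[ei]
      if (ei == parentEdge[w]) {           # tree edge
        if (!dfs2(w)) return(FALSE)
      } else {                             # back edge
        lowptEdge[ei] <<- ei
        push(0L, 0L, ei, ei)
      }
      if (lowpt[ei] < height[v]) {         # ei has a return edge
        if (k == 1L) {
          lowptEdge[e] <<- lowptEdge[ei]
        } else if (!addConstraints(ei, e)) {
          return(FALSE)
        }
      }
    }
    if (e > 0L) removeBackEdges(e)
    TRUE
  }

  for (v in roots) {
    if (!dfs2(v)) return(FALSE)
  }
  TRUE
}
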