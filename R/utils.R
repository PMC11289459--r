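# internal helpers

# stage-specific seed derived from a run seed; kept well below 2^31
.stageSeed <- function(seed, stage) {
  offsets <- c(genotypes = 101L, phenotype = 211L, methylation = 307L,
               expression = 401L, dmr = 503L, network = 601L, qtl = 701L)
  (as.integer(seed) %% 100000000L) * 10L + offsets[[stage]] %% 10L +
    offsets[[stage]] * 1000L
}

.clip <- function(x, lo = 0.001, hi = 0.999) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# OLS of each column of Y on a common design X; returns the coefficient,
# standard error and t statistic of column `which` of X for every response.
.olsScan <- function(X, Y, which) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("fewer residual degrees of freedom than design columns")
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  XtXinv <- chol2inv(qr.R(qrX))
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(XtXinv[which, which] * sigma2)
  b <- coefs[which, ]
  t <- b / se
  data.frame(coef = b, se = se, t = t,
             p = 2 * pt(-abs(t), df), row.names = colnames(Y))
}

# union-find with path compression (used by the PMFG edge pre-screen)
.ufFind <- function(parent, x) {
  while (parent[x] != x) {
    parent[x] <- parent[parent[x]]
    x <- parent[x]
  }
  x
}
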