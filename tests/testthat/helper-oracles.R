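# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical routines (quadrature instead of adaptive
# integration, grid search instead of root finding, step-up enumeration
# instead of p.adjust).

# 2-D Gauss-Legendre quadrature of the standard bivariate normal density
# over [lo1, 8] x [lo2, 8] (upper orthant probability).
gl_orthant <- function(lo1, lo2, rho, nodes = 48) {
  gl <- function(n) {
    # Golub-Welsch via eigen decomposition of the Jacobi matrix
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    list(x = e$values, w = 2 * e$vectors[1, ]^2)
  }
  q <- gl(nodes)
  map <- function(lo, hi) list(x = (hi - lo) / 2 * q$x + (hi + lo) / 2,
                               w = (hi - lo) / 2 * q$w)
  g1 <- map(lo1, 8); g2 <- map(lo2, 8)
  dens <- function(x, y) {
    det <- 1 - rho^2
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * det)) / (2 * pi * sqrt(det))
  }
  total <- 0
  for (i in seq_along(g1$x)) {
    total <- total + g1$w[i] * sum(g2$w * dens(g1$x[i], g2$x))
  }
  total
}

# Brute-force ML tetrachoric: grid search over rho matching the observed
# 1-1 cell proportion under thresholds at the marginal quantiles.
oracle_tetrachoric <- function(counts, tol = 1e-4) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  p1 <- sum(counts[2, ]) / n
  p2 <- sum(counts[, 2]) / n
  t1 <- qnorm(1 - p1); t2 <- qnorm(1 - p2)
  target <- counts[2, 2] / n
  f <- function(r) gl_orthant(t1, t2, r) - target
  grid <- seq(-0.995, 0.995, by = 0.01)
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(abs(vals))
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  while (hi - lo > tol) {
    mids <- seq(lo, hi, length.out = 11)
    v <- vapply(mids, f, numeric(1))
    j <- which.min(abs(v))
    lo <- mids[max(j - 1, 1)]; hi <- mids[min(j + 1, length(mids))]
  }
  (lo + hi) / 2
}

# Closed form for symmetric margins (p = 0.5 on both): rho = sin(2 pi (p11 - 1/4)).
closed_form_tetrachoric_symmetric <- function(p11) sin(2 * pi * (p11 - 0.25))

# Brute-force Benjamini-Hochberg step-up.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0, which(ps <= seq_len(m) / m * q)))
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# Hand-computed KMO for an equicorrelated p x p matrix with correlation r:
# all partial correlations equal r / (1 + (p - 2) r).
oracle_kmo_equicorrelated <- function(p, r) {
  q <- r / (1 + (p - 2) * r)
  npair <- p * (p - 1)
  (npair * r^2) / (npair * r^2 + npair * q^2)
}

# Multivariate normal draw via Cholesky (test-local).
draw_mvn <- function(n, Sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(n * ncol(Sigma)), n)
  X <- Z %*% chol(Sigma)
  colnames(X) <- colnames(Sigma)
  X
}

# Default-scale synthetic cohort used by several files (kept small).
test_cohort <- function(n = 892, seed = 11) {
  generate_cohort(cohort_config(), n = n, seed = seed)
}
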