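# Internal numerical helpers shared across modules.

#' Standard bivariate normal CDF
#'
#' Lower orthant probability P(X <= h, Y <= k) for a standard bivariate
#' normal with correlation `rho`, evaluated by adaptive quadrature of the
#' conditional-normal representation. Accurate to well below 1e-8, which is
#' ample for tetrachoric root-finding.
#'
#' @param h,k upper integration limits.
#' @param rho correlation in (-1, 1).
#' @return probability in `[0, 1]`.
#' @keywords internal
pbvnorm <- function(h, k, rho) {
  if (abs(rho) >= 1) {
    # degenerate: X = +/- Y
    if (rho >= 1) return(stats::pnorm(min(h, k)))
    return(max(0, stats::pnorm(h) - stats::pnorm(-k)))
  }
  if (!is.finite(h) && h > 0) return(stats::pnorm(k))
  if (!is.finite(k) && k > 0) return(stats::pnorm(h))
  if ((is.finite(h) && h < -8.5) || (is.finite(k) && k < -8.5)) return(0)
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / s)
  stats::integrate(f, -Inf, h, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Tucker congruence coefficient between two loading vectors.
congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Align a loading matrix to a target
#'
#' Factor order and sign are arbitrary after extraction/rotation. Greedily
#' matches columns of `L` to columns of `target` on absolute Tucker
#' congruence, then flips signs so matched congruences are positive.
#'
#' @param L loading matrix to align (variables x factors).
#' @param target loading matrix defining the desired order/orientation.
#' @return aligned loading matrix with the same dimensions as `L`.
#' @export
align_loadings <- function(L, target) {
  L <- as.matrix(L); target <- as.matrix(target)
  stopifnot(nrow(L) == nrow(target), ncol(L) == ncol(target))
  k <- ncol(L)
  cong <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cong[i, j] <- congruence(target[, i], L[, j])
  perm <- integer(k); used <- logical(k)
  for (i in order(-apply(abs(cong), 1, max))) {
    j <- which.max(ifelse(used, -Inf, abs(cong[i, ])))
    perm[i] <- j; used[j] <- TRUE
  }
  out <- L[, perm, drop = FALSE]
  for (i in seq_len(k)) if (cong[i, perm[i]] < 0) out[, i] <- -out[, i]
  dimnames(out) <- dimnames(target)
  out
}

# Orient each factor so its largest-magnitude loading is positive.
orient_loadings <- function(L, return_flips = FALSE) {
  L <- as.matrix(L)
  flip <- apply(L, 2, function(col) col[which.max(abs(col))] < 0)
  L[, flip] <- -L[, flip, drop = FALSE]
  if (return_flips) attr(L, "flipped") <- flip
  L
}

# Derive a reproducible child seed (< 2^31) from a parent seed and a stage
# index; documented counter scheme used by run_pipeline().
child_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + 7919 * as.double(stage)) %% 2147483647
}

# Eigenvalue-clipping PD smoothing with re-normalization to unit diagonal.
# Returns list(mat, smoothed, floor, max_change).
smooth_correlation <- function(R, floor = 1e-6, max_change = 0.05) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) {
    return(list(mat = R, smoothed = FALSE, floor = floor, max_change = 0))
  }
  # clip-and-renormalize can push an eigenvalue slightly back under the
  # floor, so iterate with a small safety margin
  S <- R
  for (i in 1:20) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) >= floor) break
    vals <- pmax(e$values, floor * 2)
    S <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
    d <- sqrt(diag(S))
    S <- S / tcrossprod(d)
    diag(S) <- 1
  }
  delta <- max(abs(S - R))
  if (delta > max_change) {
    stop(sprintf(
      "PD smoothing would change an entry by %.4f (> cap %.4f)", delta, max_change
    ))
  }
  dimnames(S) <- dimnames(R)
  list(mat = S, smoothed = TRUE, floor = floor, max_change = delta)
}

# Proportion -> threshold on the liability scale: P(Z > tau) = prevalence.
liability_threshold <- function(prevalence) stats::qnorm(1 - prevalence)

`%||%` <- function(a, b) if (is.null(a)) b else a
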