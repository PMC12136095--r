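# Mixed Pearson/tetrachoric/biserial correlation matrices over prepared MRI
# markers, with positive-definiteness smoothing and the Kaiser-Meyer-Olkin
# measure of sampling adequacy.

#' Pearson correlation between two continuous vectors
#'
#' Thin wrapper over [stats::cor()] with the preconditions the matrix
#' builder relies on (length >= 3 after pairwise deletion, non-zero
#' variance).
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  stats::cor(x, y)
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood estimate under a bivariate standard normal liability
#' model with thresholds fixed at the marginal quantiles: solves
#' `P(Z1 > tau1, Z2 > tau2; rho) = p11` by root finding, with bivariate
#' normal probabilities evaluated by quadrature. A 0.5 continuity
#' correction is added to all four cells when any cell is zero.
#'
#' @param counts 2x2 matrix of nonnegative counts; rows index the first
#'   variable (0, 1), columns the second.
#' @param correct continuity correction added to every cell when a zero
#'   cell is present (default 0.5).
#' @return estimate in (-1, 1).
#' @export
tetrachoric <- function(counts, correct = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (sum(counts) == 0) stop("empty table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("tetrachoric undefined: a margin of the 2x2 table is empty")
  }
  if (any(counts == 0)) counts <- counts + correct
  n <- sum(counts)
  p1 <- sum(counts[2, ]) / n   # P(x = 1)
  p2 <- sum(counts[, 2]) / n   # P(y = 1)
  tau1 <- liability_threshold(p1)
  tau2 <- liability_threshold(p2)
  p11 <- counts[2, 2] / n
  # P(Z1 > tau1, Z2 > tau2; rho), increasing in rho
  upper_orthant <- function(rho) pbvnorm(-tau1, -tau2, rho)
  f <- function(rho) upper_orthant(rho) - p11
  lo <- -0.9999; hi <- 0.9999
  if (f(lo) > 0) return(-1 + 1e-6)
  if (f(hi) < 0) return(1 - 1e-6)
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Biserial correlation between a continuous and a binary variable
#'
#' Point-biserial correlation rescaled under the normal-liability model:
#' `r_b = (m1 - m0) / s_x * p * (1 - p) / phi(qnorm(p))`. Estimates outside
#' `[-1, 1]` are clamped with a warning.
#'
#' @param x continuous vector.
#' @param y binary (0/1) vector.
#' @return biserial estimate in `[-1, 1]`.
#' @export
biserial <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- as.integer(y[ok] > 0)
  if (length(unique(y)) < 2) stop("biserial undefined: single-class binary variable")
  if (stats::sd(x) == 0) stop("zero-variance continuous input")
  p <- mean(y)
  m1 <- mean(x[y == 1]); m0 <- mean(x[y == 0])
  sx <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  r <- (m1 - m0) / sx * p * (1 - p) / stats::dnorm(stats::qnorm(p))
  if (abs(r) > 1) {
    warning("biserial estimate ", signif(r, 4), " outside [-1, 1]; clamped")
    r <- sign(r)
  }
  r
}

#' Mixed correlation matrix over prepared markers
#'
#' Dispatches per pair on the declared variable kinds: Pearson between
#' continuous pairs, tetrachoric between binary pairs, biserial between
#' continuous and binary. Eigenvalue-clipping smoothing (floor `pd_floor`,
#' re-normalized to unit diagonal) is applied when the assembled matrix is
#' not positive definite; the raw matrix is kept alongside for
#' inversion-free consumers (minres).
#'
#' @param table data.frame of prepared indicators (continuous z-scores and
#'   0/1 flags).
#' @param kinds named vector of `"continuous"` / `"binary"` over the columns
#'   to include (default: all columns named in [default_marker_kinds()] that
#'   are present).
#' @param use `"listwise"` (default) or `"pairwise"` deletion.
#' @param pd_floor eigenvalue floor for smoothing.
#' @param smooth_cap maximum entry change smoothing may introduce.
#' @return object of class `mixed_cor`: list with `rho` (smoothed), `raw`,
#'   `kind` (pair-kind matrix), `smoothing`, `n`.
#' @export
mixed_cor <- function(table, kinds = NULL, use = c("listwise", "pairwise"),
                      pd_floor = 1e-6, smooth_cap = 0.05) {
  use <- match.arg(use)
  if (is.null(kinds)) {
    dk <- default_marker_kinds()
    kinds <- dk[intersect(names(dk), names(table))]
  }
  vars <- names(kinds)
  if (length(vars) < 2) stop("need at least 2 variables")
  dat <- as.data.frame(table)[vars]
  if (use == "listwise") dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  p <- length(vars)
  rho <- diag(p)
  kindmat <- matrix("", p, p, dimnames = list(vars, vars))
  diag(kindmat) <- "unit"
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    xi <- dat[[i]]; xj <- dat[[j]]
    ok <- stats::complete.cases(xi, xj)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for ", vars[i], " x ", vars[j])
    ki <- kinds[[i]]; kj <- kinds[[j]]
    r <- tryCatch({
      if (ki == "continuous" && kj == "continuous") {
        kindmat[i, j] <- kindmat[j, i] <- "pearson"
        pearson_cor(xi, xj)
      } else if (ki == "binary" && kj == "binary") {
        kindmat[i, j] <- kindmat[j, i] <- "tetrachoric"
        tetrachoric(table(factor(xi[ok], 0:1), factor(xj[ok], 0:1)))
      } else {
        kindmat[i, j] <- kindmat[j, i] <- "biserial"
        if (ki == "continuous") biserial(xi, xj) else biserial(xj, xi)
      }
    }, error = function(e) {
      stop(sprintf("correlation failed for pair (%s, %s): %s",
                   vars[i], vars[j], conditionMessage(e)), call. = FALSE)
    })
    rho[i, j] <- rho[j, i] <- r
  }
  dimnames(rho) <- list(vars, vars)
  sm <- smooth_correlation(rho, floor = pd_floor, max_change = smooth_cap)
  structure(
    list(rho = sm$mat, raw = rho, kind = kindmat,
         smoothing = list(applied = sm$smoothed, floor = pd_floor,
                          max_change = sm$max_change),
         n = nrow(dat), use = use, variables = vars, kinds = kinds),
    class = "mixed_cor"
  )
}

#' @export
print.mixed_cor <- function(x, digits = 2, ...) {
  cat(sprintf("Mixed correlation matrix: %d variables, n = %d (%s deletion)\n",
              length(x$variables), x$n, x$use))
  tk <- table(x$kind[upper.tri(x$kind)])
  cat("Pair kinds:", paste(names(tk), tk, sep = "=", collapse = ", "), "\n")
  if (x$smoothing$applied) {
    cat(sprintf("PD smoothing applied (floor %.1e, max entry change %.4f)\n",
                x$smoothing$floor, x$smoothing$max_change))
  }
  print(round(x$rho, digits))
  invisible(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal pairs,
#' where `q_ij` are the anti-image partial correlations obtained from the
#' inverse correlation matrix. Per-variable measures use the corresponding
#' row sums. An (effectively) diagonal matrix yields the 0/0 limit; by
#' convention 0 is returned with a "not factorable" warning.
#'
#' @param R a `mixed_cor` object or correlation matrix.
#' @return list with `overall` and per-variable `msa`.
#' @export
kmo <- function(R) {
  M <- if (inherits(R, "mixed_cor")) R$rho else as.matrix(R)
  M <- smooth_correlation(M)$mat
  inv <- tryCatch(solve(M), error = function(e) {
    stop("correlation matrix singular after smoothing; KMO undefined")
  })
  d <- 1 / sqrt(diag(inv))
  Q <- -inv * tcrossprod(d)   # anti-image partial correlations
  diag(Q) <- 0
  R2 <- M^2; diag(R2) <- 0
  Q2 <- Q^2
  denom <- sum(R2) + sum(Q2)
  if (denom < 1e-12) {
    warning("correlation matrix is (near) diagonal: not factorable; KMO = 0")
    return(list(overall = 0,
                msa = stats::setNames(rep(0, ncol(M)), colnames(M))))
  }
  msa_den <- rowSums(R2) + rowSums(Q2)
  msa <- ifelse(msa_den < 1e-12, 0, rowSums(R2) / msa_den)
  list(overall = sum(R2) / denom,
       msa = stats::setNames(msa, colnames(M)))
}

#' Write a mixed correlation matrix to CSV with a JSON metadata sidecar
#' @param x `mixed_cor` object.
#' @param path output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mixed_cor <- function(x, path) {
  utils::write.csv(as.data.frame(x$rho), path, row.names = TRUE)
  meta <- list(variables = x$variables, kinds = as.list(x$kinds),
               pair_kind = apply(x$kind, 1, as.list),
               smoothing = x$smoothing, n = x$n, use = x$use)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a mixed correlation matrix written by [write_mixed_cor()]
#' @param path CSV path.
#' @return `mixed_cor` object.
#' @export
read_mixed_cor <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  rho <- as.matrix(df)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(rho = rho, raw = rho, kind = do.call(rbind, meta$pair_kind),
         smoothing = meta$smoothing, n = meta$n, use = meta$use,
         variables = meta$variables, kinds = unlist(meta$kinds)),
    class = "mixed_cor"
  )
}
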