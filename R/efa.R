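# Exploratory factor analysis of the MRI markers: minimum-residual
# extraction, VSS/MAP factor-count selection, iterative communality pruning,
# oblimin/varimax rotation with the orthogonality decision rule, salient
# loadings, extension analysis, and regression factor scores.

ledermann_bound <- function(p) floor((2 * p + 1 - sqrt(8 * p + 1)) / 2)

#' Minimum-residual (minres) factor extraction
#'
#' Minimizes the sum of squared off-diagonal residuals of `R - Lambda
#' Lambda'` over the uniquenesses: for a candidate uniqueness vector the
#' loadings are the scaled leading eigenvectors of the reduced matrix
#' `R - diag(psi)`, and the objective is evaluated on the off-diagonal
#' residuals only, so no matrix inversion of `R` is required. Starting
#' communalities are squared multiple correlations from the smoothed matrix.
#'
#' @param R correlation matrix (or `mixed_cor` object).
#' @param k number of factors (`1 <= k`, within the Ledermann bound).
#' @param max_iter optimizer iteration cap.
#' @param tol convergence tolerance on the objective.
#' @return list with `loadings` (variables x k, factors ordered by explained
#'   variance, oriented so the largest loading is positive), `uniquenesses`,
#'   `communalities`, `objective`, `converged`.
#' @export
minres_fit <- function(R, k, max_iter = 1000, tol = 1e-9) {
  Rm <- if (inherits(R, "mixed_cor")) R$raw else as.matrix(R)
  p <- ncol(Rm)
  if (k < 1) stop("k must be >= 1")
  if (k >= p) stop("k must be smaller than the number of variables")
  if (k > ledermann_bound(p)) {
    stop(sprintf("k = %d exceeds the Ledermann identification bound (%d) for p = %d",
                 k, ledermann_bound(p), p))
  }
  vars <- colnames(Rm) %||% paste0("V", seq_len(p))

  loadings_for <- function(psi) {
    Rs <- Rm
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  }
  off <- upper.tri(Rm)
  objective <- function(psi) {
    L <- loadings_for(psi)
    res <- Rm - tcrossprod(L)
    sum(res[off]^2)
  }
  start <- tryCatch({
    Rsm <- smooth_correlation(Rm)$mat
    pmin(pmax(1 / diag(solve(Rsm)), 1e-3), 1)   # 1 - SMC
  }, error = function(e) rep(0.5, p))
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = 1e-4, upper = 1,
                      control = list(maxit = max_iter, factr = 10))
  if (opt$convergence != 0) {
    # retry once from the best iterate (L-BFGS-B line searches can stall
    # at essentially-converged points, code 52)
    opt2 <- stats::optim(opt$par, objective, method = "L-BFGS-B",
                         lower = 1e-4, upper = 1,
                         control = list(maxit = max_iter, factr = 1e3))
    if (opt2$value <= opt$value) opt <- opt2
  }
  L <- loadings_for(opt$par)
  if (opt$convergence != 0) {
    # L-BFGS-B line searches can stall (code 52) at essentially-converged
    # points; accept if the KKT projected gradient is negligible
    h <- 1e-6
    viol <- vapply(seq_along(opt$par), function(ii) {
      up <- dn <- opt$par
      up[ii] <- min(up[ii] + h, 1); dn[ii] <- max(dn[ii] - h, 1e-4)
      g <- (objective(up) - objective(dn)) / (up[ii] - dn[ii])
      at_upper <- opt$par[ii] >= 1 - 1e-8
      at_lower <- opt$par[ii] <= 1e-4 + 1e-8
      if (at_upper) max(g, 0) else if (at_lower) max(-g, 0) else abs(g)
    }, numeric(1))
    if (max(viol) > 1e-3 && opt$value > 1e-6) {
      stop(sprintf("minres did not converge (code %d, objective %.3e); best iterate attached",
                   opt$convergence, opt$value),
           call. = FALSE)
    }
  }
  # order factors by explained variance, fix signs
  ss <- colSums(L^2)
  L <- L[, order(-ss), drop = FALSE]
  L <- orient_loadings(L)
  h2 <- rowSums(L^2)
  dimnames(L) <- list(vars, paste0("factor", seq_len(k)))
  list(loadings = L,
       uniquenesses = stats::setNames(1 - h2, vars),
       communalities = stats::setNames(h2, vars),
       objective = opt$value, converged = TRUE, k = k)
}

#' Velicer's minimum average partial (MAP) criterion
#'
#' For each number of retained principal components `k`, partials the first
#' `k` components out of `R` and averages the squared off-diagonal partial
#' correlations; the suggested factor count minimizes this average. A
#' minimum at `k = 0` means the matrix carries no common variance
#' (flagged via attribute `no_common_factors`).
#'
#' @param R correlation matrix or `mixed_cor`.
#' @param k_max largest count to examine.
#' @return integer suggestion with attributes `profile` (values for
#'   k = 0..k_max) and `no_common_factors`.
#' @export
map_criterion <- function(R, k_max) {
  Rm <- if (inherits(R, "mixed_cor")) R$rho else as.matrix(R)
  p <- ncol(Rm)
  if (k_max >= p) stop("k_max must be smaller than the number of variables")
  e <- eigen(Rm, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  off <- upper.tri(Rm)
  avg_sq <- numeric(k_max + 1)
  avg_sq[1] <- mean(Rm[off]^2)
  if (avg_sq[1] <= 1e-12) {
    # already at the unimprovable minimum: no common variance to partial out
    return(structure(0L, profile = stats::setNames(avg_sq[1], 0),
                     no_common_factors = TRUE))
  }
  for (k in seq_len(k_max)) {
    C <- Rm - tcrossprod(A[, seq_len(k), drop = FALSE])
    d <- diag(C)
    if (any(d < 1e-10)) {
      stop("partialled matrix singular at k = ", k)
    }
    P <- C / sqrt(tcrossprod(d))
    avg_sq[k + 1] <- mean(P[off]^2)
  }
  suggested <- which.min(avg_sq) - 1L
  structure(suggested,
            profile = stats::setNames(avg_sq, 0:k_max),
            no_common_factors = suggested == 0L)
}

#' Very simple structure (VSS) criterion
#'
#' For each candidate count the minres solution is rotated, simplified to
#' the `complexity` largest loadings per variable, and scored as
#' `1 - SS_offdiag(R - S S') / SS_offdiag(R)`; the suggested count maximizes
#' the profile, with a parsimony tie-break: the smallest count whose score
#' comes within `plateau` of the maximum is returned (additional factors
#' that improve the simplified fit only marginally are not counted).
#'
#' @param R correlation matrix or `mixed_cor`.
#' @param k_max largest count to examine (capped at the Ledermann bound).
#' @param complexity loadings retained per variable (1 or 2).
#' @param plateau tolerance of the parsimony tie-break.
#' @return integer suggestion with attribute `profile`.
#' @export
vss_criterion <- function(R, k_max, complexity = 1, plateau = 0.005) {
  Rm <- if (inherits(R, "mixed_cor")) R$raw else as.matrix(R)
  stopifnot(complexity %in% c(1, 2))
  if (k_max >= ncol(Rm)) stop("k_max must be smaller than the number of variables")
  k_max <- min(k_max, ledermann_bound(ncol(Rm)))
  off <- upper.tri(Rm)
  ss_r <- sum(Rm[off]^2)
  prof <- numeric(k_max)
  for (k in seq_len(k_max)) {
    fit <- minres_fit(Rm, k)
    L <- if (k >= 2) {
      fit$loadings %*% stats::varimax(fit$loadings)$rotmat
    } else fit$loadings
    c_k <- min(complexity, k)
    S <- L * 0
    for (i in seq_len(nrow(L))) {
      keep <- order(-abs(L[i, ]))[seq_len(c_k)]
      S[i, keep] <- L[i, keep]
    }
    prof[k] <- 1 - sum((Rm - tcrossprod(S))[off]^2) / ss_r
  }
  suggested <- which(prof >= max(prof) - plateau)[1]
  structure(suggested, profile = stats::setNames(prof, seq_len(k_max)))
}

#' Choose the number of factors (VSS and MAP, MAP governs)
#'
#' @param R correlation matrix or `mixed_cor`.
#' @param k_max largest count to examine.
#' @return list with `k`, `map`, `vss1`, `vss2`; warns when VSS (complexity
#'   1) and MAP disagree, in which case MAP governs.
#' @export
choose_factor_count <- function(R, k_max = 4) {
  p <- if (inherits(R, "mixed_cor")) length(R$variables) else ncol(R)
  k_max <- min(k_max, ledermann_bound(p), p - 1)
  m <- map_criterion(R, k_max)
  v1 <- vss_criterion(R, k_max, complexity = 1)
  v2 <- vss_criterion(R, k_max, complexity = 2)
  if (as.integer(v1) != as.integer(m)) {
    warning(sprintf("VSS (%d) and MAP (%d) disagree; using MAP",
                    as.integer(v1), as.integer(m)))
  }
  list(k = max(as.integer(m), 1L), map = m, vss1 = v1, vss2 = v2)
}

# ---- rotation --------------------------------------------------------------

# Quartimin criterion value and gradient (gamma = 0 oblimin).
vgQ_quartimin <- function(L) {
  k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# Gradient-projection algorithm for oblique rotation (quartimin criterion).
gpf_oblq <- function(A, maxit = 1000, eps = 1e-6) {
  k <- ncol(A)
  Tmat <- diag(k)
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- vgQ_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  s <- Inf
  trace <- numeric(0)
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    trace <- c(trace, f)
    if (s < eps) break
    al <- 2 * al
    for (i in 0:30) {
      X <- Tmat - al * Gp
      v <- 1 / sqrt(colSums(X^2))
      Tt <- X %*% diag(v, k)
      Tti <- solve(Tt)
      Lt <- A %*% t(Tti)
      vgt <- vgQ_quartimin(Lt)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt; f <- vgt$f; L <- Lt
    G <- -t(t(L) %*% vgt$Gq %*% Tti)
  }
  if (s >= eps) {
    stop(sprintf("oblimin rotation did not converge (gradient %.2e); criterion trace: %s",
                 s, paste(signif(utils::tail(trace, 5), 6), collapse = ", ")))
  }
  Phi <- t(Tmat) %*% Tmat
  dimnames(Phi) <- list(colnames(A), colnames(A))
  dimnames(L) <- dimnames(A)
  list(loadings = L, phi = Phi, criterion = f, iterations = iter)
}

#' Rotate a loading matrix
#'
#' Varimax (orthogonal; via [stats::varimax()], communality-preserving) or
#' oblimin (direct quartimin via gradient projection; returns the
#' inter-factor correlation matrix). A single factor is returned unchanged.
#'
#' @param loadings unrotated loading matrix.
#' @param method `"varimax"` or `"oblimin"`.
#' @return list with rotated `loadings` (sign-oriented), `phi`, `method`.
#' @export
rotate_loadings <- function(loadings, method = c("varimax", "oblimin")) {
  method <- match.arg(method)
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k == 1) {
    return(list(loadings = orient_loadings(L), phi = diag(1), method = "none"))
  }
  if (method == "varimax") {
    r <- stats::varimax(L)
    Lr <- L %*% r$rotmat
    phi <- diag(k)
  } else {
    r <- gpf_oblq(L)
    Lr <- r$loadings
    phi <- r$phi
  }
  ss <- colSums(Lr^2)
  ord <- order(-ss)
  Lr <- Lr[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  flip <- attr(orient_loadings(Lr, return_flips = TRUE), "flipped")
  Lr[, flip] <- -Lr[, flip, drop = FALSE]
  sgn <- ifelse(flip, -1, 1)
  phi <- diag(sgn) %*% phi %*% diag(sgn)
  colnames(Lr) <- paste0("factor", seq_len(k))
  dimnames(phi) <- list(colnames(Lr), colnames(Lr))
  list(loadings = Lr, phi = phi, method = method)
}

#' Orthogonality decision rule for the rotation
#'
#' Inspects the oblimin inter-factor correlation matrix: when every
#' off-diagonal magnitude is strictly below `threshold` (0.32, i.e. < 10%
#' shared variance) the factors are treated as orthogonal and the varimax
#' solution is adopted; otherwise the oblique solution is retained.
#'
#' @param phi oblimin inter-factor correlation matrix.
#' @param threshold strict cut-off on `|phi_ij|`.
#' @return list with `rotation` (`"varimax"` / `"oblimin"`),
#'   `max_abs_phi`, `threshold`.
#' @export
choose_rotation <- function(phi, threshold = 0.32) {
  phi <- as.matrix(phi)
  m <- if (ncol(phi) < 2) 0 else max(abs(phi[upper.tri(phi)]))
  list(rotation = if (m < threshold) "varimax" else "oblimin",
       max_abs_phi = m, threshold = threshold)
}

#' Salient-loading mask
#'
#' @param loadings rotated loading matrix.
#' @param threshold salience cut-off on `|loading|` (inclusive).
#' @return logical mask with attribute `cross_loadings` (variables salient
#'   on more than one factor).
#' @export
salient_loadings <- function(loadings, threshold = 0.32) {
  L <- as.matrix(loadings)
  mask <- abs(L) >= threshold
  dimnames(mask) <- dimnames(L)
  cross <- rownames(L)[rowSums(mask) > 1]
  structure(mask, cross_loadings = cross %||% character(0))
}

# Variance explained per factor: mean squared loading over variables
# (orthogonal case); entries ordered non-increasingly by construction.
variance_explained <- function(loadings) {
  colMeans(as.matrix(loadings)^2)
}

#' Regression factor-score coefficients
#'
#' `W = R^{-1} Lambda` (orthogonal) or `R^{-1} Lambda Phi` (oblique);
#' smoothing is applied before inversion if needed.
#'
#' @param R correlation matrix over the retained variables.
#' @param loadings rotated loading matrix.
#' @param phi inter-factor correlation matrix.
#' @return list with `weights` and `validity` (correlation of the estimated
#'   with the true factor, `sqrt(diag(S' W))` with `S` the structure
#'   matrix).
#' @export
factor_score_weights <- function(R, loadings, phi = NULL) {
  Rm <- if (inherits(R, "mixed_cor")) R$rho else as.matrix(R)
  Rm <- smooth_correlation(Rm)$mat
  L <- as.matrix(loadings)
  if (is.null(phi)) phi <- diag(ncol(L))
  Svec <- L %*% phi                      # structure matrix
  W <- tryCatch(solve(Rm, Svec), error = function(e) {
    stop("correlation matrix singular after smoothing; factor scores undefined")
  })
  validity <- sqrt(pmax(diag(t(Svec) %*% W), 0))
  dimnames(W) <- dimnames(L)
  list(weights = W, validity = stats::setNames(validity, colnames(L)))
}

#' Extension loadings for excluded variables
#'
#' Regression-based extension analysis: `Lambda_ext = R_ev W`, the
#' covariances of the excluded variables with the regression factor scores
#' implied by the retained-variable solution. Because the score SD equals
#' the score validity, salience on the extension loadings is assessed
#' against `threshold * validity`.
#'
#' @param R_full correlation matrix over retained + excluded variables.
#' @param retained,excluded variable name vectors.
#' @param loadings,phi retained-variable rotated solution.
#' @param threshold salience threshold on the factor scale.
#' @return matrix of extension loadings with attribute `salient`.
#' @export
extension_loadings <- function(R_full, retained, excluded, loadings,
                               phi = NULL, threshold = 0.32) {
  Rm <- if (inherits(R_full, "mixed_cor")) R_full$rho else as.matrix(R_full)
  stopifnot(all(retained %in% colnames(Rm)), all(excluded %in% colnames(Rm)))
  w <- factor_score_weights(Rm[retained, retained], loadings, phi)
  ext <- Rm[excluded, retained, drop = FALSE] %*% w$weights
  sal <- sweep(abs(ext), 2, threshold * w$validity, ">=")
  structure(ext, salient = sal, validity = w$validity)
}

# ---- pruning and the main fitting function ---------------------------------

#' Iterative communality pruning
#'
#' Repeatedly refits the mixed correlation matrix and the minres solution,
#' removing the variable with the lowest communality while any communality
#' falls below `threshold` (ties broken lexicographically). The history
#' records each removal with its communality at removal.
#'
#' @param table prepared marker table.
#' @param kinds marker-kind vector.
#' @param k number of factors.
#' @param threshold communality threshold (default 0.2).
#' @return list with `retained`, `history` (data.frame variable/h2), and the
#'   final `fit` and `R` (mixed_cor of retained variables).
#' @export
prune_low_communality <- function(table, kinds = default_marker_kinds(),
                                  k = 2, threshold = 0.2) {
  kinds <- kinds[intersect(names(kinds), names(table))]
  history <- data.frame(variable = character(0), h2 = numeric(0))
  repeat {
    if (length(kinds) < k + 1 || k > ledermann_bound(length(kinds))) {
      stop("pruning would leave fewer than k + 1 (identifiable) variables")
    }
    R <- mixed_cor(table, kinds)
    fit <- minres_fit(R, k)
    h2 <- fit$communalities
    low <- h2 < threshold
    if (!any(low)) {
      return(list(retained = names(kinds), history = history, fit = fit, R = R))
    }
    # lowest communality, lexicographic tie-break
    cand <- names(h2)[low]
    drop_var <- cand[order(h2[cand], cand)][1]
    history <- rbind(history,
                     data.frame(variable = drop_var, h2 = unname(h2[drop_var])))
    kinds <- kinds[setdiff(names(kinds), drop_var)]
  }
}

#' Fit the exploratory factor model of the MRI markers
#'
#' The full EFA pipeline: mixed correlation matrix and KMO adequacy, factor
#' count by VSS/MAP (`k = "auto"`), iterative communality pruning, minres
#' extraction, oblimin rotation with the orthogonality decision rule
#' (`rotation = "auto"`), salient-loading analysis, extension loadings for
#' the pruned variables, and regression factor scores.
#'
#' @param table prepared marker table (see [prepare_markers()]).
#' @param kinds marker-kind vector over the candidate indicators.
#' @param k number of factors, or `"auto"` for VSS/MAP selection.
#' @param k_max largest count examined under `k = "auto"`.
#' @param prune_threshold communality threshold for pruning.
#' @param rotation `"auto"` (oblimin, then the < 0.32 orthogonality rule),
#'   `"varimax"`, or `"oblimin"`.
#' @param salience salient-loading threshold (inclusive).
#' @param scores compute participant factor scores.
#' @return object of class `svd_efa`.
#' @export
fit_efa <- function(table, kinds = default_marker_kinds(), k = "auto",
                    k_max = 4, prune_threshold = 0.2,
                    rotation = c("auto", "varimax", "oblimin"),
                    salience = 0.32, scores = TRUE) {
  rotation <- match.arg(rotation)
  kinds <- kinds[intersect(names(kinds), names(table))]
  R_full <- mixed_cor(table, kinds)
  adequacy <- kmo(R_full)
  selection <- NULL
  if (identical(k, "auto")) {
    selection <- choose_factor_count(R_full, k_max)
    k <- selection$k
  }
  pruned <- prune_low_communality(table, kinds, k = k,
                                  threshold = prune_threshold)
  fit <- pruned$fit
  R <- pruned$R

  obl <- if (k >= 2) rotate_loadings(fit$loadings, "oblimin") else NULL
  decision <- NULL
  if (rotation == "auto") {
    if (k >= 2) {
      decision <- choose_rotation(obl$phi)
      rotation <- decision$rotation
    } else rotation <- "varimax"
  }
  rot <- if (k >= 2) {
    if (rotation == "oblimin") obl else rotate_loadings(fit$loadings, "varimax")
  } else {
    list(loadings = fit$loadings, phi = diag(1), method = "none")
  }

  mask <- salient_loadings(rot$loadings, salience)
  excluded <- pruned$history$variable
  ext <- NULL
  if (length(excluded)) {
    R_all <- mixed_cor(table, kinds)   # retained + excluded, same rows
    ext <- extension_loadings(R_all, pruned$retained, excluded,
                              rot$loadings, rot$phi, threshold = salience)
  }
  sw <- factor_score_weights(R, rot$loadings, rot$phi)
  score_mat <- NULL
  scaling <- NULL
  if (scores) {
    Z <- scale(data.matrix(as.data.frame(table)[pruned$retained]))
    scaling <- list(center = attr(Z, "scaled:center"),
                    scale = attr(Z, "scaled:scale"))
    score_mat <- Z %*% sw$weights
  }

  structure(
    list(
      loadings = rot$loadings, phi = rot$phi, rotation = rotation,
      rotation_decision = decision, oblimin_phi = if (!is.null(obl)) obl$phi,
      uniquenesses = 1 - rowSums(rot$loadings^2),
      communalities = rowSums(rot$loadings^2),
      variance_explained = variance_explained(rot$loadings),
      salient = mask, salience = salience,
      pruning = pruned$history, retained = pruned$retained,
      extension = ext, kmo = adequacy, selection = selection, k = k,
      R = R, R_full = R_full, objective = fit$objective,
      score_weights = sw$weights, score_validity = sw$validity,
      scores = score_mat, scaling = scaling, n = R$n
    ),
    class = "svd_efa"
  )
}

#' @export
print.svd_efa <- function(x, digits = 2, ...) {
  cat(sprintf("Minres factor analysis: %d factors, %d retained indicators, n = %d\n",
              x$k, length(x$retained), x$n))
  cat(sprintf("KMO overall: %.2f; rotation: %s", x$kmo$overall, x$rotation))
  if (!is.null(x$rotation_decision)) {
    cat(sprintf(" (max |inter-factor r| = %.3f, rule < %.2f)",
                x$rotation_decision$max_abs_phi, x$rotation_decision$threshold))
  }
  cat("\n")
  if (nrow(x$pruning)) {
    cat("Pruned (h2 < 0.2):",
        paste(sprintf("%s (%.2f)", x$pruning$variable, x$pruning$h2),
              collapse = ", "), "\n")
  }
  cat("Rotated loadings (salient marked *):\n")
  L <- round(x$loadings, digits)
  disp <- matrix(sprintf(paste0("%", digits + 3, ".", digits, "f%s"),
                         L, ifelse(x$salient, "*", " ")),
                 nrow(L), ncol(L), dimnames = dimnames(L))
  print(disp, quote = FALSE)
  cat("Variance explained:",
      paste(sprintf("%.2f", x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.svd_efa <- function(object, ...) {
  out <- list(
    loadings = object$loadings, communalities = object$communalities,
    variance_explained = object$variance_explained, kmo = object$kmo$overall,
    rotation = object$rotation, pruning = object$pruning,
    extension = object$extension, k = object$k, n = object$n
  )
  class(out) <- "summary.svd_efa"
  out
}

#' @export
print.summary.svd_efa <- function(x, ...) {
  cat("Loadings:\n"); print(round(x$loadings, 3))
  cat("Communalities:\n"); print(round(x$communalities, 3))
  cat("Variance explained:", paste(sprintf("%.3f", x$variance_explained),
                                   collapse = ", "), "\n")
  if (!is.null(x$extension)) {
    cat("Extension loadings of pruned variables:\n")
    print(round(unclass(x$extension), 3))
  }
  invisible(x)
}

#' @export
coef.svd_efa <- function(object, ...) object$loadings

#' Factor scores for new data
#'
#' Standardizes the retained indicator columns with the training scaling and
#' applies the stored regression score weights.
#'
#' @param object fitted `svd_efa`.
#' @param newdata prepared marker table; defaults to returning the training
#'   scores.
#' @param ... unused.
#' @return matrix of factor scores.
#' @export
predict.svd_efa <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  Z <- data.matrix(as.data.frame(newdata)[object$retained])
  Z <- sweep(sweep(Z, 2, object$scaling$center), 2, object$scaling$scale, "/")
  Z %*% object$score_weights
}

#' Write an EFA solution to CSV files
#' @param x fitted `svd_efa`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_efa <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(variable = rownames(x$loadings), x$loadings,
                              h2 = x$communalities),
                   file.path(dir, "loadings.csv"), row.names = FALSE)
  utils::write.csv(x$pruning, file.path(dir, "pruning_history.csv"),
                   row.names = FALSE)
  if (!is.null(x$scores)) {
    utils::write.csv(as.data.frame(x$scores), file.path(dir, "factor_scores.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
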