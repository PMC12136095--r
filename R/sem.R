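# Latent-variable structural equation models: RAM-parameterized maximum
# likelihood with analytic gradients, fit indices, pathway-level effect
# decomposition, bias-corrected bootstrap CIs, and single-indicator
# comparison models.
#
# Model form: v = A v + u, u ~ N(0, S), observed = F v, so
# Sigma(theta) = F (I - A)^{-1} S (I - A)^{-T} F'. Latent disturbance
# variances are fixed to 1 (all loadings free); exogenous observed blocks
# are fixed at their sample moments (their ML estimates under a saturated
# exogenous block), and counted as estimated moments in the df.

#' Declare a structural equation model
#'
#' @param latents named list: latent name -> indicator columns.
#' @param regressions named list: endogenous variable -> predictor names
#'   (observed columns or latent names).
#' @param residual_covariances list of length-2 character vectors naming
#'   indicator pairs whose residuals covary (shared method variance).
#' @param covariates observed columns given paths to every endogenous
#'   structural variable; factors are expanded to dummies at fit time.
#' @param exposure name of the independent variable (for effect
#'   decomposition).
#' @param outcome name of the outcome variable.
#' @return object of class `svd_sem_spec`.
#' @export
sem_spec <- function(latents = list(), regressions = list(),
                     residual_covariances = list(), covariates = character(0),
                     exposure = NULL, outcome = NULL) {
  stopifnot(is.list(latents), is.list(regressions))
  # acyclicity of the structural graph
  nodes <- unique(c(names(regressions), unlist(regressions)))
  edges <- do.call(rbind, lapply(names(regressions), function(dv) {
    cbind(from = regressions[[dv]], to = dv)
  }))
  if (!is.null(edges) && has_cycle(nodes, edges)) {
    stop("structural path graph is cyclic")
  }
  for (l in names(latents)) {
    if (length(latents[[l]]) < 2) {
      stop("under-identified measurement block: latent '", l,
           "' needs >= 2 indicators (variance-standardized rule)")
    }
  }
  structure(list(latents = latents, regressions = regressions,
                 residual_covariances = residual_covariances,
                 covariates = covariates, exposure = exposure,
                 outcome = outcome),
            class = "svd_sem_spec")
}

has_cycle <- function(nodes, edges) {
  adj <- split(edges[, "to"], edges[, "from"])
  state <- stats::setNames(rep(0L, length(nodes)), nodes)
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]] %||% character(0)) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  any(vapply(nodes, visit, logical(1)))
}

#' Default latent-SVD mediation model
#'
#' SVD measured by basal ganglia and thalamus PVS, periventricular and
#' subcortical WMH, and white-matter FA and trace, with same-modality
#' residual covariances; structural paths exposure -> SVD, exposure -> GM,
#' SVD -> GM, SVD -> cognition, GM -> cognition, exposure -> cognition.
#' Models with FRS as the exposure omit sex from the covariate set.
#'
#' @param exposure `"age"` or `"frs"`.
#' @param covariates covariate columns (default: demographics, site, ICV;
#'   set `character(0)` for an unadjusted model).
#' @return `svd_sem_spec`.
#' @export
default_sem_spec <- function(exposure = c("age", "frs"),
                             covariates = c("sex", "race_ethnicity",
                                            "education", "site", "icv")) {
  exposure <- match.arg(exposure)
  x <- if (exposure == "age") "age" else "frs"
  if (exposure == "frs") covariates <- setdiff(covariates, "sex")
  regs <- list()
  regs[["svd"]] <- x
  regs[["gm_volume"]] <- c(x, "svd")
  regs[["global_cognition"]] <- c(x, "svd", "gm_volume")
  sem_spec(
    latents = list(svd = SVD_INDICATORS),
    regressions = regs,
    residual_covariances = list(
      c("pvs_basal_ganglia", "pvs_thalamus"),
      c("wmh_periventricular", "wmh_subcortical"),
      c("wm_fa", "wm_tr")
    ),
    covariates = covariates,
    exposure = x, outcome = "global_cognition"
  )
}

# ---- template assembly ------------------------------------------------------

# Build the RAM template for one group: base matrices with fixed values plus
# a free-parameter table (matrix, i, j, label). `label_suffix`/`shared`
# support multigroup equality constraints; `latent_var` controls whether the
# latent (disturbance) variance is fixed to 1 or a free labelled parameter.
build_sem_template <- function(spec, obs, exog_cov = NULL,
                               label_suffix = "", shared = character(0),
                               latent_var = c("fixed", "free")) {
  latent_var <- match.arg(latent_var)
  lat <- names(spec$latents)
  vars <- c(obs, lat)
  m <- length(vars)
  idx <- stats::setNames(seq_len(m), vars)
  A0 <- matrix(0, m, m, dimnames = list(vars, vars))
  S0 <- matrix(0, m, m, dimnames = list(vars, vars))
  par <- list()
  lab <- function(base) {
    if (base %in% shared || label_suffix == "") base else paste0(base, label_suffix)
  }
  add <- function(mat, i, j, base, start, variance = FALSE) {
    par[[length(par) + 1]] <<- list(mat = mat, i = idx[[i]], j = idx[[j]],
                                    label = lab(base), start = start,
                                    variance = variance)
  }

  endo <- character(0)
  for (l in lat) {
    if (latent_var == "fixed") {
      S0[l, l] <- 1                      # latent disturbance fixed to 1
    } else {
      add("S", l, l, paste0(l, "~~", l), 1, variance = TRUE)
    }
    for (ind in spec$latents[[l]]) {
      add("A", ind, l, paste0(l, "=~", ind), 0.5)
      add("S", ind, ind, paste0(ind, "~~", ind), 0.5, variance = TRUE)
      endo <- c(endo, ind)
    }
  }
  for (dv in names(spec$regressions)) {
    for (iv in spec$regressions[[dv]]) add("A", dv, iv, paste0(dv, "~", iv), 0)
    if (!dv %in% lat) {
      add("S", dv, dv, paste0(dv, "~~", dv), 0.5, variance = TRUE)
      endo <- c(endo, dv)
    }
    for (cv in attr(obs, "covariate_cols") %||% character(0)) {
      add("A", dv, cv, paste0(dv, "~", cv), 0)
    }
  }
  for (pr in spec$residual_covariances) {
    add("S", pr[1], pr[2], paste0(pr[1], "~~", pr[2]), 0)
  }
  exog <- setdiff(obs, endo)
  n_exog_moments <- 0
  if (length(exog)) {
    if (!is.null(exog_cov)) {
      S0[exog, exog] <- exog_cov[exog, exog]
      n_exog_moments <- length(exog) * (length(exog) + 1) / 2
    } else {
      for (v in exog) add("S", v, v, paste0(v, "~~", v), 1, variance = TRUE)
      if (length(exog) > 1) {
        cmb <- utils::combn(exog, 2)
        for (c_i in seq_len(ncol(cmb))) {
          add("S", cmb[1, c_i], cmb[2, c_i],
              paste0(cmb[1, c_i], "~~", cmb[2, c_i]), 0)
        }
      }
    }
  }
  ptab <- do.call(rbind, lapply(par, function(p) {
    data.frame(mat = p$mat, i = p$i, j = p$j, label = p$label,
               start = p$start, variance = p$variance,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(paste(ptab$mat, ptab$i, ptab$j))) {
    stop("duplicate parameter labels: the same model slot is declared twice")
  }
  list(vars = vars, obs = obs, obs_idx = idx[obs], lat = lat,
       A0 = A0, S0 = S0, par = ptab, n_exog_moments = n_exog_moments,
       exog = exog)
}

sem_fill <- function(tmpl, theta) {
  A <- tmpl$A0; S <- tmpl$S0
  pt <- tmpl$par
  v <- theta[pt$label]
  isA <- pt$mat == "A"
  A[cbind(pt$i[isA], pt$j[isA])] <- v[isA]
  S[cbind(pt$i[!isA], pt$j[!isA])] <- v[!isA]
  S[cbind(pt$j[!isA], pt$i[!isA])] <- v[!isA]
  list(A = A, S = S)
}

# Full implied covariance over all variables (observed + latent).
sem_full_cov <- function(tmpl, theta) {
  ms <- sem_fill(tmpl, theta)
  B <- solve(diag(length(tmpl$vars)) - ms$A)
  C <- B %*% ms$S %*% t(B)
  dimnames(C) <- list(tmpl$vars, tmpl$vars)
  list(C = C, B = B, A = ms$A, S = ms$S)
}

#' Model-implied covariance of the observed variables
#' @param tmpl template from the fitting machinery (internal structure).
#' @param theta named parameter vector.
#' @return covariance matrix over observed variables.
#' @keywords internal
sem_sigma <- function(tmpl, theta) {
  sem_full_cov(tmpl, theta)$C[tmpl$obs, tmpl$obs]
}

# F_ML and analytic gradient for one group.
sem_fml <- function(tmpl, theta, Ssamp, logdetS) {
  Sig <- tryCatch(sem_sigma(tmpl, theta), error = function(e) NULL)
  if (is.null(Sig) || anyNA(Sig)) return(list(f = 1e10, ok = FALSE))
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(list(f = 1e10, ok = FALSE))
  logdet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  p <- ncol(Sig)
  f <- logdet + sum(Sinv * Ssamp) - logdetS - p
  if (!is.finite(f)) return(list(f = 1e10, ok = FALSE))
  list(f = f, ok = TRUE, Sinv = Sinv)
}

sem_grad <- function(tmpl, theta, Ssamp) {
  zero <- stats::setNames(rep(0, length(theta)), names(theta))
  fc <- tryCatch(sem_full_cov(tmpl, theta), error = function(e) NULL)
  if (is.null(fc) || anyNA(fc$C)) return(zero)
  Sig <- fc$C[tmpl$obs, tmpl$obs]
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(zero)
  Sinv <- chol2inv(ch)
  W <- Sinv - Sinv %*% Ssamp %*% Sinv
  M <- fc$B[tmpl$obs_idx, , drop = FALSE]
  N <- fc$C[tmpl$obs_idx, , drop = FALSE]
  GA <- 2 * t(M) %*% W %*% N
  GS <- t(M) %*% W %*% M
  pt <- tmpl$par
  g <- numeric(length(theta))
  names(g) <- names(theta)
  for (r in seq_len(nrow(pt))) {
    gi <- if (pt$mat[r] == "A") {
      GA[pt$i[r], pt$j[r]]
    } else if (pt$i[r] == pt$j[r]) {
      GS[pt$i[r], pt$i[r]]
    } else {
      2 * GS[pt$i[r], pt$j[r]]
    }
    g[pt$label[r]] <- g[pt$label[r]] + gi
  }
  g[!is.finite(g)] <- 0
  g
}

# Shared optimizer over one or more groups with a common labelled theta.
sem_optimize <- function(groups, start, max_iter = 1000, n_starts = 3,
                         seed_jitter = 1) {
  labels <- names(start)
  lower <- rep(-Inf, length(start))
  variance_labels <- unique(unlist(lapply(groups, function(g) {
    g$tmpl$par$label[g$tmpl$par$variance]
  })))
  lower[labels %in% variance_labels] <- 1e-6
  obj <- function(th) {
    names(th) <- labels
    val <- sum(vapply(groups, function(g) {
      (g$n - 1) * sem_fml(g$tmpl, th, g$Ssamp, g$logdetS)$f
    }, numeric(1)))
    if (!is.finite(val)) 1e12 else val
  }
  grf <- function(th) {
    names(th) <- labels
    out <- numeric(length(th))
    for (g in groups) {
      out <- out + (g$n - 1) * sem_grad(g$tmpl, th, g$Ssamp)[labels]
    }
    out
  }
  best <- NULL
  th0 <- start
  for (s in seq_len(n_starts)) {
    opt <- stats::optim(th0, obj, grf, method = "L-BFGS-B", lower = lower,
                        control = list(maxit = max_iter, factr = 1e4))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0 && opt$value < 1e9) break
    # deterministic jitter (keeps the caller's RNG stream untouched)
    th0 <- start + 0.1 * sin(seq_along(start) * (seed_jitter + s) * 2.39996)
  }
  if (best$value >= 1e9) {
    stop("SEM optimization failed: implied covariance never positive definite")
  }
  if (best$convergence != 0) {
    # line-search stalls (code 52) at a stationary point are convergence;
    # check the KKT projected gradient before complaining
    g <- grf(best$par)
    at_lower <- best$par <= lower + 1e-8
    viol <- ifelse(at_lower, pmax(-g, 0), abs(g))
    if (max(viol) > 1e-3 * max(1, abs(best$value))) {
      warning("SEM optimizer reported convergence code ", best$convergence)
    } else {
      best$convergence <- 0
    }
  }
  names(best$par) <- labels
  best
}

# PCA-informed starting values for measurement parameters.
sem_starts <- function(tmpl, Ssamp, spec) {
  start <- stats::setNames(tmpl$par$start, tmpl$par$label)
  Rs <- stats::cov2cor(Ssamp)
  for (l in tmpl$lat) {
    inds <- intersect(spec$latents[[l]], rownames(Rs))
    if (length(inds) >= 2) {
      e <- eigen(Rs[inds, inds], symmetric = TRUE)
      v <- e$vectors[, 1] * sqrt(max(e$values[1], 0.1))
      if (v[which.max(abs(v))] < 0) v <- -v
      for (ii in seq_along(inds)) {
        lb <- paste0(l, "=~", inds[ii])
        if (lb %in% names(start)) start[lb] <- v[ii] * 0.8
        vb <- paste0(inds[ii], "~~", inds[ii])
        if (vb %in% names(start)) start[vb] <- max(1 - (v[ii] * 0.8)^2, 0.2)
      }
    }
  }
  for (v in tmpl$obs) {
    vb <- paste0(v, "~~", v)
    if (vb %in% names(start)) {
      start[vb] <- max(Ssamp[v, v] * 0.5, 1e-3)
    }
  }
  start
}

# Orient each latent so its largest-magnitude loading is positive: flipping
# the latent's sign negates every path into and out of it and leaves Sigma
# unchanged.
sem_fix_latent_signs <- function(tmpl, theta, spec) {
  pt <- tmpl$par
  for (l in tmpl$lat) {
    li <- which(tmpl$vars == l)
    ind_idx <- tmpl$obs_idx[intersect(spec$latents[[l]], tmpl$obs)]
    load_lab <- pt$label[pt$mat == "A" & pt$j == li & pt$i %in% ind_idx]
    lv <- theta[load_lab]
    if (length(lv) && lv[which.max(abs(lv))] < 0) {
      touch <- unique(pt$label[pt$mat == "A" & (pt$i == li | pt$j == li)])
      theta[touch] <- -theta[touch]
    }
  }
  theta
}

# ---- the main fitting function ---------------------------------------------

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes `F_ML = log|Sigma(theta)| + tr(S Sigma^{-1}) - log|S| - p`;
#' `chi^2 = (n - 1) F_ML` at the optimum. Observed variables are z-scored
#' by default (`standardize = TRUE`); the completely standardized solution
#' is computed from the model-implied variances either way.
#'
#' @param data participant-level data (listwise deletion over the model
#'   columns). Alternatively supply `S` and `n` directly.
#' @param spec an [sem_spec()].
#' @param S optional sample covariance matrix (used with `n` when `data` is
#'   `NULL`).
#' @param n sample size accompanying `S`.
#' @param standardize report estimates on the z-score scale (`TRUE`) or the
#'   raw scale (`FALSE`). Optimization always runs on the correlation scale
#'   (the model is scale-equivariant, so the raw-scale ML solution is the
#'   rescaled one); the completely standardized solution is identical either
#'   way.
#' @param max_iter optimizer iteration cap.
#' @return object of class `svd_sem`.
#' @export
fit_sem <- function(data = NULL, spec = default_sem_spec(), S = NULL, n = NULL,
                    standardize = TRUE, max_iter = 1000) {
  base_obs <- unique(c(unlist(spec$latents),
                       setdiff(unlist(spec$regressions), names(spec$latents)),
                       setdiff(names(spec$regressions), names(spec$latents))))
  cov_cols <- character(0)
  if (!is.null(data)) {
    dat <- as.data.frame(data)
    cols <- c(base_obs, spec$covariates)
    dat <- dat[stats::complete.cases(dat[cols]), cols, drop = FALSE]
    n <- nrow(dat)
    X <- data.matrix(dat[base_obs])
    if (length(spec$covariates)) {
      mm <- stats::model.matrix(~ ., dat[spec$covariates])[, -1, drop = FALSE]
      colnames(mm) <- make.names(colnames(mm))
      cov_cols <- colnames(mm)
      X <- cbind(X, mm)
    }
    S <- stats::cov(X)
  } else {
    if (is.null(S) || is.null(n)) stop("supply either data or S and n")
    S <- as.matrix(S)
    if (!all(base_obs %in% colnames(S))) {
      stop("S lacks observed variables: ",
           paste(setdiff(base_obs, colnames(S)), collapse = ", "))
    }
  }
  p_all <- length(base_obs) + length(cov_cols)
  if (n <= p_all) stop("n must exceed the number of observed variables")
  obs <- c(base_obs, cov_cols)
  attr(obs, "covariate_cols") <- cov_cols
  S <- S[obs, obs]

  # optimize on the correlation scale for numerical stability
  sds <- sqrt(diag(S))
  Sstd <- S / tcrossprod(sds)
  tmpl <- build_sem_template(spec, obs, exog_cov = Sstd)
  logdetS <- determinant(Sstd)$modulus
  start <- sem_starts(tmpl, Sstd, spec)
  groups <- list(list(tmpl = tmpl, Ssamp = Sstd, logdetS = logdetS, n = n))
  opt <- sem_optimize(groups, start, max_iter = max_iter)
  theta <- sem_fix_latent_signs(tmpl, opt$par, spec)

  # Heywood check
  vlab <- tmpl$par$label[tmpl$par$variance]
  if (any(theta[vlab] <= 1e-6 + 1e-12)) {
    warning("Heywood case: residual variance(s) at the 1e-6 boundary: ",
            paste(vlab[theta[vlab] <= 1e-6 + 1e-12], collapse = ", "))
  }

  if (!standardize) {
    # rescale the ML solution to the raw variable scale (latent scale is set
    # by its fixed unit disturbance and does not change)
    sd_of <- function(idx) {
      v <- tmpl$vars[idx]
      if (v %in% obs) sds[[v]] else 1
    }
    tmpl_raw <- build_sem_template(spec, obs, exog_cov = S)
    pt <- tmpl_raw$par
    theta_raw <- theta
    for (r in seq_len(nrow(pt))) {
      theta_raw[pt$label[r]] <- if (pt$mat[r] == "A") {
        theta[pt$label[r]] * sd_of(pt$i[r]) / sd_of(pt$j[r])
      } else {
        theta[pt$label[r]] * sd_of(pt$i[r]) * sd_of(pt$j[r])
      }
    }
    return(sem_finalize(tmpl_raw, theta_raw, S, n, spec, opt))
  }
  sem_finalize(tmpl, theta, Sstd, n, spec, opt)
}

sem_finalize <- function(tmpl, theta, Ssamp, n, spec, opt) {
  fc <- sem_full_cov(tmpl, theta)
  Sig <- fc$C[tmpl$obs, tmpl$obs]
  p <- length(tmpl$obs)
  fml <- sem_fml(tmpl, theta, Ssamp, determinant(Ssamp)$modulus)$f
  chi2 <- (n - 1) * fml
  n_free <- length(theta)
  df <- as.integer(p * (p + 1) / 2 - n_free - tmpl$n_exog_moments)
  if (df < 0) stop("negative degrees of freedom: model not identified")
  # independence baseline (diagonal Sigma): closed form
  chi2_b <- (n - 1) * (sum(log(diag(Ssamp))) -
                         as.numeric(determinant(Ssamp)$modulus))
  df_b <- p * (p - 1) / 2
  srmr <- sem_srmr(Ssamp, Sig)
  idx <- fit_indices(chi2, df, chi2_b, df_b, n, srmr = srmr)

  std <- sem_standardize(tmpl, theta, fc)
  r2 <- NULL
  if (!is.null(spec$outcome) && spec$outcome %in% tmpl$vars) {
    vres <- paste0(spec$outcome, "~~", spec$outcome)
    if (vres %in% names(theta)) {
      r2 <- 1 - theta[[vres]] / fc$C[spec$outcome, spec$outcome]
    }
  }
  structure(
    list(theta = theta, standardized = std$theta, A_std = std$A, S_std = std$S,
         sigma = Sig, sample_cov = Ssamp, chisq = chi2, df = df,
         baseline_chisq = chi2_b, baseline_df = df_b,
         cfi = idx$cfi, rmsea = idx$rmsea, srmr = srmr, fml = fml,
         n = n, spec = spec, tmpl = tmpl, r2_outcome = r2,
         convergence = opt$convergence, objective = opt$value),
    class = "svd_sem"
  )
}

sem_srmr <- function(Ssamp, Sig) {
  d <- sqrt(diag(Ssamp))
  Rs <- Ssamp / tcrossprod(d)
  ds <- sqrt(diag(Sig))
  Ri <- Sig / tcrossprod(ds)
  res <- Rs - Ri
  diag(res) <- 1 - diag(Sig) / diag(Ssamp)   # variance residuals on S scale
  lt <- lower.tri(res, diag = TRUE)
  sqrt(mean(res[lt]^2))
}

sem_standardize <- function(tmpl, theta, fc = NULL) {
  if (is.null(fc)) fc <- sem_full_cov(tmpl, theta)
  sd_all <- sqrt(pmax(diag(fc$C), 1e-12))
  A_std <- fc$A * outer(1 / sd_all, sd_all)
  S_std <- fc$S / tcrossprod(sd_all)
  pt <- tmpl$par
  th <- theta
  for (r in seq_len(nrow(pt))) {
    th[pt$label[r]] <- if (pt$mat[r] == "A") {
      A_std[pt$i[r], pt$j[r]]
    } else S_std[pt$i[r], pt$j[r]]
  }
  dimnames(A_std) <- dimnames(S_std) <- list(tmpl$vars, tmpl$vars)
  list(theta = th, A = A_std, S = S_std)
}

#' SEM fit indices
#'
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)` (1 when
#' the denominator vanishes), `RMSEA = sqrt(max(chi2 - df, 0) / (df (n-1)))`
#' (0 when `df = 0` by convention), and SRMR passed through from the
#' standardized residuals.
#'
#' @param chi2,df model test statistic and degrees of freedom.
#' @param chi2_baseline,df_baseline independence-model statistic/df.
#' @param n sample size.
#' @param srmr standardized root mean squared residual (optional).
#' @return list with `cfi`, `rmsea`, `srmr`.
#' @export
fit_indices <- function(chi2, df, chi2_baseline, df_baseline, n, srmr = NA) {
  num <- max(chi2 - df, 0)
  den <- max(chi2_baseline - df_baseline, chi2 - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  rmsea <- if (df <= 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  list(cfi = cfi, rmsea = rmsea, srmr = srmr)
}

#' @export
print.svd_sem <- function(x, ...) {
  cat(sprintf("SEM fit (ML): n = %d, chi2(%d) = %.3f, CFI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$n, x$df, x$chisq, x$cfi, x$rmsea, x$srmr))
  if (!is.null(x$r2_outcome)) {
    cat(sprintf("Outcome R2 (%s): %.3f\n", x$spec$outcome, x$r2_outcome))
  }
  invisible(x)
}

#' @export
summary.svd_sem <- function(object, ...) {
  est <- data.frame(parameter = names(object$theta),
                    estimate = unname(object$theta),
                    std = unname(object$standardized[names(object$theta)]))
  out <- list(estimates = est, chisq = object$chisq, df = object$df,
              cfi = object$cfi, rmsea = object$rmsea, srmr = object$srmr,
              n = object$n, r2_outcome = object$r2_outcome)
  class(out) <- "summary.svd_sem"
  out
}

#' @export
print.summary.svd_sem <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f | CFI %.3f | RMSEA %.3f | SRMR %.3f | n = %d\n",
              x$df, x$chisq, x$cfi, x$rmsea, x$srmr, x$n))
  print(transform(x$estimates, estimate = round(estimate, 4),
                  std = round(std, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.svd_sem <- function(object, standardized = FALSE, ...) {
  if (standardized) object$standardized else object$theta
}

#' @export
logLik.svd_sem <- function(object, ...) {
  # up to the saturated-model constant
  structure(-0.5 * (object$n - 1) * object$fml, df = length(object$theta),
            class = "logLik")
}

#' Asymptotic covariance of the free parameters
#'
#' Inverse observed information of the ML discrepancy:
#' `2 H^{-1}` with `H` the numeric Hessian of `(n - 1) F_ML` at the optimum
#' (analytic gradient differentiated numerically).
#'
#' @param object fitted `svd_sem`.
#' @param ... unused.
#' @return covariance matrix of `coef(object)`.
#' @export
vcov.svd_sem <- function(object, ...) {
  tmpl <- object$tmpl
  labels <- names(object$theta)
  gr <- function(th) {
    names(th) <- labels
    (object$n - 1) * sem_grad(tmpl, th, object$sample_cov)[labels]
  }
  fn <- function(th) {
    names(th) <- labels
    (object$n - 1) * sem_fml(tmpl, th, object$sample_cov,
                             determinant(object$sample_cov)$modulus)$f
  }
  H <- stats::optimHess(object$theta, fn, gr)
  V <- 2 * solve(H)
  dimnames(V) <- list(labels, labels)
  V
}

#' Simulate observed data from the default population mediation model
#'
#' Draws multivariate-normal data from the covariance implied by
#' [sem_population()], for parameter-recovery experiments.
#'
#' @param n rows.
#' @param exposure `"age"` or `"frs"`.
#' @param seed optional RNG seed.
#' @return data.frame with the nine observed model variables.
#' @export
simulate_sem_population <- function(n, exposure = "age", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- sem_population(exposure)
  as.data.frame(rmvn_chol(n, pop$cov))
}

#' Simulate observed data from a fitted SEM
#' @param object fitted `svd_sem`.
#' @param nsim number of data sets.
#' @param seed optional seed.
#' @param n rows per data set (default: fitted n).
#' @param ... unused.
#' @return a data.frame (or list of them when `nsim > 1`).
#' @export
simulate.svd_sem <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- n %||% object$n
  out <- lapply(seq_len(nsim), function(i) {
    as.data.frame(rmvn_chol(n, object$sigma))
  })
  if (nsim == 1) out[[1]] else out
}

rmvn_chol <- function(n, Sigma) {
  ch <- chol(Sigma + diag(1e-12, ncol(Sigma)))
  Z <- matrix(stats::rnorm(n * ncol(Sigma)), n)
  X <- Z %*% ch
  colnames(X) <- colnames(Sigma)
  X
}

# ---- population truth for simulation experiments ---------------------------

#' Population covariance and standardized truth of the default mediation model
#'
#' Assembles the completely standardized model (measurement loadings from
#' the default marker loading matrix's SVD column, residual covariances from
#' the second-factor column products, and the configured structural paths)
#' and returns the implied covariance of the nine observed variables plus
#' the true standardized parameter values under the fitting labels.
#'
#' @param exposure `"age"` or `"frs"`.
#' @return list with `cov` (9 x 9), `theta_std` (named truth vector), `spec`.
#' @export
sem_population <- function(exposure = c("age", "frs")) {
  exposure <- match.arg(exposure)
  x <- if (exposure == "age") "age" else "frs"
  spec <- default_sem_spec(exposure, covariates = character(0))
  L <- cohort_marker_loadings()[SVD_INDICATORS, ]
  sc <- default_structural_coefficients(exposure)
  vars <- c(SVD_INDICATORS, x, "gm_volume", "global_cognition", "svd")
  m <- length(vars)
  A <- matrix(0, m, m, dimnames = list(vars, vars))
  S <- matrix(0, m, m, dimnames = list(vars, vars))
  A[SVD_INDICATORS, "svd"] <- L[, 1]
  for (ind in SVD_INDICATORS) S[ind, ind] <- 1 - L[ind, 1]^2
  for (pr in spec$residual_covariances) {
    S[pr[1], pr[2]] <- S[pr[2], pr[1]] <- L[pr[1], 2] * L[pr[2], 2]
  }
  A["svd", x] <- sc$x_svd
  A["gm_volume", "svd"] <- sc$svd_gm
  A["gm_volume", x] <- sc$x_gm
  A["global_cognition", "svd"] <- sc$svd_cog
  A["global_cognition", "gm_volume"] <- sc$gm_cog
  A["global_cognition", x] <- sc$x_cog
  S[x, x] <- 1
  S["svd", "svd"] <- 1 - sc$x_svd^2
  B <- solve(diag(m) - A)
  # set disturbances so every variable has unit variance
  for (v in c("gm_volume", "global_cognition")) {
    S[v, v] <- 1
    C <- (B %*% S %*% t(B))
    S[v, v] <- 1 - (C[v, v] - S[v, v])
  }
  C <- B %*% S %*% t(B)
  obs <- setdiff(vars, "svd")
  theta_std <- c(
    stats::setNames(L[, 1], paste0("svd=~", SVD_INDICATORS)),
    stats::setNames(c(sc$x_svd, sc$x_gm, sc$svd_gm, sc$x_cog, sc$svd_cog,
                      sc$gm_cog),
                    c(paste0("svd~", x), paste0("gm_volume~", x),
                      "gm_volume~svd", paste0("global_cognition~", x),
                      "global_cognition~svd", "global_cognition~gm_volume"))
  )
  list(cov = C[obs, obs], theta_std = theta_std, spec = spec,
       full = list(A = A, S = S, vars = vars))
}

# ---- effect decomposition ---------------------------------------------------

enumerate_paths <- function(A, from, to, nodes) {
  paths <- list()
  walk <- function(v, trail) {
    if (v == to) {
      paths[[length(paths) + 1]] <<- trail
      return(invisible())
    }
    succ <- nodes[A[nodes, v] != 0]
    for (w in succ) walk(w, c(trail, w))
  }
  walk(from, from)
  paths
}

#' Decompose a total effect into pathway-specific components
#'
#' Enumerates all directed paths from the exposure to the outcome in the
#' standardized structural graph; each pathway effect is the product of its
#' standardized path coefficients. Total = direct + total indirect and
#' total indirect = sum of pathway effects hold as algebraic identities.
#'
#' @param fit fitted `svd_sem`.
#' @param x exposure variable (default: the spec's).
#' @param outcome outcome variable (default: the spec's).
#' @return object of class `effect_decomposition`.
#' @export
decompose_effects <- function(fit, x = NULL, outcome = NULL) {
  x <- x %||% fit$spec$exposure
  outcome <- outcome %||% fit$spec$outcome
  A <- fit$A_std
  structural <- unique(c(x, names(fit$spec$regressions),
                         setdiff(unlist(fit$spec$regressions), character(0))))
  structural <- intersect(structural, rownames(A))
  paths <- enumerate_paths(A, x, outcome, structural)
  if (!length(paths)) stop("no directed path from ", x, " to ", outcome)
  effects <- vapply(paths, function(tr) {
    prod(A[cbind(tr[-1], tr[-length(tr)])])
  }, numeric(1))
  names(effects) <- vapply(paths, paste, "", collapse = "->")
  direct_name <- paste(x, outcome, sep = "->")
  direct <- unname(effects[direct_name] %||% 0)
  if (is.na(direct)) direct <- 0
  pathway <- effects[setdiff(names(effects), direct_name)]
  decompose_paths(direct, pathway, exposure = x, outcome = outcome)
}

#' Assemble an effect decomposition from a direct effect and pathway effects
#'
#' The arithmetic core of mediation reporting: total indirect is the sum of
#' the pathway-specific effects, the total effect is direct + total
#' indirect, and proportions mediated are each component divided by the
#' total effect (in percent; flagged undefined for a zero total).
#'
#' @param direct direct effect of the exposure on the outcome.
#' @param pathways named numeric vector of pathway-specific indirect
#'   effects.
#' @param exposure,outcome names used for printing.
#' @return object of class `effect_decomposition` with fields `direct`,
#'   `pathways`, `total_indirect`, `total`, `proportion_mediated`
#'   (overall %), `proportion_by_pathway` (%).
#' @export
decompose_paths <- function(direct, pathways, exposure = "x", outcome = "y") {
  total_indirect <- sum(pathways)
  total <- direct + total_indirect
  undefined <- abs(total) < 1e-12
  if (undefined) warning("zero total effect: proportion mediated undefined")
  structure(
    list(exposure = exposure, outcome = outcome, direct = direct,
         pathways = pathways, total_indirect = total_indirect, total = total,
         proportion_mediated = if (undefined) NA_real_ else
           100 * total_indirect / total,
         proportion_by_pathway = if (undefined) rep(NA_real_, length(pathways))
           else 100 * pathways / total,
         ci = NULL),
    class = "effect_decomposition"
  )
}

#' @export
print.effect_decomposition <- function(x, digits = 3, ...) {
  cat(sprintf("Effect decomposition: %s -> %s\n", x$exposure, x$outcome))
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  cat("  total:         ", fmt(x$total), "\n")
  cat("  direct:        ", fmt(x$direct), "\n")
  cat("  total indirect:", fmt(x$total_indirect),
      sprintf(" (%.0f%% mediated)\n", x$proportion_mediated))
  for (i in seq_along(x$pathways)) {
    cat(sprintf("    %-55s %s (%.0f%%)\n", names(x$pathways)[i],
                fmt(x$pathways[i]), x$proportion_by_pathway[i]))
  }
  if (!is.null(x$ci)) {
    cat("Bootstrap bias-corrected 95% CIs:\n")
    print(round(x$ci, digits))
  }
  invisible(x)
}

# Flatten a decomposition into the named statistic vector bootstrapped below.
decomposition_stats <- function(d) {
  c(total = d$total, direct = d$direct, total_indirect = d$total_indirect,
    d$pathways)
}

# ---- bias-corrected bootstrap ----------------------------------------------

#' Bias-corrected bootstrap confidence intervals
#'
#' Nonparametric case resampling with the normal-quantile bias correction
#' `z0 = qnorm(#{boot < estimate} / B)`; no acceleration term. Resamples on
#' which `statistic` fails are dropped, with an error if more than
#' `max_fail` of them fail.
#'
#' @param data data.frame resampled by rows.
#' @param statistic function(data) -> named numeric vector.
#' @param n_boot number of resamples (reference analysis scale: 5000).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @param max_fail tolerated failure fraction.
#' @return data.frame with estimate, lower, upper, z0, n_boot per statistic.
#' @export
bootstrap_bc_ci <- function(data, statistic, n_boot = 5000, seed = NULL,
                            conf = 0.95, max_fail = 0.1) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  est <- statistic(data)
  if (is.null(names(est))) names(est) <- paste0("stat", seq_along(est))
  n <- nrow(data)
  boots <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
  failures <- character(0)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- tryCatch(statistic(data[idx, , drop = FALSE]),
                  error = function(e) conditionMessage(e))
    if (is.character(r)) failures <- c(failures, r) else boots[b, ] <- r
  }
  if (length(failures) > max_fail * n_boot) {
    stop(sprintf("%d/%d bootstrap fits failed; first failures: %s",
                 length(failures), n_boot,
                 paste(utils::head(unique(failures), 3), collapse = " | ")))
  }
  alpha <- (1 - conf) / 2
  out <- lapply(names(est), function(nm) {
    bt <- boots[!is.na(boots[, nm]), nm]
    B <- length(bt)
    if (stats::sd(bt) < 1e-14) {
      warning("degenerate bootstrap distribution for ", nm,
              ": zero-width interval")
      return(data.frame(statistic = nm, estimate = est[[nm]],
                        lower = est[[nm]], upper = est[[nm]], z0 = 0,
                        n_boot = B))
    }
    frac <- (sum(bt < est[[nm]]) + 0.5 * sum(bt == est[[nm]])) / B
    frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))
    z0 <- stats::qnorm(frac)
    plo <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
    phi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
    q <- stats::quantile(bt, c(plo, phi), names = FALSE, type = 7)
    data.frame(statistic = nm, estimate = est[[nm]], lower = q[1],
               upper = q[2], z0 = z0, n_boot = B)
  })
  do.call(rbind, out)
}

#' Effect decomposition with bootstrap bias-corrected CIs
#'
#' Refits the SEM on each case resample and bootstraps the full effect
#' decomposition (total, direct, total indirect, pathway effects).
#'
#' @param data participant-level data.
#' @param spec an [sem_spec()].
#' @param n_boot number of resamples.
#' @param seed RNG seed.
#' @return `effect_decomposition` with a `ci` table attached.
#' @export
sem_mediation <- function(data, spec = default_sem_spec(), n_boot = 5000,
                          seed = NULL) {
  fit <- fit_sem(data, spec)
  dec <- decompose_effects(fit)
  if (n_boot > 0) {
    stat <- function(d) {
      decomposition_stats(decompose_effects(fit_sem(d, spec)))
    }
    dec$ci <- bootstrap_bc_ci(data, stat, n_boot = n_boot, seed = seed)
  }
  dec$fit <- fit
  dec
}

# ---- single-indicator comparison -------------------------------------------

#' Compare the latent-SVD model with single-indicator mediation models
#'
#' Refits the structural model with each observed indicator substituted for
#' the latent SVD variable and tabulates the indirect effect transmitted
#' through the mediator (both mediator pathways) and the outcome R-squared,
#' alongside the latent-variable model.
#'
#' @param data participant-level data.
#' @param exposure `"age"` or `"frs"` (or any exposure column).
#' @param indicators indicator columns to substitute.
#' @param covariates covariates passed to the structural models.
#' @return data.frame with one row per model.
#' @export
single_indicator_comparison <- function(data, exposure = "age",
                                        indicators = SVD_INDICATORS,
                                        covariates = character(0)) {
  latent_spec <- default_sem_spec(if (exposure == "frs") "frs" else "age",
                                  covariates = covariates)
  latent_spec$exposure <- exposure
  latent_spec$regressions <- stats::setNames(
    lapply(latent_spec$regressions, function(v) replace(v, v %in% c("age", "frs"), exposure)),
    names(latent_spec$regressions))
  fit_lat <- fit_sem(data, latent_spec)
  dec_lat <- decompose_effects(fit_lat)
  via <- function(dec, mediator) {
    sum(dec$pathways[grepl(paste0("->", mediator, "->"), names(dec$pathways))])
  }
  rows <- list(data.frame(
    model = "latent_svd", mediator = "svd",
    indirect_via_mediator = via(dec_lat, "svd"),
    total = dec_lat$total, r2_outcome = unname(fit_lat$r2_outcome)
  ))
  for (ind in indicators) {
    spec_i <- sem_spec(
      latents = list(),
      regressions = stats::setNames(
        list(exposure, c(exposure, ind), c(exposure, ind, "gm_volume")),
        c(ind, "gm_volume", "global_cognition")),
      covariates = covariates,
      exposure = exposure, outcome = "global_cognition"
    )
    fit_i <- fit_sem(data, spec_i)
    dec_i <- decompose_effects(fit_i)
    rows[[length(rows) + 1]] <- data.frame(
      model = paste0("single_", ind), mediator = ind,
      indirect_via_mediator = via(dec_i, ind),
      total = dec_i$total, r2_outcome = unname(fit_i$r2_outcome)
    )
  }
  do.call(rbind, rows)
}
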