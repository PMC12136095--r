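# Multi-group CFA invariance ladder across study sites with (scaled)
# chi-square difference tests.
#
# Identification: the latent variance is fixed to 1 in the first group; it
# is freed in the remaining groups once loadings are constrained equal
# (metric level), and constrained equal (to 1) across groups at the
# residual-equality level, which additionally equates indicator residual
# variances across sites. With 6 sites and the 6-indicator measurement model
# (3 residual covariances) this yields 36 / 61 / 96 degrees of freedom for
# the configural / metric / residual levels.

#' Measurement-only spec for the SVD latent construct
#' @return `svd_sem_spec` with the six SVD indicators and the same-modality
#'   residual covariances, no structural part.
#' @export
measurement_spec <- function() {
  sem_spec(
    latents = list(svd = SVD_INDICATORS),
    residual_covariances = list(
      c("pvs_basal_ganglia", "pvs_thalamus"),
      c("wmh_periventricular", "wmh_subcortical"),
      c("wm_fa", "wm_tr")
    )
  )
}

invariance_shared <- function(spec, level) {
  loadings <- unlist(lapply(names(spec$latents), function(l) {
    paste0(l, "=~", spec$latents[[l]])
  }))
  residvars <- unlist(lapply(names(spec$latents), function(l) {
    paste0(spec$latents[[l]], "~~", spec$latents[[l]])
  }))
  switch(level,
         configural = character(0),
         metric = loadings,
         residual = c(loadings, residvars),
         stop("unknown constraint level: ", level))
}

#' Fit a multi-group CFA at one invariance level
#'
#' Joint ML over groups: minimizes `sum_g (n_g - 1) F_ML,g` under the
#' level's equality constraints. Levels: `"configural"` (same structure,
#' all parameters group-specific, latent variance fixed to 1 everywhere),
#' `"metric"` (loadings equal across groups; latent variance free in groups
#' 2..G), `"residual"` (additionally equal indicator residual variances and
#' equal latent variance across groups; residual covariances stay free).
#'
#' @param data participant-level data.
#' @param spec measurement spec (default [measurement_spec()]).
#' @param group grouping column name (e.g. `"site"`).
#' @param level `"configural"`, `"metric"`, or `"residual"`.
#' @param standardize z-score indicators (within the pooled sample).
#' @return object of class `svd_sem_mg` with the joint chi-square, df, fit
#'   indices, and per-group estimates.
#' @export
fit_multigroup <- function(data, spec = measurement_spec(), group = "site",
                           level = c("configural", "metric", "residual"),
                           standardize = TRUE) {
  level <- match.arg(level)
  dat <- as.data.frame(data)
  obs <- unique(c(unlist(spec$latents),
                  setdiff(unlist(spec$regressions), names(spec$latents)),
                  setdiff(names(spec$regressions), names(spec$latents))))
  keep <- stats::complete.cases(dat[c(obs, group)])
  dat <- dat[keep, , drop = FALSE]
  g <- factor(dat[[group]])
  X <- data.matrix(dat[obs])
  if (standardize) X <- scale(X)
  shared <- invariance_shared(spec, level)
  groups <- list()
  start <- numeric(0)
  for (gi in seq_along(levels(g))) {
    rows <- which(g == levels(g)[gi])
    if (length(rows) <= length(obs)) {
      stop("group too small: ", levels(g)[gi], " (n = ", length(rows), ")")
    }
    lv <- if (level == "configural" || level == "residual") "fixed"
          else if (gi == 1) "fixed" else "free"
    obs_g <- obs
    attr(obs_g, "covariate_cols") <- character(0)
    tmpl <- build_sem_template(spec, obs_g, exog_cov = NULL,
                               label_suffix = paste0("_g", gi),
                               shared = shared, latent_var = lv)
    Sg <- stats::cov(X[rows, , drop = FALSE])
    st <- sem_starts(tmpl, Sg, spec)
    start <- c(start, st[setdiff(names(st), names(start))])
    groups[[gi]] <- list(tmpl = tmpl, Ssamp = Sg,
                         logdetS = determinant(Sg)$modulus,
                         n = length(rows), label = levels(g)[gi])
  }
  opt <- sem_optimize(groups, start)
  theta <- opt$par
  for (gr in groups) theta <- sem_fix_latent_signs(gr$tmpl, theta, spec)

  n_total <- sum(vapply(groups, `[[`, 0, "n"))
  p <- length(obs)
  chi2 <- opt$value
  n_free <- length(theta)
  df <- as.integer(length(groups) * p * (p + 1) / 2 - n_free)
  chi2_b <- sum(vapply(groups, function(gr) {
    (gr$n - 1) * (sum(log(diag(gr$Ssamp))) -
                    as.numeric(determinant(gr$Ssamp)$modulus))
  }, numeric(1)))
  df_b <- length(groups) * p * (p - 1) / 2
  srmr <- mean(vapply(groups, function(gr) {
    sem_srmr(gr$Ssamp, sem_sigma(gr$tmpl, theta))
  }, numeric(1)))
  idx <- fit_indices(chi2, df, chi2_b, df_b, n_total, srmr = srmr)
  group_estimates <- lapply(groups, function(gr) {
    labs <- unique(gr$tmpl$par$label)
    theta[labs]
  })
  names(group_estimates) <- vapply(groups, `[[`, "", "label")
  structure(
    list(level = level, theta = theta, chisq = chi2, df = df,
         cfi = idx$cfi, rmsea = idx$rmsea, srmr = srmr,
         baseline_chisq = chi2_b, baseline_df = df_b,
         n = n_total, groups = vapply(groups, `[[`, "", "label"),
         group_n = vapply(groups, `[[`, 0, "n"),
         group_estimates = group_estimates,
         scaling_factor = 1, convergence = opt$convergence),
    class = "svd_sem_mg"
  )
}

#' @export
print.svd_sem_mg <- function(x, ...) {
  cat(sprintf("Multi-group CFA (%s): %d groups, n = %d, chi2(%d) = %.3f, CFI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$level, length(x$groups), x$n, x$df, x$chisq, x$cfi, x$rmsea,
              x$srmr))
  invisible(x)
}

#' Scaled chi-square difference test for nested models
#'
#' Satorra-Bentler-style scaled difference: with restricted/free test
#' statistics `T_r`, `T_f` (already on the scaled metric), dfs, and scaling
#' factors `c_r`, `c_f`, the difference scaling factor is
#' `cd = (df_r c_r - df_f c_f) / (df_r - df_f)` and the statistic
#' `(T_r c_r - T_f c_f) / cd` on `df_r - df_f` degrees of freedom. With both
#' scaling factors 1 (plain ML) this reduces to `T_r - T_f`. Negative scaled
#' differences are floored at 0 with a warning. Fits may be supplied as
#' `svd_sem_mg` objects or via the numeric arguments.
#'
#' @param fit_restricted,fit_free nested fits on identical data (restricted
#'   = more constraints, larger df), or numeric test statistics.
#' @param df_restricted,df_free dfs when statistics are passed numerically.
#' @param scaling_restricted,scaling_free scaling factors (default 1; may be
#'   injected from a robust estimator).
#' @return list with `statistic`, `df`, `p`, `scaling`.
#' @export
scaled_chisq_diff <- function(fit_restricted, fit_free,
                              df_restricted = NULL, df_free = NULL,
                              scaling_restricted = NULL, scaling_free = NULL) {
  getf <- function(f, what, default = NULL) {
    if (inherits(f, "svd_sem_mg") || inherits(f, "svd_sem")) f[[what]] else default
  }
  Tr <- if (is.numeric(fit_restricted)) fit_restricted else fit_restricted$chisq
  Tf <- if (is.numeric(fit_free)) fit_free else fit_free$chisq
  dfr <- df_restricted %||% getf(fit_restricted, "df")
  dff <- df_free %||% getf(fit_free, "df")
  cr <- scaling_restricted %||% getf(fit_restricted, "scaling_factor", 1) %||% 1
  cf <- scaling_free %||% getf(fit_free, "scaling_factor", 1) %||% 1
  if (is.null(dfr) || is.null(dff)) stop("degrees of freedom required")
  if (dfr <= dff) stop("models not nested: df_restricted must exceed df_free")
  ddf <- dfr - dff
  cd <- (dfr * cr - dff * cf) / ddf
  stat <- (Tr * cr - Tf * cf) / cd
  if (stat < 0) {
    warning("negative scaled chi-square difference floored at 0")
    stat <- 0
  }
  list(statistic = stat, df = ddf, p = stats::pchisq(stat, ddf, lower.tail = FALSE),
       scaling = cd)
}

#' Fit the full measurement-invariance ladder across sites
#'
#' Configural, metric (equal loadings), and residual (equal indicator
#' residual variances and equal latent variance) levels, with chi-square
#' difference tests between adjacent levels.
#'
#' @param data participant-level data.
#' @param spec measurement spec.
#' @param group grouping column.
#' @return object of class `invariance_ladder`: per-level fits and the
#'   comparison table.
#' @export
fit_invariance <- function(data, spec = measurement_spec(), group = "site") {
  levels_ <- c("configural", "metric", "residual")
  fits <- lapply(levels_, function(lv) {
    fit_multigroup(data, spec, group = group, level = lv)
  })
  names(fits) <- levels_
  comp <- list()
  for (i in 2:3) {
    d <- scaled_chisq_diff(fits[[i]], fits[[i - 1]])
    comp[[length(comp) + 1]] <- data.frame(
      comparison = paste(levels_[i], "vs", levels_[i - 1]),
      statistic = d$statistic, df = d$df, p = d$p
    )
  }
  table <- data.frame(
    level = levels_,
    chisq = vapply(fits, `[[`, 0, "chisq"),
    df = vapply(fits, `[[`, 0, "df"),
    cfi = vapply(fits, `[[`, 0, "cfi"),
    rmsea = vapply(fits, `[[`, 0, "rmsea"),
    srmr = vapply(fits, `[[`, 0, "srmr")
  )
  structure(list(fits = fits, table = table,
                 comparisons = do.call(rbind, comp)),
            class = "invariance_ladder")
}

#' @export
print.invariance_ladder <- function(x, ...) {
  cat("Measurement-invariance ladder:\n")
  print(transform(x$table, chisq = round(chisq, 3), cfi = round(cfi, 3),
                  rmsea = round(rmsea, 3), srmr = round(srmr, 3)),
        row.names = FALSE)
  cat("Nested comparisons (chi-square difference):\n")
  print(transform(x$comparisons, statistic = round(statistic, 3),
                  p = round(p, 3)), row.names = FALSE)
  invisible(x)
}
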