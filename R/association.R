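# Association models: Gaussian identity-link GLMs of cognitive outcomes on
# factor scores or individual markers, with profile-likelihood confidence
# intervals and per-domain Benjamini-Hochberg FDR control.

MODEL1_COVARIATES <- c("age", "sex", "race_ethnicity", "education", "site",
                       "icv", "language", "mri_cog_interval", "mri_first")
MODEL2_COVARIATES <- c(MODEL1_COVARIATES, "sbp", "antihypertensive",
                       "diabetes", "hyperlipidemia", "smoking", "alcohol",
                       "whr", "physical_activity")
MODEL3_COVARIATES <- c(MODEL2_COVARIATES, "apoe4")

#' Covariate set for an adjustment level
#' @param level 1 (demographics/design), 2 (+ vascular risk factors), or
#'   3 (+ APOE e4).
#' @return character vector of covariate column names.
#' @export
model_covariates <- function(level) {
  switch(as.character(level),
         "1" = MODEL1_COVARIATES,
         "2" = MODEL2_COVARIATES,
         "3" = MODEL3_COVARIATES,
         stop("level must be 1, 2 or 3"))
}

#' Profile-likelihood confidence interval for one coefficient
#'
#' Profiles the log-likelihood over the focal coefficient by refitting the
#' model with the focal term moved into an offset, and inverts the deviance
#' at the `level` chi-square(1) cutoff by root finding. A monotone profile
#' on one side yields a one-sided interval with a warning.
#'
#' @param fit a fitted [stats::glm()].
#' @param parameter coefficient name.
#' @param level confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  if (!parameter %in% names(stats::coef(fit))) {
    stop("unknown parameter: ", parameter)
  }
  est <- stats::coef(fit)[[parameter]]
  se <- sqrt(stats::vcov(fit)[parameter, parameter])
  if (!is.finite(se) || se <= 0) stop("degenerate fit: no finite standard error")
  if (stats::family(fit)$family == "gaussian" &&
      fit$deviance <= 1e-10 * max(1, sum(fit$y^2))) {
    stop("degenerate fit: zero residual variance, profile undefined")
  }
  mf <- stats::model.frame(fit)
  X <- stats::model.matrix(fit)
  y <- stats::model.response(mf)
  xj <- X[, parameter]
  Xr <- X[, setdiff(colnames(X), parameter), drop = FALSE]
  w <- stats::weights(fit) %||% rep(1, length(y))
  base_off <- fit$offset %||% rep(0, length(y))
  ll_full <- as.numeric(stats::logLik(fit))
  cutoff <- stats::qchisq(level, 1) / 2
  prof <- function(b) {
    f <- stats::glm.fit(Xr, y, weights = w, offset = base_off + b * xj,
                        family = fit$family)
    cls <- c(f$class, "glm", "lm")
    f$call <- fit$call
    class(f) <- cls
    ll_full - as.numeric(stats::logLik(f)) - cutoff
  }
  find_side <- function(dir) {
    step <- se
    lo <- est
    for (i in 1:30) {
      cand <- est + dir * step * 2
      if (prof(cand) > 0) {
        return(stats::uniroot(prof, sort(c(lo, cand)), tol = se * 1e-6)$root)
      }
      lo <- cand
      step <- step * 2
    }
    warning("monotone profile: one-sided interval on the ",
            if (dir < 0) "lower" else "upper", " side")
    dir * Inf
  }
  c(lower = find_side(-1), upper = find_side(1))
}

#' Fit one cognitive association model
#'
#' Gaussian identity-link GLM of `outcome` on `predictor` plus the level-1,
#' -2 or -3 covariate set, with listwise deletion and a profile-likelihood
#' 95% CI for the predictor coefficient.
#'
#' @param table scored cohort table.
#' @param outcome outcome column (a cognitive score).
#' @param predictor main predictor column (factor score or marker).
#' @param level adjustment level (1, 2, 3).
#' @param covariates optional explicit covariate set overriding `level`.
#' @param ci compute the profile-likelihood CI (disable in large calibration
#'   loops where only the p-value is needed).
#' @return object of class `svd_association` (also a list row: outcome,
#'   predictor, level, beta, ci, p, n).
#' @export
fit_association <- function(table, outcome, predictor, level = 1,
                            covariates = NULL, ci = TRUE) {
  covariates <- covariates %||% model_covariates(level)
  covariates <- intersect(covariates, names(table))
  vars <- c(outcome, predictor, covariates)
  dat <- as.data.frame(table)[vars]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  rhs <- paste(c(sprintf("`%s`", predictor),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs))
  fit <- stats::glm(fml, data = dat, family = stats::gaussian())
  if (nrow(dat) <= length(stats::coef(fit))) {
    stop("fewer complete observations than parameters")
  }
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop("rank-deficient design; aliased: ",
         paste(names(stats::coef(fit))[alias], collapse = ", "))
  }
  cn <- sprintf("`%s`", predictor)
  if (!cn %in% names(stats::coef(fit))) cn <- predictor
  beta <- stats::coef(fit)[[cn]]
  interval <- if (ci) profile_ci(fit, cn) else c(lower = NA_real_, upper = NA_real_)
  sm <- summary(fit)$coefficients
  structure(
    list(outcome = outcome, predictor = predictor, level = level,
         beta = beta, ci = interval, p = sm[cn, 4], n = nrow(dat),
         covariates = covariates, fit = fit),
    class = "svd_association"
  )
}

#' @export
print.svd_association <- function(x, ...) {
  cat(sprintf("%s ~ %s (Model %d, n = %d): beta = %.3f [%.3f, %.3f], p = %.3g\n",
              x$outcome, x$predictor, x$level, x$n, x$beta,
              x$ci[["lower"]], x$ci[["upper"]], x$p))
  invisible(x)
}

#' Run a batch of association models
#'
#' @param table scored cohort table.
#' @param jobs data.frame with columns `outcome`, `predictor`, `level`, and
#'   optionally `domain` (grouping for FDR control); or a YAML path with a
#'   list of such jobs.
#' @param fdr_q FDR level applied within each domain group (set `NULL` to
#'   skip).
#' @return tidy data.frame of results with `fdr_significant` flags.
#' @export
run_associations <- function(table, jobs, fdr_q = 0.05) {
  if (is.character(jobs)) {
    jl <- yaml::read_yaml(jobs)
    jobs <- do.call(rbind, lapply(jl, as.data.frame))
  }
  res <- lapply(seq_len(nrow(jobs)), function(i) {
    a <- fit_association(table, jobs$outcome[i], jobs$predictor[i],
                         jobs$level[i] %||% 1)
    data.frame(outcome = a$outcome, predictor = a$predictor, level = a$level,
               beta = a$beta, ci_lower = a$ci[["lower"]],
               ci_upper = a$ci[["upper"]], p = a$p, n = a$n)
  })
  out <- do.call(rbind, res)
  out$domain <- jobs$domain %||% out$outcome
  if (!is.null(fdr_q)) {
    out$fdr_significant <- bh_fdr(out$p, q = fdr_q, grouping = out$domain)
  }
  out
}

#' Benjamini-Hochberg FDR control within groups
#'
#' Step-up procedure applied independently within each grouping level
#' (cognitive domain).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @param grouping optional grouping vector (default: one group).
#' @return logical rejection flags.
#' @export
bh_fdr <- function(p_values, q = 0.05, grouping = NULL) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  if (is.null(grouping)) grouping <- rep(1, length(p_values))
  flags <- logical(length(p_values))
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    flags[idx] <- stats::p.adjust(p_values[idx], method = "BH") <= q
  }
  flags
}
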