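# SEM engine: template assembly, ML fitting, fit indices, effect
# decomposition, BC bootstrap, single-indicator comparison.

test_that("template assembly counts free parameters correctly", {
  spec <- measurement_spec()
  obs <- SVD_INDICATORS
  attr(obs, "covariate_cols") <- character(0)
  tmpl <- svdlatent:::build_sem_template(spec, obs)
  # 6 free loadings, 6 residual variances, 3 residual covariances
  expect_identical(sum(grepl("=~", tmpl$par$label)), 6L)
  expect_identical(nrow(tmpl$par), 15L)
  # duplicate slot declarations error
  spec2 <- measurement_spec()
  spec2$residual_covariances <- c(spec2$residual_covariances,
                                  list(c("wm_fa", "wm_tr")))
  expect_error(svdlatent:::build_sem_template(spec2, obs), "duplicate")
})

test_that("sem_spec validates structure", {
  expect_error(sem_spec(latents = list(svd = "only_one")), "under-identified")
  expect_error(sem_spec(regressions = list(a = "b", b = "a")), "cyclic")
})

test_that("the population covariance matches hand path-tracing", {
  pop <- sem_population("age")
  L <- cohort_marker_loadings()[SVD_INDICATORS, 1]
  sc <- default_structural_coefficients("age")
  C <- pop$cov
  # cov(indicator, exposure) = loading * (x -> svd)
  expect_equal(C["wmh_periventricular", "age"], L[["wmh_periventricular"]] * sc$x_svd,
               tolerance = 1e-12)
  # cov(two indicators) = product of loadings + residual covariance
  L2 <- cohort_marker_loadings()
  expect_equal(C["wm_fa", "wm_tr"],
               L[["wm_fa"]] * L[["wm_tr"]] + L2["wm_fa", 2] * L2["wm_tr", 2],
               tolerance = 1e-12)
  expect_equal(C["pvs_basal_ganglia", "wmh_subcortical"],
               L[["pvs_basal_ganglia"]] * L[["wmh_subcortical"]],
               tolerance = 1e-12)
  # cov(gm, x) = svd_gm * x_svd + x_gm
  expect_equal(C["gm_volume", "age"], sc$svd_gm * sc$x_svd + sc$x_gm,
               tolerance = 1e-12)
  # everything standardized
  expect_equal(unname(diag(C)), rep(1, 9), tolerance = 1e-12)
  # total effect equals the printed-arithmetic sum by construction
  expect_equal(sc$x_svd * sc$svd_cog + sc$x_svd * sc$svd_gm * sc$gm_cog +
                 sc$x_gm * sc$gm_cog + sc$x_cog, -0.071, tolerance = 1e-12)
})

test_that("fitting the exact population covariance gives a perfect fit", {
  pop <- sem_population("age")
  fit <- fit_sem(S = pop$cov, n = 892, spec = pop$spec)
  expect_lt(fit$fml, 1e-8)
  expect_lt(fit$chisq, 1e-4)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0, tolerance = 1e-4)
  expect_lt(fit$srmr, 1e-4)
  expect_equal(fit$df, 21)
  # standardized estimates equal the generating standardized truth
  dev <- fit$standardized[names(pop$theta_std)] - pop$theta_std
  expect_lt(max(abs(dev)), 1e-4)
})

test_that("chi-square is calibrated under a correctly specified model", {
  set.seed(81)
  reps <- 30
  stats_ <- vapply(seq_len(reps), function(i) {
    d <- simulate_sem_population(600, "age")
    fit_sem(d, default_sem_spec("age", covariates = character(0)))$chisq
  }, numeric(1))
  # mean of chi2(21) is 21; MC SE of the mean is sqrt(2*21/30) ~ 1.18
  expect_lt(abs(mean(stats_) - 21), 4)
})

test_that("fit indices match hand arithmetic", {
  idx <- fit_indices(100, 36, 1000, 45, 892)
  expect_equal(idx$cfi, 1 - 64 / 955, tolerance = 1e-12)
  expect_equal(idx$rmsea, sqrt(64 / (36 * 891)), tolerance = 1e-12)
  idx2 <- fit_indices(36, 36, 500, 45, 892)
  expect_identical(idx2$cfi, 1)
  expect_identical(idx2$rmsea, 0)
  expect_identical(fit_indices(5, 0, 100, 10, 50)$rmsea, 0)
})

test_that("decompose_paths performs the mediation arithmetic", {
  d <- decompose_paths(0.1, c(m = 0.5 * 0.4))
  expect_equal(d$total_indirect, 0.2)
  expect_equal(d$total, 0.3)
  expect_equal(d$proportion_mediated, 100 * 0.2 / 0.3)
  expect_warning(d0 <- decompose_paths(0, c(m = 0)), "undefined")
  expect_true(is.na(d0$proportion_mediated))
})

test_that("decomposition identities hold on fitted models and resamples", {
  set.seed(82)
  d <- simulate_sem_population(1500, "age")
  spec <- default_sem_spec("age", covariates = character(0))
  fit <- fit_sem(d, spec)
  dec <- decompose_effects(fit)
  expect_equal(dec$total, dec$direct + dec$total_indirect, tolerance = 1e-12)
  expect_equal(dec$total_indirect, sum(dec$pathways), tolerance = 1e-12)
  expect_identical(length(dec$pathways), 3L)
  # identity survives resampling
  for (i in 1:3) {
    idx <- sample.int(nrow(d), nrow(d), replace = TRUE)
    dd <- decompose_effects(fit_sem(d[idx, ], spec))
    expect_equal(dd$total, dd$direct + sum(dd$pathways), tolerance = 1e-12)
  }
})

test_that("standardized solutions are scale-invariant", {
  set.seed(83)
  d <- simulate_sem_population(4000, "age")
  spec <- default_sem_spec("age", covariates = character(0))
  f1 <- fit_sem(d, spec, standardize = TRUE)
  draw <- d
  draw$gm_volume <- draw$gm_volume * 64803 + 599773   # raw units
  draw$age <- draw$age * 7.9 + 73.6
  f2 <- fit_sem(draw, spec, standardize = FALSE)
  common <- names(f1$standardized)
  expect_equal(f1$standardized[common], f2$standardized[common],
               tolerance = 1e-4)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-4)
})

test_that("bias-corrected bootstrap behaves per its contracts", {
  set.seed(84)
  n <- 1500
  md <- data.frame(x = rnorm(n))
  md$m <- 0.4 * md$x + sqrt(1 - 0.16) * rnorm(n)
  md$y <- 0.4 * md$m + sqrt(1 - 0.16) * rnorm(n)
  stat <- function(dd) {
    S <- cov(dd)
    a <- S["x", "m"] / S["x", "x"]
    b <- solve(S[c("m", "x"), c("m", "x")], S[c("m", "x"), "y"])[["m"]]
    c(indirect = a * b, a = a)
  }
  ci <- bootstrap_bc_ci(md, stat, n_boot = 500, seed = 1)
  expect_identical(nrow(ci), 2L)
  expect_true(all(ci$lower < ci$estimate & ci$estimate < ci$upper))
  # reproducible given the seed
  ci2 <- bootstrap_bc_ci(md, stat, n_boot = 500, seed = 1)
  expect_identical(ci, ci2)
  # z0 ~ 0 implies BC endpoints ~ plain percentile endpoints
  expect_lt(abs(ci$z0[2]), 0.15)
  # degenerate statistic: zero-width interval with a warning
  expect_warning(
    cid <- bootstrap_bc_ci(md, function(dd) c(k = 1), n_boot = 200, seed = 2),
    "degenerate")
  expect_identical(cid$lower, cid$upper)
  # failure budget: a statistic failing on most resamples errors out
  # (resamples contain duplicated rows; the original data do not)
  flaky <- function(dd) {
    if (anyDuplicated(dd$x)) stop("boom")
    c(s = mean(dd$x))
  }
  expect_error(bootstrap_bc_ci(md, flaky, n_boot = 200, seed = 3), "failed")
  expect_error(bootstrap_bc_ci(md, stat, n_boot = 50), "100")
})

test_that("BC endpoints equal plain percentiles for a symmetric bootstrap", {
  set.seed(85)
  d <- data.frame(v = rnorm(4001))
  ci <- bootstrap_bc_ci(d, function(dd) c(m = median(dd$v)), n_boot = 999,
                        seed = 4)
  # median resampling of a symmetric sample: z0 essentially 0
  expect_lt(abs(ci$z0), 0.1)
})

test_that("single-indicator models attenuate relative to the latent model", {
  set.seed(86)
  d <- simulate_sem_population(8000, "age")
  tab <- single_indicator_comparison(d, exposure = "age")
  lat <- tab[tab$model == "latent_svd", ]
  singles <- tab[tab$model != "latent_svd", ]
  expect_true(all(abs(lat$indirect_via_mediator) >
                    abs(singles$indirect_via_mediator)))
  expect_true(lat$r2_outcome >= max(singles$r2_outcome) - 1e-6)
  # a pure-noise mediator transmits nothing
  d$noise_marker <- rnorm(nrow(d))
  tabn <- single_indicator_comparison(d, exposure = "age",
                                      indicators = "noise_marker")
  expect_lt(abs(tabn$indirect_via_mediator[tabn$mediator == "noise_marker"]),
            0.01)
})

test_that("an error-free indicator reproduces the latent model", {
  set.seed(87)
  n <- 20000
  x <- rnorm(n)
  svd_lat <- 0.5 * x + sqrt(0.75) * rnorm(n)
  gm <- -0.3 * svd_lat + sqrt(1 - 0.09) * rnorm(n)
  y <- -0.4 * svd_lat + 0.3 * gm + sqrt(1 - var(-0.4 * svd_lat + 0.3 * gm)) * rnorm(n)
  d <- data.frame(x = x, perfect = svd_lat, gm_volume = gm,
                  global_cognition = y)
  spec_obs <- sem_spec(
    regressions = list(perfect = "x",
                       gm_volume = c("x", "perfect"),
                       global_cognition = c("x", "perfect", "gm_volume")),
    exposure = "x", outcome = "global_cognition")
  fit <- fit_sem(d, spec_obs)
  dec <- decompose_effects(fit)
  # structural paths recovered without attenuation
  expect_equal(unname(fit$standardized["perfect~x"]), 0.5, tolerance = 0.03)
  expect_equal(unname(fit$standardized["global_cognition~perfect"]), -0.4,
               tolerance = 0.03)
  expect_equal(dec$total, cov(x, y) / sd(x) / sd(y), tolerance = 0.01)
})

test_that("simulate() round-trips the implied covariance", {
  pop <- sem_population("age")
  fit <- fit_sem(S = pop$cov, n = 2000, spec = pop$spec)
  sim <- simulate(fit, seed = 9, n = 60000)
  expect_identical(dim(sim), c(60000L, 9L))
  expect_lt(max(abs(cov(sim) - fit$sigma)), 0.03)
  sim2 <- simulate(fit, seed = 9, n = 100)
  sim3 <- simulate(fit, seed = 9, n = 100)
  expect_identical(sim2, sim3)
})

test_that("sem_mediation attaches bootstrap BC intervals to the decomposition", {
  set.seed(89)
  d <- simulate_sem_population(800, "age")
  med <- sem_mediation(d, default_sem_spec("age", covariates = character(0)),
                       n_boot = 100, seed = 10)
  expect_s3_class(med, "effect_decomposition")
  expect_identical(nrow(med$ci), 6L)   # total, direct, total indirect, 3 paths
  expect_true(all(med$ci$lower <= med$ci$estimate &
                    med$ci$estimate <= med$ci$upper))
  tot <- med$ci[med$ci$statistic == "total", ]
  expect_equal(tot$estimate, med$total, tolerance = 1e-12)
})

test_that("vcov gives usable asymptotic standard errors", {
  set.seed(88)
  d <- simulate_sem_population(5000, "age")
  fit <- fit_sem(d, default_sem_spec("age", covariates = character(0)))
  V <- vcov(fit)
  se <- sqrt(diag(V))
  expect_true(all(is.finite(se) & se > 0))
  # loading SEs shrink like 1/sqrt(n): compare against a bigger sample
  expect_lt(se[["svd=~wmh_periventricular"]], 0.05)
})
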