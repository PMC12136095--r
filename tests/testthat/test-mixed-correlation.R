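# Mixed correlation matrix: estimator oracles, dispatch, smoothing, KMO.

test_that("pearson_cor obeys the basic contracts", {
  x <- rnorm(100)
  expect_equal(pearson_cor(x, x), 1)
  expect_equal(pearson_cor(x, -x), -1)
  expect_error(pearson_cor(x, rep(1, 100)), "zero-variance")
  set.seed(1)
  a <- rnorm(1e5); b <- rnorm(1e5)
  expect_lt(abs(pearson_cor(a, b)), 0.01)
})

test_that("tetrachoric matches the grid-search quadrature oracle", {
  expect_equal(tetrachoric(matrix(c(25, 25, 25, 25), 2, 2)), 0,
               tolerance = 1e-6)
  tab <- matrix(c(40, 10, 10, 40), 2, 2)
  est <- tetrachoric(tab)
  expect_equal(est, oracle_tetrachoric(tab), tolerance = 1e-3)
  # symmetric margins admit a closed form: rho = sin(2 pi (p11 - 1/4))
  expect_equal(est, closed_form_tetrachoric_symmetric(0.4), tolerance = 1e-6)
  # an asymmetric table as well
  tab2 <- matrix(c(60, 15, 5, 20), 2, 2)
  expect_equal(tetrachoric(tab2), oracle_tetrachoric(tab2), tolerance = 1e-3)
})

test_that("tetrachoric handles zero cells and empty margins", {
  tab <- matrix(c(50, 10, 0, 40), 2, 2)
  est <- tetrachoric(tab)
  expect_true(is.finite(est) && abs(est) < 1)
  expect_equal(est, oracle_tetrachoric(tab + 0.5), tolerance = 1e-3)
  expect_error(tetrachoric(matrix(c(0, 0, 30, 40), 2, 2)), "margin")
  expect_error(tetrachoric(matrix(0, 2, 2)), "empty")
})

test_that("tetrachoric is antisymmetric under swapping one margin's labels", {
  tab <- matrix(c(55, 12, 8, 35), 2, 2)
  expect_equal(tetrachoric(tab[, 2:1]), -tetrachoric(tab), tolerance = 1e-6)
  expect_equal(tetrachoric(tab[2:1, ]), -tetrachoric(tab), tolerance = 1e-6)
})

test_that("biserial matches simulation oracles under the liability model", {
  set.seed(21)
  n <- 1e6
  z <- rnorm(n)
  # liability identical to x: biserial approaches 1 (and may be clamped)
  est1 <- suppressWarnings(biserial(z, as.integer(z > 0)))
  expect_equal(est1, 1, tolerance = 0.01)
  # latent correlation 0.5, prevalence 0.3
  x <- 0.5 * z + sqrt(0.75) * rnorm(n)
  y <- as.integer(z > qnorm(0.7))
  expect_equal(biserial(x, y), 0.5, tolerance = 0.01)
  # independence
  expect_lt(abs(biserial(rnorm(1e5), rbinom(1e5, 1, 0.3))), 0.02)
  expect_error(biserial(z[1:50], rep(1, 50)), "single-class")
})

test_that("mixed_cor dispatches by kind and matches plain correlations", {
  set.seed(31)
  d <- as.data.frame(matrix(rnorm(300), 100, 3))
  kinds <- setNames(rep("continuous", 3), names(d))
  mc <- mixed_cor(d, kinds)
  expect_equal(unname(mc$rho), unname(cor(d)), tolerance = 1e-12)
  expect_true(all(mc$kind[upper.tri(mc$kind)] == "pearson"))
  # cohort markers: 3 tetrachoric pairs among the MB flags
  pp <- prepare_markers(test_cohort(n = 600, seed = 13))
  mcc <- mixed_cor(pp)
  expect_identical(sum(mcc$kind == "tetrachoric") / 2, 3)
  expect_identical(sum(mcc$kind == "biserial") / 2, 30)  # 10 continuous x 3 binary
  expect_true(isSymmetric(mcc$rho))
  expect_equal(unname(diag(mcc$rho)), rep(1, 13))
  expect_true(all(abs(mcc$rho) <= 1))
})

test_that("mixed_cor is invariant to row order and close to the population", {
  cc <- prepare_markers(test_cohort(n = 500, seed = 17))
  m1 <- mixed_cor(cc)
  m2 <- mixed_cor(cc[rev(seq_len(nrow(cc))), ])
  expect_equal(m1$rho, m2$rho, tolerance = 1e-10)

  # population check at n = 1e5: all pairs within 0.02 of the implied matrix
  cfg <- cohort_config()
  L <- cfg$loading_matrix
  mb <- cfg$mb_specs
  Lall <- rbind(L, do.call(rbind, lapply(mb, `[[`, "loadings")))
  rownames(Lall) <- c(rownames(L), names(mb))
  set.seed(41)
  n <- 1e5
  f <- matrix(rnorm(n * 2), n, 2)
  h2 <- rowSums(Lall^2)
  z <- f %*% t(Lall) + matrix(rnorm(n * nrow(Lall)), n) %*%
    diag(sqrt(1 - h2), nrow(Lall))
  colnames(z) <- rownames(Lall)
  d <- as.data.frame(z)
  for (nm in names(mb)) {
    d[[nm]] <- as.integer(d[[nm]] > qnorm(1 - mb[[nm]]$prevalence))
  }
  kinds <- setNames(c(rep("continuous", nrow(L)), rep("binary", 3)),
                    rownames(Lall))
  mc <- mixed_cor(d, kinds)
  expect_lt(max(abs(mc$rho - implied_sigma(Lall))), 0.02)
})

test_that("smoothing respects the entry-change cap", {
  R <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(svdlatent:::smooth_correlation(R, max_change = 0.05), "cap")
  # a mildly indefinite matrix (min eigenvalue ~ -0.036) is repaired and flagged
  R2 <- matrix(c(1, 0.8, 0.8, 0.8, 1, 0.2, 0.8, 0.2, 1), 3, 3)
  sm <- svdlatent:::smooth_correlation(R2, max_change = 0.2)
  expect_true(sm$smoothed)
  expect_gte(min(eigen(sm$mat)$values), 1e-6 - 1e-12)
  expect_equal(unname(diag(sm$mat)), rep(1, 3))
})

test_that("kmo agrees with hand-computed partial-correlation oracles", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  expect_equal(kmo(R)$overall, oracle_kmo_equicorrelated(3, 0.5),
               tolerance = 1e-10)
  expect_equal(kmo(R)$overall, 6 * 0.25 / (6 * 0.25 + 6 / 9),
               tolerance = 1e-10)
  expect_equal(unname(kmo(R)$msa), rep(oracle_kmo_equicorrelated(3, 0.5), 3),
               tolerance = 1e-10)
  # two-block matrix: within-block 0.6, between 0; partials are 0.6/(1.36-...)
  B <- diag(4)
  B[1, 2] <- B[2, 1] <- B[3, 4] <- B[4, 3] <- 0.6
  inv <- solve(B)
  q <- -inv / sqrt(tcrossprod(diag(inv))); diag(q) <- 0
  oracle <- sum(B[upper.tri(B)]^2) /
    (sum(B[upper.tri(B)]^2) + sum(q[upper.tri(q)]^2))
  expect_equal(kmo(B)$overall, oracle, tolerance = 1e-10)
  # near-diagonal: defined limit 0 with a warning
  D <- diag(5); D[upper.tri(D)] <- D[lower.tri(D)] <- 1e-8
  expect_warning(k0 <- kmo(D), "not factorable")
  expect_identical(k0$overall, 0)
})

test_that("mixed_cor round-trips through CSV + JSON sidecar", {
  pp <- prepare_markers(test_cohort(n = 300, seed = 19))
  mc <- mixed_cor(pp)
  tmp <- tempfile(fileext = ".csv")
  write_mixed_cor(mc, tmp)
  back <- read_mixed_cor(tmp)
  expect_equal(back$rho, mc$rho, tolerance = 1e-12)
  expect_identical(unname(back$kinds), unname(mc$kinds))
  unlink(c(tmp, paste0(tmp, ".json")))
})
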