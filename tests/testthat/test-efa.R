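# Factor extraction, factor-count criteria, pruning, rotation, extension
# analysis, and regression factor scores.

test_that("minres recovers exact low-rank-plus-diagonal structures", {
  lam <- matrix(c(0.8, 0.7, 0.6), 3, 1)
  f <- minres_fit(implied_sigma(lam), 1)
  expect_equal(unname(f$loadings[, 1]), c(0.8, 0.7, 0.6), tolerance = 1e-4)
  expect_lt(f$objective, 1e-9)
  # identity: no common variance, loadings 0, objective 0
  f0 <- minres_fit(diag(5), 1)
  expect_lt(max(abs(f0$loadings)), 1e-4)
  expect_lt(f0$objective, 1e-9)
})

test_that("minres + varimax reproduces the generating two-factor pattern", {
  L <- default_marker_loadings()[1:9, ]
  f <- minres_fit(implied_sigma(L), 2)
  rot <- rotate_loadings(f$loadings, "varimax")
  al <- align_loadings(rot$loadings, L)
  expect_lt(max(abs(al - L)), 0.01)
  # communalities h2 + uniqueness = 1, variance explained ordered
  h2 <- rowSums(al^2)
  expect_equal(unname(h2 + f$uniquenesses[rownames(L)]), rep(1, 9),
               tolerance = 0.02)
  ve <- colMeans(al^2)
  expect_true(ve[1] >= ve[2])
})

test_that("minres enforces identification preconditions", {
  R <- implied_sigma(default_marker_loadings()[1:4, ])
  expect_error(minres_fit(R, 0), ">= 1")
  expect_error(minres_fit(R, 4), "smaller")
  expect_error(minres_fit(R, 2), "Ledermann")
})

test_that("MAP criterion finds the generating factor count", {
  L2 <- default_marker_loadings()[1:9, ]
  expect_identical(as.integer(map_criterion(implied_sigma(L2), 4)), 2L)
  lam1 <- matrix(c(0.8, 0.75, 0.7, 0.65, 0.6), 5, 1)
  expect_identical(as.integer(map_criterion(implied_sigma(lam1), 3)), 1L)
  m0 <- map_criterion(diag(6), 3)
  expect_identical(as.integer(m0), 0L)
  expect_true(attr(m0, "no_common_factors"))
})

test_that("VSS criterion finds the generating count with values in [0, 1]", {
  L2 <- default_marker_loadings()[1:9, ]
  v <- vss_criterion(implied_sigma(L2), 4)
  expect_identical(as.integer(v), 2L)
  expect_true(all(attr(v, "profile") >= 0 & attr(v, "profile") <= 1))
  v2 <- vss_criterion(implied_sigma(L2), 4, complexity = 2)
  expect_identical(as.integer(v2), 2L)
  lam1 <- matrix(c(0.8, 0.75, 0.7, 0.65, 0.6), 5, 1)
  expect_identical(as.integer(vss_criterion(implied_sigma(lam1), 3)), 1L)
})

test_that("factor-count selection lets MAP govern on disagreement", {
  sel <- choose_factor_count(implied_sigma(default_marker_loadings()[1:9, ]))
  expect_identical(sel$k, 2L)
})

test_that("rotation contracts: k = 1 identity, varimax communalities, restore", {
  L1 <- matrix(c(0.8, 0.7, 0.6), 3, 1)
  r1 <- rotate_loadings(L1, "varimax")
  expect_equal(unname(r1$loadings), unname(L1))
  expect_identical(r1$method, "none")

  L <- default_marker_loadings()[1:9, ]
  set.seed(77)
  Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  scrambled <- L %*% Q
  rv <- rotate_loadings(scrambled, "varimax")
  # communalities preserved by orthogonal rotation
  expect_equal(rowSums(rv$loadings^2), rowSums(scrambled^2), tolerance = 1e-8,
               ignore_attr = TRUE)
  al <- align_loadings(rv$loadings, L)
  cong <- vapply(1:2, function(j) {
    sum(al[, j] * L[, j]) / sqrt(sum(al[, j]^2) * sum(L[, j]^2))
  }, numeric(1))
  expect_true(all(cong > 0.999))
})

test_that("oblimin on an orthogonal truth returns a near-zero phi", {
  L <- default_marker_loadings()[1:9, ]
  f <- minres_fit(implied_sigma(L), 2)
  ob <- rotate_loadings(f$loadings, "oblimin")
  expect_lt(abs(ob$phi[1, 2]), 0.05)
  expect_equal(unname(diag(ob$phi)), c(1, 1), tolerance = 1e-8)
})

test_that("the rotation decision rule is strict at 0.32", {
  expect_identical(choose_rotation(matrix(c(1, 0.005, 0.005, 1), 2))$rotation,
                   "varimax")
  expect_identical(choose_rotation(matrix(c(1, 0.5, 0.5, 1), 2))$rotation,
                   "oblimin")
  expect_identical(choose_rotation(matrix(c(1, 0.32, 0.32, 1), 2))$rotation,
                   "oblimin")
  expect_identical(choose_rotation(matrix(c(1, -0.5, -0.5, 1), 2))$rotation,
                   "oblimin")
})

test_that("salient loadings follow the inclusive 0.32 rule", {
  L <- default_marker_loadings()[1:9, ]
  m <- salient_loadings(L)
  expect_identical(sum(m[, 1]), 6L)   # includes FA at -0.73
  expect_true(m["wm_fa", 1])
  expect_identical(sum(m[, 2]), 3L)
  expect_identical(length(attr(m, "cross_loadings")), 0L)
  expect_identical(sum(salient_loadings(matrix(0, 4, 2))), 0L)
  expect_true(salient_loadings(matrix(0.32, 1, 1))[1, 1])
})

test_that("pruning removes low-communality indicators iteratively", {
  pp <- prepare_markers(test_cohort(n = 892, seed = 11))
  pr <- prune_low_communality(pp, k = 2)
  expect_setequal(pr$history$variable,
                  c("mb_lobar", "mb_deep", "mb_infratentorial", "pvs_brainstem"))
  expect_true(all(pr$history$h2 < 0.2))
  expect_setequal(pr$retained,
                  c(SVD_INDICATORS, "pvs_frontoparietal", "pvs_temporal",
                    "pvs_insular"))
  expect_true(all(pr$fit$communalities >= 0.2))
  # no removals when everything is well explained
  strong <- as.data.frame(generate_indicators(
    2000, default_marker_loadings()[c(2, 3, 4, 6, 7, 9), ], seed = 3)$z)
  kinds <- setNames(rep("continuous", 6), names(strong))
  pr2 <- prune_low_communality(strong, kinds, k = 2)
  expect_identical(nrow(pr2$history), 0L)
  # cannot prune below an identifiable variable count
  set.seed(97)
  weak <- as.data.frame(matrix(rnorm(300 * 6), 300, 6))
  kw <- setNames(rep("continuous", 6), names(weak))
  expect_error(prune_low_communality(weak, kw, k = 2),
               "identifiable|k \\+ 1")
})

test_that("extension loadings agree with empirical score covariances", {
  L <- default_marker_loadings()[1:9, ]
  set.seed(88)
  n <- 20000
  f <- matrix(rnorm(n * 2), n, 2)
  z <- f %*% t(L) + matrix(rnorm(n * 9), n) %*% diag(sqrt(1 - rowSums(L^2)), 9)
  colnames(z) <- rownames(L)
  # an excluded variable correlated only with factor 1, and a pure-noise one
  extra <- cbind(dup = 0.6 * f[, 1] + 0.8 * rnorm(n), noise = rnorm(n))
  full <- cbind(z, extra)
  Rfull <- cor(full)
  retained <- rownames(L)
  fit <- minres_fit(Rfull[retained, retained], 2)
  rot <- rotate_loadings(fit$loadings, "varimax")
  Lal <- align_loadings(rot$loadings, L)
  ext <- extension_loadings(Rfull, retained, c("dup", "noise"), Lal)
  # empirical route: covariance of the excluded columns with computed scores
  w <- factor_score_weights(Rfull[retained, retained], Lal)
  scores <- scale(z) %*% w$weights
  emp <- cov(extra, scores)
  expect_equal(unclass(ext), emp, tolerance = 0.02, ignore_attr = TRUE)
  expect_lt(max(abs(ext["noise", ])), 0.03)
  # covariance with the score of a variable loading 0.6 on the factor is
  # 0.6 * validity^2 (the regression score has SD equal to its validity)
  expect_equal(unname(ext["dup", 1]), 0.6 * unname(w$validity[1])^2,
               tolerance = 0.03)
})

test_that("regression factor scores satisfy the closed-form contracts", {
  # loadings = identity: scores equal the z-scores themselves
  sol <- diag(2)
  w <- factor_score_weights(diag(2), sol)
  expect_equal(unname(w$weights), diag(2))
  expect_equal(unname(w$validity), c(1, 1))

  # orthogonal two-factor data: score correlations near diagonal
  L <- default_marker_loadings()[1:9, ]
  gi <- generate_indicators(10000, L, seed = 5)
  R <- cor(gi$z)
  fit <- minres_fit(R, 2)
  rot <- rotate_loadings(fit$loadings, "varimax")
  ws <- factor_score_weights(R, rot$loadings)
  sc <- scale(gi$z) %*% ws$weights
  expect_lt(abs(cor(sc)[1, 2]), 0.05)

  # validity matches sqrt(diag(L' R^-1 L)) and the empirical truth correlation
  gi2 <- generate_indicators(100000, L, seed = 6)
  R2 <- cor(gi2$z)
  fit2 <- minres_fit(R2, 2)
  rot2 <- rotate_loadings(fit2$loadings, "varimax")
  al2 <- align_loadings(rot2$loadings, L)
  ws2 <- factor_score_weights(R2, al2)
  sc2 <- scale(gi2$z) %*% ws2$weights
  truth_cor <- cor(sc2[, 1], gi2$factors[, 1])
  closed <- sqrt(diag(t(L) %*% solve(implied_sigma(L)) %*% L))
  expect_equal(abs(truth_cor), unname(closed[1]), tolerance = 0.01)
  expect_equal(unname(ws2$validity[1]), unname(closed[1]), tolerance = 0.01)
})

test_that("fit_efa runs the full pipeline on the default cohort", {
  pp <- prepare_markers(test_cohort(n = 892, seed = 11))
  efa <- fit_efa(pp)
  expect_s3_class(efa, "svd_efa")
  expect_identical(efa$k, 2L)
  expect_identical(efa$rotation, "varimax")
  expect_lt(efa$rotation_decision$max_abs_phi, 0.32)
  expect_identical(length(efa$retained), 9L)
  expect_true(all(efa$communalities >= 0.2))
  # extension analysis: deep MB is the standout excluded variable on factor 1
  ext <- efa$extension
  expect_gt(ext["mb_deep", 1], max(ext[setdiff(rownames(ext), "mb_deep"), 1]))
  expect_gt(ext["mb_deep", 1], 0.25)
  # scores: mean 0, orthogonal-ish
  expect_equal(unname(colMeans(efa$scores)), c(0, 0), tolerance = 1e-8)
  expect_lt(abs(cor(efa$scores)[1, 2]), 0.1)
  # predict on the training data reproduces stored scores
  expect_equal(predict(efa, pp), efa$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  # KMO within a sane adequacy band
  expect_gt(efa$kmo$overall, 0.5)
  # salient pattern: 6 on factor 1, 3 on factor 2, no cross-loadings
  expect_identical(sum(efa$salient[, 1]), 6L)
  expect_identical(sum(efa$salient[, 2]), 3L)
  expect_identical(length(attr(efa$salient, "cross_loadings")), 0L)
  # printing is quiet-clean
  expect_output(print(efa), "Minres factor analysis")
  expect_output(print(summary(efa)), "Variance explained")
})

test_that("minres objective at the solution never exceeds the generator's", {
  for (s in 1:3) {
    set.seed(s)
    k <- sample(1:2, 1)
    p <- sample(6:9, 1)
    L <- matrix(runif(p * k, -0.8, 0.8), p, k)
    while (any(rowSums(L^2) > 0.95)) L <- L * 0.9
    R <- implied_sigma(L)
    f <- minres_fit(R, k)
    off <- upper.tri(R)
    gen_obj <- sum((R - tcrossprod(L))[off]^2)
    expect_lte(f$objective, gen_obj + 1e-10)
    # rotation alignment: orthogonal Procrustes of the recovered loadings
    # onto the generating ones, then per-column congruence
    sv <- svd(t(f$loadings) %*% L)
    al <- f$loadings %*% (sv$u %*% t(sv$v))
    for (j in seq_len(k)) {
      cong <- abs(sum(al[, j] * L[, j]) / sqrt(sum(al[, j]^2) * sum(L[, j]^2)))
      expect_gt(cong, 0.99)
    }
  }
})
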