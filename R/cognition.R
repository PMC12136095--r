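# Cognitive scoring: Tukey ladder-of-powers normalization, a priori domain
# averages, and the PCA-weighted global cognitive composite.

#' Tukey ladder-of-powers normalization
#'
#' Chooses the power from `{-2, -1, -1/2, 0 (log), 1/3, 1/2, 1, 2}` that
#' maximizes the correlation of the transformed sample with normal
#' quantiles. Negative powers are negated to keep the transformation
#' monotone increasing. Non-positive values are shifted to positivity
#' (recorded in the result) before powers requiring it are evaluated.
#'
#' @param x continuous vector.
#' @param grid candidate powers.
#' @return list with `lambda`, `transformed`, `shift`, and the per-power
#'   `criterion` (normal-quantile correlation).
#' @export
tukey_ladder <- function(x, grid = c(-2, -1, -1/2, 0, 1/3, 1/2, 1, 2)) {
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("need at least 3 non-missing values")
  if (stats::sd(x[ok]) == 0) stop("constant vector: transformation undefined")
  shift <- 0
  if (min(x[ok]) <= 0) shift <- -min(x[ok]) + 1e-6 * diff(range(x[ok]))
  xs <- x + shift
  apply_power <- function(v, lam) {
    if (lam == 0) log(v) else if (lam < 0) -(v^lam) else v^lam
  }
  q <- stats::qnorm(stats::ppoints(sum(ok)))
  crit <- vapply(grid, function(lam) {
    tv <- apply_power(xs[ok], lam)
    if (any(!is.finite(tv)) || stats::sd(tv) == 0) return(-Inf)
    stats::cor(sort(tv), q)
  }, numeric(1))
  lam <- grid[which.max(crit)]
  out <- rep(NA_real_, length(x))
  out[ok] <- apply_power(xs[ok], lam)
  list(lambda = lam, transformed = out, shift = shift,
       criterion = stats::setNames(crit, grid))
}

#' Average cognitive domain scores
#'
#' Each domain score is the arithmetic mean of its mapped normalized tests;
#' a participant missing any constituent test gets `NA` for that domain
#' (listwise-within-domain policy).
#'
#' @param battery data.frame containing the normalized test columns.
#' @param mapping named list mapping domains to test columns (default
#'   [default_domain_mapping()]).
#' @return data.frame of domain scores (one column per domain).
#' @export
domain_scores <- function(battery, mapping = default_domain_mapping()) {
  if (!length(mapping)) stop("empty domain mapping")
  missing_tests <- setdiff(unlist(mapping), names(battery))
  if (length(missing_tests)) {
    stop("tests absent from battery: ", paste(missing_tests, collapse = ", "))
  }
  out <- lapply(mapping, function(tests) {
    m <- data.matrix(as.data.frame(battery)[tests])
    rowMeans(m)   # NA if any constituent missing
  })
  as.data.frame(out)
}

#' PCA-weighted global cognitive composite
#'
#' The first principal component of the correlation matrix of the normalized
#' test scores, computed on the cognitively normal subset (listwise
#' complete), supplies unit-norm weights; the composite is the weighted sum
#' of all participants' test scores, oriented so that higher values mean
#' better performance (majority-positive weights).
#'
#' @param battery data.frame with the test columns.
#' @param tests test column names.
#' @param normal logical vector flagging cognitively normal participants
#'   (defaults to a `cognitively_normal` column, else all).
#' @return list with `composite`, `weights`, `pc1_variance`.
#' @export
global_score <- function(battery, tests = intersect(COG_TESTS, names(battery)),
                         normal = NULL) {
  if (length(tests) < 2) stop("need at least 2 tests")
  X <- data.matrix(as.data.frame(battery)[tests])
  if (is.null(normal)) {
    normal <- if ("cognitively_normal" %in% names(battery)) {
      as.logical(battery$cognitively_normal)
    } else rep(TRUE, nrow(X))
  }
  Xn <- X[which(normal), , drop = FALSE]
  Xn <- Xn[stats::complete.cases(Xn), , drop = FALSE]
  if (nrow(Xn) < length(tests)) {
    stop("cognitively normal subset smaller than the number of tests")
  }
  e <- eigen(stats::cor(Xn), symmetric = TRUE)
  w <- e$vectors[, 1]
  if (mean(w >= 0) < 0.5) w <- -w       # majority-positive orientation
  w <- w / sqrt(sum(w^2))
  composite <- drop(X %*% w)
  list(composite = composite,
       weights = stats::setNames(w, tests),
       pc1_variance = e$values[1] / sum(e$values))
}

#' Score the cognitive battery of a cohort
#'
#' Appends the seven domain scores and the global composite to the table.
#'
#' @param table cohort data.frame.
#' @param mapping domain-to-test mapping.
#' @return the table with `domain_*` columns and `global_cognition` added;
#'   PC1 weights in `attr(, "cognition_weights")`.
#' @export
score_cognition <- function(table, mapping = default_domain_mapping()) {
  dom <- domain_scores(table, mapping)
  names(dom) <- paste0("domain_", names(dom))
  g <- global_score(table, tests = unique(unlist(mapping)))
  out <- cbind(as.data.frame(table), dom,
               global_cognition = g$composite)
  for (a in c("latents", "config", "prep")) attr(out, a) <- attr(table, a)
  attr(out, "cognition_weights") <- g$weights
  out
}

#' Read a domain mapping from YAML
#' @param path YAML file mapping domain names to test-name lists.
#' @return named list.
#' @export
read_domain_mapping <- function(path) {
  m <- yaml::read_yaml(path)
  lapply(m, unlist)
}
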