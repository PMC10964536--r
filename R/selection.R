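# Selection module: the feature-reduction cascade — ICC robustness
# filter, Welch t-test filter, greedy correlation pruning, mRMR ranking
# and LASSO with cross-validated lambda.

#' Fit / apply z-score standardization
#'
#' Standardization parameters are fit on training rows only and applied
#' unchanged elsewhere (no test-set leakage). Zero-variance features get
#' unit scale.
#'
#' @param x numeric matrix or data.frame (lesions x features).
#' @return `zscore_fit()`: list with `center` and `scale`;
#'   `zscore_apply()`: the standardized matrix.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

#' @rdname zscore_fit
#' @param fit result of `zscore_fit()`.
#' @export
zscore_apply <- function(x, fit) {
  x <- as.matrix(x)
  sweep(sweep(x[, names(fit$center), drop = FALSE], 2, fit$center), 2,
        fit$scale, "/")
}

#' ICC(2,1) robustness filter
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation between two aligned measurements of every
#' feature (test-retest or two raters; here typically a mask-perturbed
#' re-extraction). Features with ICC below the threshold are dropped.
#' Not applicable to habitat features (whose labels are not anchored
#' across re-segmentations); exclude those from the call.
#'
#' @param table_a,table_b aligned numeric matrices (lesions x features,
#'   same columns, >= 3 lesions).
#' @param threshold minimum ICC to keep a feature (default 0.85).
#' @return Character vector of kept feature names; per-feature ICC
#'   attached as `attr(, "icc")`.
#' @export
icc_filter <- function(table_a, table_b, threshold = 0.85) {
  a <- as.matrix(table_a)
  b <- as.matrix(table_b)
  if (!identical(colnames(a), colnames(b))) stop("feature columns differ")
  n <- nrow(a)
  if (n < 3) stop("ICC needs at least 3 lesions")
  k <- 2
  rowm <- (a + b) / 2
  grand <- (colMeans(a) + colMeans(b)) / 2
  msr <- k * colSums(sweep(rowm, 2, grand)^2) / (n - 1)
  msc <- n * (sweep(rbind(colMeans(a), colMeans(b)), 2, grand)^2 |>
                colSums()) / (k - 1)
  sst <- colSums(sweep(a, 2, grand)^2) + colSums(sweep(b, 2, grand)^2)
  sse <- sst - msr * (n - 1) - msc * (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  mse[mse < 0] <- 0
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc[colSums(abs(a - b)) == 0] <- 1  # identical measurements
  icc[!is.finite(icc)] <- 0
  kept <- colnames(a)[icc >= threshold]
  structure(kept, icc = stats::setNames(icc, colnames(a)))
}

#' Welch t-test filter
#'
#' Per-feature two-sample Welch t-test between the outcome classes;
#' keeps features with `p < alpha`. Features with zero variance in both
#' groups are dropped with a warning.
#'
#' @param table numeric matrix (lesions x features), typically z-scored.
#' @param labels binary outcome (logical, 0/1, or two-level factor).
#' @param alpha significance level (default 0.05).
#' @return Kept feature names, p-values attached as `attr(, "p")`.
#' @export
ttest_filter <- function(table, labels, alpha = 0.05) {
  x <- as.matrix(table)
  y <- as_binary(labels)
  if (sum(y) < 2 || sum(!y) < 2) stop("both classes need >= 2 lesions")
  g1 <- x[y == 1, , drop = FALSE]
  g0 <- x[y == 0, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- apply(g1, 2, var); v0 <- apply(g0, 2, var)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tt), df)
  dead <- v1 < 1e-24 & v0 < 1e-24
  if (any(dead)) {
    warning(sum(dead), " zero-variance feature(s) dropped")
    p[dead] <- NA_real_
  }
  kept <- colnames(x)[!is.na(p) & p < alpha]
  structure(kept, p = stats::setNames(p, colnames(x)))
}

#' Greedy correlation pruning
#'
#' Repeatedly deletes the feature with the greatest number of partners
#' exceeding the correlation threshold (ties: larger mean absolute
#' correlation, then lexicographically first name) until no pair
#' exceeds the threshold.
#'
#' @param table numeric matrix (lesions x features).
#' @param threshold absolute Pearson correlation above which a pair is
#'   redundant (default 0.9).
#' @return Kept feature names (original column order).
#' @export
corr_prune <- function(table, threshold = 0.9) {
  x <- as.matrix(table)
  p <- ncol(x)
  if (p < 2) return(colnames(x))
  C <- abs(suppressWarnings(cor(x)))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  alive <- rep(TRUE, p)
  nms <- colnames(x)
  repeat {
    sub <- C[alive, alive, drop = FALSE]
    cnt <- rowSums(sub > threshold)
    if (!length(cnt) || max(cnt) == 0) break
    cand <- which(cnt == max(cnt))
    if (length(cand) > 1) {
      mr <- rowMeans(sub)[cand]
      cand <- cand[mr == max(mr)]
      if (length(cand) > 1) {
        cand <- cand[order(rownames(sub)[cand])][1]
      }
    }
    drop_name <- rownames(sub)[cand[1]]
    alive[match(drop_name, nms)] <- FALSE
  }
  nms[alive]
}

# equal-frequency discretization into `bins` levels
discretize_ef <- function(x, bins = 4) {
  ceiling(bins * rank(x, ties.method = "first") / length(x))
}

# mutual information (nats) between two discrete vectors
mi_discrete <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  ratio <- sweep(sweep(p, 1, pa, "/"), 2, pb, "/")
  sum(p[p > 0] * log(ratio[p > 0]))
}

#' mRMR feature ranking (MID criterion)
#'
#' Greedy minimum-redundancy maximum-relevance selection: relevance is
#' the mutual information between the (equal-frequency, 4-bin
#' discretized) feature and the binary label; redundancy is the mean
#' pairwise mutual information with the already-selected set; each step
#' adds the feature maximizing relevance minus redundancy.
#'
#' @param table numeric matrix (lesions x features).
#' @param labels binary outcome.
#' @param m number of features to return (default 8; truncated to the
#'   number of candidates).
#' @param bins discretization bins (default 4).
#' @return Feature names in selection order, length `min(m, ncol)`.
#' @export
mrmr_select <- function(table, labels, m = 8, bins = 4) {
  if (m < 1) stop("m must be >= 1")
  x <- as.matrix(table)
  y <- as_binary(labels)
  p <- ncol(x)
  disc <- apply(x, 2, discretize_ef, bins = bins)
  rel <- apply(disc, 2, mi_discrete, b = y)
  m <- min(m, p)
  sel <- integer(0)
  red_sum <- numeric(p)
  for (step in seq_len(m)) {
    score <- rel - if (length(sel)) red_sum / length(sel) else 0
    score[sel] <- -Inf
    nxt <- which.max(score)
    sel <- c(sel, nxt)
    if (step < m) {
      red_sum <- red_sum + apply(disc, 2, mi_discrete, b = disc[, nxt])
    }
  }
  colnames(x)[sel]
}

#' LASSO feature selection with cross-validated lambda
#'
#' L1-penalized linear model on the 0/1 outcome (squared loss); the
#' penalty is chosen to minimize 10-fold cross-validated mean squared
#' error over a log-spaced grid, and features with nonzero coefficients
#' at the optimum are returned. Folds are stratified by class.
#'
#' @param table numeric matrix (lesions x features), typically z-scored.
#' @param labels binary outcome.
#' @param folds number of CV folds (default 10; must be < n).
#' @param lambda_grid optional decreasing lambda sequence; by default
#'   100 log-spaced values from the smallest all-zero lambda down by
#'   1e-4.
#' @param seed integer seed for fold assignment.
#' @return list with `features`, `coefficients` (named, nonzero),
#'   `lambda` (selected) and `cvm` (CV-MSE curve).
#' @export
lasso_select <- function(table, labels, folds = 10, lambda_grid = NULL,
                         seed = 1) {
  x <- as.matrix(table)
  y <- as.numeric(as_binary(labels))
  n <- nrow(x)
  if (n <= folds) stop("need more lesions than folds")
  if (!is.null(lambda_grid) && !length(lambda_grid)) {
    stop("empty lambda grid")
  }
  if (is.null(lambda_grid)) {
    lmax <- max(abs(crossprod(x, y - mean(y)))) / n
    lmax <- max(lmax, 1e-6)
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))
  }
  foldid <- stratified_folds(as_binary(labels), folds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "gaussian",
                          lambda = lambda_grid, foldid = foldid,
                          type.measure = "mse", standardize = FALSE)
  co <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  nz <- co[co != 0]
  list(features = names(nz), coefficients = nz,
       lambda = cv$lambda.min, cvm = cv$cvm)
}

# labels -> logical vector (TRUE = positive / non-CR class)
as_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("labels must be binary")
  if (all(c("CR", "nonCR") %in% lv)) return(as.character(labels) == "nonCR")
  as.character(labels) == lv[2]
}

# stratified fold ids, re-stratified so every fold sees both classes
# whenever class sizes permit
stratified_folds <- function(y, k, seed = 1) {
  y <- as_binary(y)
  n <- length(y)
  foldid <- integer(n)
  with_seed(seed, {
    for (cl in c(TRUE, FALSE)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  foldid
}
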