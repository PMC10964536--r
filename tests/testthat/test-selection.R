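test_that("ICC(2,1) matches the closed form on a 4-subject example", {
  # classic two-rater table
  a <- c(9, 6, 8, 7)
  b <- c(2, 1, 4, 1)
  x <- cbind(rater = c(a, b))
  n <- 4; k <- 2
  rowm <- (a + b) / 2; grand <- mean(c(a, b))
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((c(mean(a), mean(b)) - grand)^2) / (k - 1)
  sse <- sum((a - grand)^2) + sum((b - grand)^2) -
    msr * (n - 1) - msc * (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc_hand <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  kept <- icc_filter(matrix(a, dimnames = list(NULL, "f")),
                     matrix(b, dimnames = list(NULL, "f")),
                     threshold = -1)
  expect_equal(unname(attr(kept, "icc")["f"]), icc_hand)
  # independent oracle: two-way ANOVA mean squares via aov()
  dat <- data.frame(y = c(a, b), subj = factor(rep(1:4, 2)),
                    rater = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + rater, data = dat))[[1]]$`Mean Sq`
  icc_aov <- (ms[1] - ms[3]) /
    (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
  expect_equal(unname(attr(kept, "icc")["f"]), icc_aov)
})

test_that("ICC filter keeps identical and drops independent features", {
  set.seed(14)
  x <- matrix(rnorm(200), 40, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  kept <- icc_filter(x, x, 0.85)
  expect_equal(length(kept), 5)
  expect_true(all(attr(kept, "icc") == 1))
  y <- matrix(rnorm(200), 40, 5, dimnames = dimnames(x))
  kept2 <- icc_filter(x, y, 0.85)
  expect_equal(length(kept2), 0)
  expect_error(icc_filter(x[1:2, ], x[1:2, ]), "3")
})

test_that("Welch statistic matches the formula on a 3v3 instance", {
  g1 <- c(1.1, 2.3, 1.9); g0 <- c(3.2, 4.0, 3.1)
  x <- matrix(c(g1, g0), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(1, 1, 1, 0, 0, 0)
  kept <- ttest_filter(x, y, alpha = 1)
  tt <- t.test(g1, g0)  # Welch by default
  expect_equal(unname(attr(kept, "p")["f"]), tt$p.value)
})

test_that("t-test filter retains ~alpha of null features and all signal", {
  set.seed(15)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  x <- matrix(rnorm(n * 200), n, 200,
              dimnames = list(NULL, paste0("f", 1:200)))
  kept <- ttest_filter(x, sample(y), alpha = 0.05)
  # binomial band: 200 * 0.05 +/- 3 * sqrt(200 * .05 * .95)
  expect_lte(length(kept), 10 + 3 * sqrt(200 * 0.05 * 0.95))
  sig <- matrix(y + rnorm(n, 0, 0.05), ncol = 1,
                dimnames = list(NULL, "s"))
  expect_equal(as.character(ttest_filter(sig, y, 0.05)), "s")
  dead <- cbind(x[, 1:2], const = 1)
  expect_warning(ttest_filter(dead, y, 0.05), "zero-variance")
})

test_that("correlation pruning removes duplicates and respects the bound", {
  set.seed(16)
  base <- rnorm(50)
  x <- cbind(a = base, b = base, c = rnorm(50), d = rnorm(50))
  kept <- corr_prune(x, 0.9)
  expect_equal(length(intersect(c("a", "b"), kept)), 1)
  expect_true(all(c("c", "d") %in% kept))
  # orthogonal features all kept
  o <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  expect_equal(length(corr_prune(o, 0.9)), 4)
  # postcondition on a correlated 5-feature instance
  z <- rnorm(60)
  xx <- cbind(f1 = z, f2 = z + rnorm(60, 0, 0.05),
              f3 = z + rnorm(60, 0, 0.05), f4 = rnorm(60),
              f5 = -z + rnorm(60, 0, 0.05))
  kk <- corr_prune(xx, 0.9)
  C <- abs(cor(xx[, kk, drop = FALSE])); diag(C) <- 0
  expect_lt(max(C), 0.9)
  # brute-force feasibility: some deletion order achieves a valid set;
  # greedy must too (already asserted by the postcondition above)
})

test_that("mRMR returns the requested count with relevance first", {
  set.seed(17)
  n <- 150
  y <- rep(c(1, 0), each = n / 2)
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  expect_equal(length(mrmr_select(x, y, m = 8)), 8)
  expect_error(mrmr_select(x, y, m = 0), "m must be")
  # one informative feature ranks first
  x[, 7] <- y + rnorm(n, 0, 0.3)
  colnames(x) <- paste0("f", 1:20)
  expect_equal(mrmr_select(x, y, m = 3)[1], "f7")
})

test_that("mRMR penalizes a duplicated informative feature (MID)", {
  set.seed(18)
  n <- 400
  y <- rep(c(1, 0), each = n / 2)
  strong <- y + rnorm(n, 0, 0.4)
  weak <- y + rnorm(n, 0, 1.2)
  x <- cbind(s1 = strong, s2 = strong, w = weak)
  sel <- mrmr_select(x, y, m = 3)
  expect_equal(sel[1], "s1")
  expect_equal(sel[2], "w")  # s2 is fully redundant with s1
})

test_that("LASSO shrinks fully at huge lambda and matches OLS at 0", {
  set.seed(19)
  n <- 50
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(x[, 1] * 0.8 + rnorm(n, 0, 0.3) > 0)
  big <- lasso_select(x, y, folds = 5, lambda_grid = c(1e4, 9e3), seed = 1)
  expect_equal(length(big$features), 0)
  # lambda -> 0: coefficients approach the least-squares oracle
  small <- lasso_select(x, y, folds = 5,
                        lambda_grid = c(1e-8, 5e-9), seed = 1)
  ols <- coef(lm(y ~ x))[-1]
  expect_equal(unname(small$coefficients[c("a", "b", "c")]),
               unname(ols), tolerance = 1e-4)
})

test_that("z-score parameters fit on training rows only", {
  set.seed(21)
  tr <- matrix(rnorm(60, 5, 2), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  te <- matrix(rnorm(30, 50, 9), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- zscore_fit(tr)
  ztr <- zscore_apply(tr, fit)
  zte <- zscore_apply(te, fit)
  expect_equal(unname(colMeans(ztr)), c(0, 0, 0), tolerance = 1e-12)
  # test rows transformed with training parameters, not their own
  expect_equal(zte, (te - rep(fit$center, each = 10)) /
                 rep(fit$scale, each = 10), ignore_attr = TRUE)
  # recomputation check: refitting on test would differ
  expect_gt(max(abs(colMeans(zte))), 1)
})
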