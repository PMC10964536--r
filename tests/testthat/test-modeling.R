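test_that("univariate OR matches the 2x2 cross-product", {
  # table (20,10 / 10,20): OR = (20*20)/(10*10) = 4
  x <- data.frame(flag = c(rep(1, 30), rep(0, 30)))
  y <- c(rep(TRUE, 20), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 20))
  res <- univariate_screen(x, y)
  expect_equal(res$or[res$variable == "flag"], 4, tolerance = 1e-6)
  expect_lt(res$p[1], 0.05)
})

test_that("null covariates calibrate and degenerate ones are flagged", {
  set.seed(25)
  n <- 2000
  x <- data.frame(noise = rnorm(n), const = 1)
  y <- runif(n) < 0.3
  expect_warning(res <- univariate_screen(x, y), "constant")
  noise_row <- res[res$variable == "noise", ]
  expect_true(noise_row$ci_lo < 1 && noise_row$ci_hi > 1)
  expect_equal(res$status[res$variable == "const"], "constant")
  # complete separation flagged
  sep <- data.frame(perfect = as.numeric(y))
  expect_warning(r2 <- univariate_screen(sep, y), "separation")
  expect_equal(r2$status[1], "separated")
})

test_that("multivariate screening keeps joint signal, drops planted nulls", {
  set.seed(26)
  drops <- 0
  keeps <- 0
  for (s in 1:20) {
    n <- 1000
    x <- data.frame(a = rnorm(n), b = rnorm(n), null = rnorm(n))
    lp <- 0.9 * x$a - 0.9 * x$b
    y <- runif(n) < plogis(lp)
    res <- multivariate_screen(x, y, c("a", "b", "null"))
    ret <- attr(res, "retained")
    if (!"null" %in% ret) drops <- drops + 1
    if (all(c("a", "b") %in% ret)) keeps <- keeps + 1
  }
  expect_gte(drops, 18)  # >= 90% of seeds
  expect_gte(keeps, 18)
})

test_that("single-candidate multivariate equals the univariate fit", {
  set.seed(27)
  x <- data.frame(v = rnorm(200))
  y <- runif(200) < plogis(x$v)
  uni <- univariate_screen(x, y)
  multi <- multivariate_screen(x, y, "v")
  expect_equal(multi$or, uni$or, tolerance = 1e-8)
  expect_equal(multi$p, uni$p, tolerance = 1e-6)
})

test_that("collinear candidates fall back to a ridge-stabilized fit", {
  set.seed(28)
  x <- data.frame(a = rnorm(100))
  x$b <- x$a  # exact copy
  y <- runif(100) < plogis(x$a)
  expect_warning(res <- multivariate_screen(x, y, c("a", "b")),
                 "ridge")
  expect_true(all(is.finite(res$or)))
})

test_that("clinical encoding is the documented integer map", {
  rec <- data.frame(sex = c("M", "F"), lobe = c("RUL", "LLL"),
                    electrode = c("expandable", "straight"),
                    primary_site = c("rectum", "caecum"),
                    iah = c(TRUE, FALSE), age = c(60, 50))
  enc <- encode_clinical(rec)
  expect_equal(enc$sex, c(0, 1))
  expect_equal(enc$lobe, c(1, 5))
  expect_equal(enc$electrode, c(1, 0))
  expect_equal(enc$primary_site, c(1, 4))
  expect_equal(enc$iah, c(1, 0))
  expect_equal(enc$age, c(60, 50))
})

test_that("signature models fit, store thresholds and predict in [0,1]", {
  set.seed(29)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- runif(n) < plogis(2 * x[, 1])
  for (fam in c("lr", "rf", "extratrees", "xgboost", "knn", "svm", "mlp")) {
    mod <- fit_signature(x, y, family = fam, seed = 1, name = fam)
    p <- predict(mod, x)
    expect_true(all(p >= 0 & p <= 1), info = fam)
    expect_true(is.finite(mod$threshold), info = fam)
    # training rows reproduce stored training probabilities
    expect_equal(p, mod$train_probs, tolerance = 1e-8, info = fam)
  }
  expect_error(predict(fit_signature(x, y, "lr", seed = 1),
                       x[, 1:2, drop = FALSE]), "f3")
})

test_that("separable data reach training AUC 1 and grids behave", {
  set.seed(30)
  x <- matrix(c(rnorm(40, 0), rnorm(40, 8)), ncol = 2)
  colnames(x) <- c("u", "v")
  y <- rep(c(FALSE, TRUE), 20)
  x[y, ] <- x[y, ] + 10
  mod <- fit_signature(x, y, "lr", seed = 3)
  expect_equal(roc_auc(mod$train_probs, y)$auc, 1)
  # grid of size 1 equals a direct fit with those hyperparameters
  g1 <- data.frame(k = 5)
  m1 <- fit_signature(x, y, "knn", grid = g1, seed = 4)
  expect_equal(m1$hyper$k, 5)
})

test_that("null labels give chance-level CV AUC", {
  set.seed(31)
  aucs <- replicate(20, {
    n <- 60
    x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- sample(rep(c(TRUE, FALSE), n / 2))
    fit_signature(x, y, "lr", seed = sample.int(1e6, 1))$cv_auc
  })
  se <- sd(aucs) / sqrt(20)
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("one-feature logistic response is monotone in the feature", {
  set.seed(32)
  x <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "f"))
  y <- runif(100) < plogis(3 * x[, 1])
  mod <- fit_signature(x, y, "lr", seed = 5)
  grid <- matrix(seq(-2, 2, length.out = 20), ncol = 1,
                 dimnames = list(NULL, "f"))
  p <- predict(mod, grid)
  expect_true(all(diff(p) > 0))
})

test_that("test labels cannot influence the fitted pipeline", {
  # leakage audit: corrupt test labels, assert identical models/scores
  cfg <- run_config(n_lesions = 20, noncr_prevalence = 0.4, seed = 77,
                    icc_n = 0, k_fixed = 2, ratio_train = 0.75,
                    signatures = "Intra", families = c(Intra = "lr"))
  cohort <- generate_cohort(cohort_config(
    n_lesions = cfg$n_lesions, noncr_prevalence = 0.4, seed = 42))
  sp <- split_cohort(cohort, cfg$ratio_train, seed = 2)
  res1 <- suppressWarnings(run_all(cfg, cohort = sp))
  sp2 <- sp
  for (i in seq_along(sp2$test)) {
    sp2$test[[i]]$label <- ifelse(sp2$test[[i]]$label == "CR",
                                  "nonCR", "CR")
  }
  res2 <- suppressWarnings(run_all(cfg, cohort = sp2))
  expect_identical(res1$selected, res2$selected)
  expect_equal(res1$report_test$signatures$Intra$auc,
               1 - res2$report_test$signatures$Intra$auc,
               tolerance = 1e-12)
  expect_equal(coef(res1$models$Intra$fit), coef(res2$models$Intra$fit))
})
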