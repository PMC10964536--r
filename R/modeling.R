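# Modeling module: logistic screening for the clinical signature, and
# cross-validated grid search over classifier families for the
# radiomics signatures, with training-set Youden thresholds.

#' Encode clinical covariates as documented numerics
#'
#' Mapping: flags -> 0/1; `sex` M=0, F=1; `primary_site` rectum=1,
#' sigmoid_left=2, transverse_right=3, caecum=4; `lobe` RUL=1, RML=2,
#' RLL=3, LUL=4, LLL=5 (upper-to-lower, right-to-left); `electrode`
#' expandable=1, straight=0. Continuous covariates pass through.
#'
#' @param records data.frame of clinical records ([clinical_table()]
#'   without the id/label columns is accepted).
#' @return A numeric data.frame.
#' @export
encode_clinical <- function(records) {
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  rec <- rec[setdiff(names(rec), c("lesion_id", "patient_id", "label"))]
  enc <- function(x, levels) as.numeric(match(x, levels))
  out <- rec
  if ("sex" %in% names(out)) out$sex <- enc(out$sex, c("M", "F")) - 1
  if ("primary_site" %in% names(out)) {
    out$primary_site <- enc(out$primary_site,
                            c("rectum", "sigmoid_left", "transverse_right",
                              "caecum"))
  }
  if ("lobe" %in% names(out)) {
    out$lobe <- enc(out$lobe, c("RUL", "RML", "RLL", "LUL", "LLL"))
  }
  if ("electrode" %in% names(out)) {
    out$electrode <- as.numeric(out$electrode == "expandable")
  }
  for (nm in names(out)) {
    if (is.logical(out[[nm]])) out[[nm]] <- as.numeric(out[[nm]])
  }
  out
}

#' Univariate logistic screening of clinical covariates
#'
#' One-variable logistic regression of the outcome on each covariate;
#' reports the Wald odds ratio, 95% CI and p-value. Constant covariates
#' and covariates with complete separation are flagged and excluded.
#'
#' @param records clinical covariates (data.frame; encoded via
#'   [encode_clinical()] if non-numeric columns are present).
#' @param labels binary outcome.
#' @return A `screening_result`: data.frame with columns `variable`,
#'   `or`, `ci_lo`, `ci_hi`, `p`, `status`.
#' @export
univariate_screen <- function(records, labels) {
  x <- encode_clinical(records)
  y <- as_binary(labels)
  rows <- lapply(names(x), function(nm) {
    v <- x[[nm]]
    if (length(unique(v)) < 2) {
      warning("constant covariate excluded: ", nm)
      return(data.frame(variable = nm, or = NA, ci_lo = NA, ci_hi = NA,
                        p = NA, status = "constant"))
    }
    fit <- suppressWarnings(glm(y ~ v, family = binomial()))
    co <- summary(fit)$coefficients
    beta <- co["v", "Estimate"]; se <- co["v", "Std. Error"]
    if (!is.finite(se) || se > 50 || abs(beta) > 25) {
      warning("complete separation, covariate excluded: ", nm)
      return(data.frame(variable = nm, or = NA, ci_lo = NA, ci_hi = NA,
                        p = NA, status = "separated"))
    }
    data.frame(variable = nm, or = exp(beta),
               ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
               p = co["v", "Pr(>|z|)"], status = "ok")
  })
  res <- do.call(rbind, rows)
  class(res) <- c("screening_result", class(res))
  res
}

# Ridge-stabilized logistic IRLS used when the joint design is
# rank-deficient; Wald statistics from the penalized information matrix.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 50) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)))
  for (i in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    H <- crossprod(X1, X1 * w) + pen
    g <- crossprod(X1, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(H)))
  list(beta = beta, se = se)
}

#' Multivariate logistic screening
#'
#' Joint logistic fit over the candidates passing the univariate gate;
#' variables with multivariate Wald `p < 0.05` form the clinical
#' signature's inputs. Collinear candidate sets fall back to a
#' ridge-stabilized fit with a warning.
#'
#' @param records clinical covariates.
#' @param labels binary outcome.
#' @param candidates character vector of covariate names (from the
#'   univariate gate).
#' @param alpha retention threshold (default 0.05).
#' @return A `screening_result` data.frame with a `retained` attribute.
#' @export
multivariate_screen <- function(records, labels, candidates, alpha = 0.05) {
  x <- encode_clinical(records)[, candidates, drop = FALSE]
  y <- as_binary(labels)
  X <- as.matrix(x)
  qrX <- qr(cbind(1, scale(X)))
  if (qrX$rank < ncol(X) + 1) {
    warning("collinear candidates: using ridge-stabilized fit")
    rf <- ridge_logistic(scale(X), as.numeric(y))
    beta <- rf$beta[-1]; se <- rf$se[-1]
    sds <- apply(X, 2, sd)
    beta <- beta / sds; se <- se / sds  # back to original units
  } else {
    fit <- suppressWarnings(glm(y ~ ., data = data.frame(x),
                                family = binomial()))
    co <- summary(fit)$coefficients
    beta <- co[-1, "Estimate"]; se <- co[-1, "Std. Error"]
  }
  p <- 2 * pnorm(-abs(beta / se))
  res <- data.frame(variable = candidates, or = exp(beta),
                    ci_lo = exp(beta - 1.96 * se),
                    ci_hi = exp(beta + 1.96 * se), p = p, status = "ok")
  attr(res, "retained") <- candidates[p < alpha]
  class(res) <- c("screening_result", class(res))
  res
}

# --- classifier families -------------------------------------------------

default_grid <- function(family) {
  switch(family,
         lr = data.frame(dummy = 1),
         svm = expand.grid(cost = c(0.5, 2, 8), gamma_scale = c(0.5, 1, 2)),
         knn = data.frame(k = c(3, 5, 9)),
         rf = expand.grid(ntree = 300, mtry_frac = c(0.33, 0.6, 1)),
         extratrees = expand.grid(num.trees = 300,
                                  mtry_frac = c(0.33, 0.6, 1)),
         xgboost = expand.grid(nrounds = c(40, 80), max_depth = c(2, 3),
                               eta = 0.3),
         mlp = expand.grid(size = c(2, 4), decay = c(0.01, 0.1)),
         stop("unknown classifier family: ", family))
}

fit_family <- function(x, y, family, hp, seed = 1) {
  x <- as.matrix(x)
  yf <- factor(as.integer(y), levels = c(0, 1))
  with_seed(seed, switch(
    family,
    lr = {
      dat <- data.frame(y = as.numeric(y), x)
      suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
    },
    svm = {
      gam <- hp$gamma_scale / ncol(x)
      e1071::svm(x, yf, kernel = "radial", cost = hp$cost, gamma = gam,
                 probability = TRUE)
    },
    knn = list(train = x, cl = yf, k = hp$k),
    rf = {
      mtry <- max(1, round(hp$mtry_frac * ncol(x)))
      randomForest::randomForest(x, yf, ntree = hp$ntree, mtry = mtry)
    },
    extratrees = {
      mtry <- max(1, round(hp$mtry_frac * ncol(x)))
      ranger::ranger(y = yf, x = as.data.frame(x),
                     num.trees = hp$num.trees, mtry = mtry,
                     splitrule = "extratrees", probability = TRUE,
                     num.threads = 1, seed = seed)
    },
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = hp$max_depth, eta = hp$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1),
      nrounds = hp$nrounds, verbose = 0),
    mlp = nnet::nnet(x, as.numeric(y), size = hp$size, decay = hp$decay,
                     maxit = 300, entropy = TRUE, trace = FALSE)))
}

predict_family <- function(fit, x, family) {
  x <- as.matrix(x)
  p <- switch(
    family,
    lr = unname(predict(fit, newdata = data.frame(x), type = "response")),
    svm = {
      pr <- predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    knn = {
      pr <- class::knn(fit$train, x, fit$cl, k = fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    rf = predict(fit, x, type = "prob")[, "1"],
    extratrees = predict(fit, as.data.frame(x))$predictions[, "1"],
    xgboost = predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    mlp = drop(predict(fit, x)))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Fit a signature model with cross-validated grid search
#'
#' Stratified 5-fold cross-validation over the hyperparameter grid,
#' maximizing the mean validation AUC, then a refit on the full
#' training table. The training-set Youden threshold is stored with the
#' model and must be reused unchanged on test data.
#'
#' @param table numeric feature matrix (training lesions x features).
#' @param labels binary outcome.
#' @param family classifier family: `"lr"`, `"svm"`, `"knn"`, `"rf"`,
#'   `"extratrees"`, `"xgboost"` or `"mlp"`.
#' @param grid data.frame of hyperparameter combinations (default:
#'   a small per-family grid).
#' @param folds CV folds (default 5).
#' @param seed integer seed for folds and stochastic learners.
#' @param name signature name carried in the result.
#' @return A `signature_model` with fields `family`, `hyper`,
#'   `features`, `threshold` (training Youden cutoff), `cv_auc` and
#'   `train_probs`.
#' @export
fit_signature <- function(table, labels, family = "lr", grid = NULL,
                          folds = 5, seed = 1, name = family) {
  x <- as.matrix(table)
  y <- as_binary(labels)
  if (min(sum(y), sum(!y)) < 2) stop("both classes needed for fitting")
  if (is.null(grid)) grid <- default_grid(family)
  k <- min(folds, sum(y), sum(!y))
  foldid <- stratified_folds(y, k, seed)
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- grid[g, , drop = FALSE]
    aucs <- vapply(seq_len(k), function(f) {
      tr <- foldid != f
      fit <- fit_family(x[tr, , drop = FALSE], y[tr], family, hp,
                        seed = seed + f)
      pr <- predict_family(fit, x[!tr, , drop = FALSE], family)
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      roc_auc(pr, y[!tr])$auc
    }, numeric(1))
    cv_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv_auc)
  hp <- grid[best, , drop = FALSE]
  fit <- fit_family(x, y, family, hp, seed = seed)
  probs <- predict_family(fit, x, family)
  yt <- youden_threshold(probs, y)
  structure(list(name = name, family = family, hyper = hp, fit = fit,
                 features = colnames(x), threshold = yt$threshold,
                 cv_auc = cv_auc[best], train_probs = probs),
            class = "signature_model")
}

#' Predict response probabilities from a signature model
#'
#' @param object a `signature_model`.
#' @param table feature matrix containing the model's feature columns.
#' @param ... unused.
#' @return Probabilities in `[0, 1]`, deterministic given the fitted
#'   model.
#' @export
predict.signature_model <- function(object, table, ...) {
  x <- as.matrix(table)
  missing <- setdiff(object$features, colnames(x))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  }
  predict_family(object$fit, x[, object$features, drop = FALSE],
                 object$family)
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %s (%s), %d features, CV AUC %.3f\n",
              x$name, x$family, length(x$features), x$cv_auc))
  invisible(x)
}
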