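# Evaluation module: ROC/AUC with DeLong inference, the paired DeLong
# test, Youden cutoff metrics, Hosmer-Lemeshow calibration and decision
# curves — implemented from their defining formulas.

# DeLong structural components: V10 (per positive) and V01 (per
# negative) placement values; ties count one half.
delong_components <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = sum(r_all[seq_len(m)]) / (m * n) -
         (m + 1) / (2 * n))
}

# variance that is 0 (not NA) for singleton samples
var0 <- function(x) if (length(x) < 2) 0 else var(x)

#' AUC with a DeLong confidence interval
#'
#' Computes the area under the ROC curve as the Mann-Whitney statistic
#' (ties count one half) and a 95% confidence interval from the DeLong
#' structural-components variance, clipped to `[0, 1]`.
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary outcome; both classes must be present.
#' @return list with `auc`, `ci` (length 2), and `se`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  if (!any(y) || all(y)) stop("both classes must be present")
  dc <- delong_components(scores, y)
  v <- var0(dc$v10) / length(dc$v10) + var0(dc$v01) / length(dc$v01)
  se <- sqrt(max(v, 0))
  ci <- pmin(pmax(dc$auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  list(auc = dc$auc, ci = ci, se = se)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Structural-components implementation of the paired DeLong test for
#' two models scored on identical lesions; two-sided p-value. A zero
#' variance of the AUC difference yields `z = 0, p = 1` by convention.
#'
#' @param scores_a,scores_b paired prediction vectors.
#' @param labels binary outcome.
#' @return list with `z`, `p`, `auc_a`, `auc_b`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary(labels)
  if (length(scores_a) != length(scores_b)) stop("scores must be paired")
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  d10 <- ca$v10 - cb$v10
  d01 <- ca$v01 - cb$v01
  v <- var0(d10) / length(d10) + var0(d01) / length(d01)
  if (v <= 1e-16) {
    return(list(z = 0, p = 1, auc_a = ca$auc, auc_b = cb$auc))
  }
  z <- (ca$auc - cb$auc) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)), auc_a = ca$auc, auc_b = cb$auc)
}

#' Youden-optimal threshold and confusion metrics
#'
#' Scans all midpoints between sorted unique scores (classification
#' rule: positive if `score >= threshold`) and returns the threshold
#' maximizing Youden's `J = sensitivity + specificity - 1` (ties: lower
#' threshold), with accuracy, sensitivity, specificity, PPV and NPV at
#' that cutoff.
#'
#' @param scores numeric predictions.
#' @param labels binary outcome; both classes present.
#' @return list with `threshold`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `youden`.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as_binary(labels)
  if (!any(y) || all(y)) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) u else (u[-length(u)] + u[-1]) / 2
  cand <- c(min(u) - 1, cand)  # all-positive rule included
  m <- sum(y); nn <- sum(!y)
  stats_at <- vapply(cand, function(th) {
    pred <- scores >= th
    tp <- sum(pred & y); fp <- sum(pred & !y)
    sens <- tp / m; spec <- (nn - fp) / nn
    c(sens + spec - 1, sens, spec, tp, fp)
  }, numeric(5))
  best <- which.max(stats_at[1, ])  # first max = lowest threshold
  th <- cand[best]
  sens <- stats_at[2, best]; spec <- stats_at[3, best]
  tp <- stats_at[4, best]; fp <- stats_at[5, best]
  fn <- m - tp; tn <- nn - fp
  list(threshold = th,
       accuracy = (tp + tn) / (m + nn),
       sensitivity = sens, specificity = spec,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       youden = sens + spec - 1)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping of predicted probabilities (equal-count
#' quantile groups, ties kept together); statistic
#' `sum (O - E)^2 / (E (1 - E / n_g))` with a chi-square reference on
#' `groups - 2` degrees of freedom. Groups with degenerate expected
#' counts are merged with a neighbour (with a warning, df adjusted).
#'
#' @param probs predicted probabilities.
#' @param labels binary outcome.
#' @param groups target number of groups (default 10; requires
#'   `n >= 2 * groups`).
#' @return list with `statistic`, `p`, `df` and the per-group `table`.
#' @export
hosmer_lemeshow <- function(probs, labels, groups = 10) {
  y <- as.numeric(as_binary(labels))
  n <- length(y)
  if (n < 2 * groups) stop("need n >= 2 * groups")
  br <- unique(quantile(probs, seq(0, 1, length.out = groups + 1)))
  if (length(br) < 3) br <- c(-Inf, mean(probs), Inf)
  g <- cut(probs, breaks = br, include.lowest = TRUE, labels = FALSE)
  ng <- tapply(y, g, length)
  O <- tapply(y, g, sum)
  E <- tapply(probs, g, sum)
  # merge degenerate groups (expected 0 or n_g) into the neighbour
  merged <- FALSE
  repeat {
    bad <- which(E < 1e-9 | (ng - E) < 1e-9)
    if (!length(bad) || length(E) <= 2) break
    i <- bad[1]
    j <- if (i == 1) 2 else i - 1
    E[j] <- E[j] + E[i]; O[j] <- O[j] + O[i]; ng[j] <- ng[j] + ng[i]
    E <- E[-i]; O <- O[-i]; ng <- ng[-i]
    merged <- TRUE
  }
  if (merged) warning("degenerate risk group(s) merged; df adjusted")
  stat <- sum((O - E)^2 / (E * (1 - E / ng)))
  df <- max(length(E) - 2, 1)
  list(statistic = stat, p = pchisq(stat, df, lower.tail = FALSE),
       df = df,
       table = data.frame(n = as.numeric(ng), observed = as.numeric(O),
                          expected = as.numeric(E)))
}

#' Decision-curve analysis
#'
#' Net benefit `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)` of treating at
#' each threshold probability, plus treat-all and treat-none reference
#' curves.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcome.
#' @param thresholds threshold probabilities, all inside (0, 1)
#'   (default 0.01 to 0.99 by 0.01).
#' @return data.frame with columns `threshold`, `net_benefit`,
#'   `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  y <- as_binary(labels)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    pred <- probs >= pt
    tp <- sum(pred & y); fp <- sum(pred & !y)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = ta, treat_none = 0)
}

#' Evaluate one signature's scores on one cohort
#'
#' Bundles AUC + DeLong CI, confusion metrics at a fixed (training)
#' threshold or at the cohort's own Youden cutoff, the Hosmer-Lemeshow
#' test and the decision curve.
#'
#' @param scores predicted probabilities.
#' @param labels binary outcome.
#' @param threshold optional fixed decision threshold (training Youden
#'   cutoff); if `NULL` the cohort's own Youden cutoff is used.
#' @param hl_groups Hosmer-Lemeshow groups (skipped with `NA` results
#'   if the cohort is too small).
#' @param dca_thresholds decision-curve grid.
#' @return list of metric components.
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL,
                            hl_groups = 10,
                            dca_thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- as_binary(labels)
  ra <- roc_auc(scores, y)
  if (is.null(threshold)) {
    yt <- youden_threshold(scores, y)
  } else {
    m <- sum(y); nn <- sum(!y)
    pred <- scores >= threshold
    tp <- sum(pred & y); fp <- sum(pred & !y)
    fn <- m - tp; tn <- nn - fp
    yt <- list(threshold = threshold, accuracy = (tp + tn) / (m + nn),
               sensitivity = tp / m, specificity = tn / nn,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
               youden = tp / m + tn / nn - 1)
  }
  hl <- if (length(y) >= 2 * hl_groups) {
    tryCatch(suppressWarnings(hosmer_lemeshow(scores, y, hl_groups)),
             error = function(e) list(statistic = NA, p = NA, df = NA))
  } else list(statistic = NA, p = NA, df = NA)
  list(auc = ra$auc, auc_ci = ra$ci, auc_se = ra$se,
       threshold = yt$threshold, accuracy = yt$accuracy,
       sensitivity = yt$sensitivity, specificity = yt$specificity,
       ppv = yt$ppv, npv = yt$npv, youden = yt$youden,
       hl_statistic = hl$statistic, hl_p = hl$p,
       dca = decision_curve(scores, y, dca_thresholds))
}

#' Build an evaluation report across signatures
#'
#' @param score_list named list of probability vectors (one per
#'   signature), all on the same lesions.
#' @param labels binary outcome.
#' @param thresholds optional named list of fixed decision thresholds.
#' @return An `evaluation_report`: per-signature metrics plus a
#'   pairwise DeLong p-value matrix.
#' @export
evaluation_report <- function(score_list, labels, thresholds = NULL) {
  sigs <- names(score_list)
  per <- lapply(sigs, function(s) {
    evaluate_scores(score_list[[s]], labels,
                    threshold = thresholds[[s]] %||% NULL)
  })
  names(per) <- sigs
  np <- length(sigs)
  pmat <- matrix(NA_real_, np, np, dimnames = list(sigs, sigs))
  zmat <- pmat
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i == j) next
    dt <- delong_test(score_list[[i]], score_list[[j]], labels)
    pmat[i, j] <- dt$p; zmat[i, j] <- dt$z
  }
  structure(list(signatures = per, delong_p = pmat, delong_z = zmat),
            class = "evaluation_report")
}

#' Summarize an evaluation report as a table
#'
#' One row per signature with ACC, AUC, 95% CI, sensitivity,
#' specificity, PPV, NPV and Youden index.
#'
#' @param report an `evaluation_report`.
#' @return A data.frame.
#' @export
report_table <- function(report) {
  rows <- lapply(names(report$signatures), function(s) {
    m <- report$signatures[[s]]
    data.frame(signature = s, acc = m$accuracy, auc = m$auc,
               ci_lo = m$auc_ci[1], ci_hi = m$auc_ci[2],
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, youden = m$youden,
               hl_p = m$hl_p)
  })
  do.call(rbind, rows)
}

#' Serialize / restore an evaluation report
#'
#' @param report an `evaluation_report`.
#' @param path JSON file path.
#' @return `report_write()` returns `path` invisibly; `report_read()`
#'   the restored list.
#' @export
report_write <- function(report, path) {
  out <- list(signatures = lapply(report$signatures, function(m) {
    m$dca <- as.list(m$dca)
    m
  }), delong_p = report$delong_p, delong_z = report$delong_z)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname report_write
#' @export
report_read <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
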