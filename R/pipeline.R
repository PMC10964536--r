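# Pipeline module: orchestrates simulate -> preprocess -> ring ->
# habitat -> features -> select -> train -> evaluate as one seeded,
# configured run.

#' Pipeline run configuration
#'
#' Collects every tunable of the full analysis. All random stages
#' derive their seeds from `seed`. The cohort defaults here are
#' desk-scale (60 lesions); the generator's own defaults reproduce the
#' reference cohort size (515).
#'
#' @param n_lesions cohort size for the run.
#' @param noncr_prevalence non-CR fraction.
#' @param effect_sizes list with `residual` and `clinical` multipliers
#'   (see [cohort_config()]).
#' @param seed master seed.
#' @param spacing_mm working grid spacing (resample target), mm.
#' @param window HU window `c(lo, hi)` mapped to `[0, out_max]`.
#' @param out_max intensity ceiling after windowing.
#' @param rings peritumoral ring thicknesses, mm.
#' @param k_range habitat cluster-number candidates.
#' @param k_fixed optional fixed habitat count (skips CH selection).
#' @param k_vote_n lesions polled (per phase) for the cohort-level CH
#'   vote.
#' @param icc_n training lesions re-extracted with perturbed masks for
#'   the ICC filter (0 disables the ICC stage).
#' @param icc_threshold,alpha,corr_threshold,mrmr_m,lasso_folds
#'   selection-cascade tunables.
#' @param cv_folds signature-model CV folds.
#' @param ratio_train training fraction of the split.
#' @param bin_width texture discretization bin width.
#' @param signatures signatures to build, a subset of `"Clinical"`,
#'   `"Intra"`, `"Peri5"`, `"Peri10"`, `"Habitat"`, `"HabitatPeri5"`.
#' @param families named character map signature -> classifier family.
#' @param output_dir optional artifact directory.
#' @return A `run_config` list.
#' @export
run_config <- function(n_lesions = 60, noncr_prevalence = 0.2,
                       effect_sizes = list(residual = 1, clinical = 1),
                       seed = 1, spacing_mm = c(1, 1, 1),
                       window = c(-1200, 600), out_max = 255,
                       rings = c(5, 10), k_range = 2:6, k_fixed = NULL,
                       k_vote_n = 12, icc_n = 40, icc_threshold = 0.85,
                       alpha = 0.05, corr_threshold = 0.9, mrmr_m = 8,
                       lasso_folds = 10, cv_folds = 5, ratio_train = 0.8,
                       bin_width = 25,
                       signatures = c("Clinical", "Intra", "Peri5",
                                      "Peri10", "Habitat", "HabitatPeri5"),
                       families = c(Clinical = "xgboost", Intra = "rf",
                                    Peri5 = "xgboost", Peri10 = "xgboost",
                                    Habitat = "extratrees",
                                    HabitatPeri5 = "xgboost"),
                       output_dir = NULL) {
  cfg <- list(n_lesions = n_lesions, noncr_prevalence = noncr_prevalence,
              effect_sizes = effect_sizes, seed = as.integer(seed),
              spacing_mm = spacing_mm, window = window, out_max = out_max,
              rings = rings, k_range = k_range, k_fixed = k_fixed,
              k_vote_n = k_vote_n, icc_n = icc_n,
              icc_threshold = icc_threshold, alpha = alpha,
              corr_threshold = corr_threshold, mrmr_m = mrmr_m,
              lasso_folds = lasso_folds, cv_folds = cv_folds,
              ratio_train = ratio_train, bin_width = bin_width,
              signatures = signatures, families = families,
              output_dir = output_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take [run_config()] defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$families)) raw$families <- unlist(raw$families)
  do.call(run_config, raw)
}

# preprocess one case to the working grid and intensity scale
preprocess_case <- function(case, config) {
  tgt <- config$spacing_mm
  pre <- resample_isotropic(case$pre_image, tgt, "bspline")
  post <- resample_isotropic(case$post_image, tgt, "bspline")
  list(pre = window_scale(pre, config$window[1], config$window[2],
                          config$out_max),
       post = window_scale(post, config$window[1], config$window[2],
                           config$out_max),
       tumor = resample_isotropic(case$tumor_mask, tgt, "nearest"),
       ablation = resample_isotropic(case$ablation_mask, tgt, "nearest"),
       lung = resample_isotropic(case$lung_mask, tgt, "nearest"))
}

# Repeat-segmentation surrogate: jitter the mask boundary by a smooth
# zero-mean random displacement field (~0.7 mm SD, 2 mm correlation
# length), moving the contour locally in and out without the systematic
# bias an erosion or dilation would introduce.
perturb_mask <- function(mask, seed = 1) {
  sp <- mask$spacing
  d <- dim(mask$values)
  inside <- mask$values > 0
  d_in <- sqrt(array(.edt_sq(!inside, as.integer(d), sp), d))
  d_out <- sqrt(array(.edt_sq(inside, as.integer(d), sp), d))
  signed <- d_in - d_out                    # positive inside, mm
  eta <- with_seed(seed, array(rnorm(prod(d)), d))
  eta <- smooth3d(eta, 2, sp)
  eta <- eta / max(sd(eta), 1e-12) * 0.7
  jittered <- signed + eta > 0
  if (sum(jittered) < 8) jittered <- inside  # degenerate: keep original
  mask_volume(array(as.integer(jittered), d), sp, mask$origin)
}

# region masks (intra + peri unions) for one phase
phase_regions <- function(mask, lung, rings) {
  out <- list(intra = mask)
  if (length(rings)) {
    dm <- distance_map(mask)$values
    for (r in rings) {
      ring <- dm > 0 & dm <= r + 1e-9 & lung$values > 0
      out[[paste0("peri", r)]] <-
        mask_volume(array(as.integer(mask$values > 0 | ring),
                          dim(ring)), mask$spacing, mask$origin)
    }
  }
  out
}

# ring/region names actually needed by the configured signatures
needed_regions <- function(config) {
  regs <- "intra"
  if ("Peri5" %in% config$signatures ||
      "HabitatPeri5" %in% config$signatures) {
    regs <- c(regs, "peri5")
  }
  if ("Peri10" %in% config$signatures) regs <- c(regs, "peri10")
  intersect(c("intra", paste0("peri", config$rings)), regs)
}

# named feature vector for one lesion; habitat_k = c(pre =, post =) or
# NULL to skip habitat features
lesion_features <- function(case, config, habitat_k = NULL,
                            perturb = FALSE, regions = NULL,
                            seed = 1) {
  pp <- preprocess_case(case, config)
  if (perturb) {
    pp$tumor <- perturb_mask(pp$tumor, seed = seed)
    pp$ablation <- perturb_mask(pp$ablation, seed = seed + 1)
  }
  need_rings <- if (is.null(regions)) config$rings else {
    rr <- regions[grepl("^peri", regions)]
    as.numeric(sub("peri", "", rr))
  }
  out <- numeric(0)
  for (phase in c("pre", "post")) {
    img <- pp[[phase]]
    msk <- if (phase == "pre") pp$tumor else pp$ablation
    regs <- phase_regions(msk, pp$lung, need_rings)
    if (!is.null(regions)) regs <- regs[intersect(names(regs), c(regions))]
    for (rn in names(regs)) {
      fv <- extract_features(img, regs[[rn]], bin_width = config$bin_width)
      out <- c(out, stats::setNames(fv, paste0(phase, ".", rn, ".",
                                               names(fv))))
    }
    if (!is.null(habitat_k)) {
      hk <- habitat_k[[phase]]
      hv <- tryCatch({
        bf <- block_features(img, msk)
        map <- cluster_habitats(bf, min(hk, nrow(bf$vectors)), seed = seed)
        habitat_features(img, map, bin_width = config$bin_width)
      }, error = function(e) NULL)
      if (!is.null(hv)) {
        out <- c(out, stats::setNames(hv, paste0(phase, ".", names(hv))))
      }
    }
  }
  out
}

# cohort-level CH vote: modal select_k over polled lesions, per phase
choose_habitat_k <- function(cases, config, seed = 1) {
  if (!is.null(config$k_fixed)) {
    return(list(pre = config$k_fixed, post = config$k_fixed))
  }
  poll <- cases[seq_len(min(config$k_vote_n, length(cases)))]
  pick <- function(phase) {
    ks <- vapply(seq_along(poll), function(i) {
      case <- poll[[i]]
      pp <- preprocess_case(case, config)
      img <- pp[[phase]]
      msk <- if (phase == "pre") pp$tumor else pp$ablation
      tryCatch({
        bf <- block_features(img, msk)
        Z <- scale(bf$vectors)
        Z[!is.finite(Z)] <- 0
        as.integer(select_k(Z, config$k_range, seed = seed + i))
      }, error = function(e) NA_integer_)
    }, integer(1))
    ks <- ks[!is.na(ks)]
    if (!length(ks)) return(3L)
    as.integer(names(sort(table(ks), decreasing = TRUE))[1])
  }
  list(pre = pick("pre"), post = pick("post"))
}

# assemble the lesions x features table (rows aligned, NA-padded)
build_feature_table <- function(cases, config, habitat_k, seed = 1) {
  regions <- needed_regions(config)
  vecs <- lapply(seq_along(cases), function(i) {
    lesion_features(cases[[i]], config, habitat_k = habitat_k,
                    regions = regions, seed = seed + i)
  })
  all_names <- unique(unlist(lapply(vecs, names)))
  tab <- matrix(NA_real_, nrow = length(cases), ncol = length(all_names),
                dimnames = list(vapply(cases, `[[`, "", "lesion_id"),
                                all_names))
  for (i in seq_along(vecs)) tab[i, names(vecs[[i]])] <- vecs[[i]]
  tab
}

# median imputation fit on training rows only
impute_fit <- function(x) apply(x, 2, median, na.rm = TRUE)
impute_apply <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

signature_pool <- function(cols, signature) {
  switch(signature,
         Intra = grep("\\.intra\\.", cols, value = TRUE),
         Peri5 = grep("\\.peri5\\.", cols, value = TRUE),
         Peri10 = grep("\\.peri10\\.", cols, value = TRUE),
         Habitat = grep("\\.habitat", cols, value = TRUE),
         stop("no feature pool for signature ", signature))
}

# the selection cascade for one pool; returns selected features + trace
run_cascade <- function(ztrain, labels, pool, config, icc_keep = NULL,
                        seed = 1) {
  trace <- list(pool_size = length(pool))
  feats <- pool
  if (!is.null(icc_keep)) {
    feats <- intersect(feats, icc_keep)
    trace$after_icc <- length(feats)
  }
  if (length(feats) == 0) return(list(features = character(0), trace = trace))
  kept_t <- suppressWarnings(
    ttest_filter(ztrain[, feats, drop = FALSE], labels, config$alpha))
  trace$after_ttest <- length(kept_t)
  feats <- if (length(kept_t)) kept_t else feats[
    order(attr(kept_t, "p")[feats])][seq_len(min(3, length(feats)))]
  feats <- corr_prune(ztrain[, feats, drop = FALSE], config$corr_threshold)
  trace$after_corr <- length(feats)
  feats <- mrmr_select(ztrain[, feats, drop = FALSE], labels,
                       m = config$mrmr_m)
  trace$after_mrmr <- length(feats)
  if (length(feats) >= 2) {
    las <- lasso_select(ztrain[, feats, drop = FALSE], labels,
                        folds = min(config$lasso_folds, nrow(ztrain) - 1),
                        seed = seed)
    sel <- las$features
    if (!length(sel)) sel <- feats[1]  # keep the top-ranked mRMR feature
    trace$lambda <- las$lambda
  } else {
    sel <- feats
  }
  trace$after_lasso <- length(sel)
  list(features = sel, trace = trace)
}

#' Run the full habitat-radiomics pipeline
#'
#' Generates a seeded synthetic cohort, splits it 4:1, preprocesses all
#' volumes, constructs peritumoral rings and habitat maps, extracts and
#' fuses pre/post features, runs the selection cascade per region pool,
#' fits the configured signature models (the clinical signature via
#' logistic screening), and evaluates everything on the held-out test
#' set. All feature standardization, selection, hyperparameters and
#' decision thresholds are determined on training lesions only.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-generated cohort (list of `lesion_case`),
#'   or a pre-split list with elements `train` and `test`; by default a
#'   cohort is generated from the config.
#' @return A `run_result` list: `report_train`, `report_test`, `models`,
#'   `selected`, `trace`, `habitat_k`, `config`.
#' @export
run_all <- function(config = run_config(), cohort = NULL) {
  t0 <- Sys.time()
  seeds <- child_seeds(config$seed, 6)
  if (is.null(cohort)) {
    cohort <- generate_cohort(cohort_config(
      n_lesions = config$n_lesions,
      noncr_prevalence = config$noncr_prevalence,
      spacing_mm = config$spacing_mm,
      effect_sizes = config$effect_sizes, seed = seeds[1]))
  }
  if (identical(sort(names(cohort)), c("test", "train"))) {
    train <- cohort$train; test <- cohort$test
  } else {
    sp <- split_cohort(cohort, config$ratio_train, seed = seeds[2])
    train <- sp$train; test <- sp$test
  }
  y_train <- vapply(train, `[[`, "", "label") == "nonCR"
  y_test <- vapply(test, `[[`, "", "label") == "nonCR"

  radiomic_sigs <- intersect(config$signatures,
                             c("Intra", "Peri5", "Peri10", "Habitat",
                               "HabitatPeri5"))
  need_habitat <- any(c("Habitat", "HabitatPeri5") %in% config$signatures)
  habitat_k <- if (need_habitat) {
    choose_habitat_k(train, config, seed = seeds[3])
  } else NULL

  models <- list()
  selected <- list()
  trace <- list(habitat_k = habitat_k)
  score_train <- list()
  score_test <- list()
  thresholds <- list()

  if (length(radiomic_sigs)) {
    tab_train <- build_feature_table(train, config, habitat_k,
                                     seed = seeds[3])
    tab_test <- build_feature_table(test, config, habitat_k,
                                    seed = seeds[3])
    tab_test <- tab_test[, colnames(tab_train), drop = FALSE]
    med <- impute_fit(tab_train)
    med[is.na(med)] <- 0
    tab_train <- impute_apply(tab_train, med)
    tab_test <- impute_apply(tab_test, med)
    zs <- zscore_fit(tab_train)
    ztrain <- zscore_apply(tab_train, zs)
    ztest <- zscore_apply(tab_test, zs)

    icc_keep <- NULL
    if (config$icc_n > 0) {
      sub <- train[seq_len(min(config$icc_n, length(train)))]
      tab_a <- build_feature_table(sub, config, habitat_k = NULL,
                                   seed = seeds[4])
      vecs_b <- lapply(seq_along(sub), function(i) {
        lesion_features(sub[[i]], config, habitat_k = NULL,
                        perturb = TRUE, regions = needed_regions(config),
                        seed = seeds[4] + i)
      })
      tab_b <- matrix(NA_real_, nrow = length(sub), ncol = ncol(tab_a),
                      dimnames = dimnames(tab_a))
      for (i in seq_along(vecs_b)) {
        nm <- intersect(names(vecs_b[[i]]), colnames(tab_b))
        tab_b[i, nm] <- vecs_b[[i]][nm]
      }
      common <- colnames(tab_a)[colSums(is.na(tab_a)) == 0 &
                                  colSums(is.na(tab_b)) == 0]
      kept <- icc_filter(tab_a[, common, drop = FALSE],
                         tab_b[, common, drop = FALSE],
                         config$icc_threshold)
      # ICC gates only the non-habitat features it measured
      icc_keep <- union(kept,
                        setdiff(colnames(ztrain),
                                grep("\\.(intra|peri[0-9]+)\\.",
                                     colnames(ztrain), value = TRUE)))
      trace$icc <- list(measured = length(common), kept = length(kept))
    }

    base_sigs <- intersect(c("Intra", "Peri5", "Peri10", "Habitat"),
                           union(radiomic_sigs,
                                 if ("HabitatPeri5" %in% radiomic_sigs)
                                   c("Habitat", "Peri5") else character(0)))
    for (s in base_sigs) {
      pool <- signature_pool(colnames(ztrain), s)
      icc_gate <- if (s == "Habitat") NULL else icc_keep
      cas <- run_cascade(ztrain, y_train, pool, config,
                         icc_keep = icc_gate, seed = seeds[5])
      selected[[s]] <- cas$features
      trace[[paste0("cascade_", s)]] <- cas$trace
    }
    if ("HabitatPeri5" %in% radiomic_sigs) {
      selected$HabitatPeri5 <- union(selected$Habitat, selected$Peri5)
    }
    for (s in radiomic_sigs) {
      fam <- unname(config$families[s])
      mod <- fit_signature(ztrain[, selected[[s]], drop = FALSE], y_train,
                           family = fam, folds = config$cv_folds,
                           seed = seeds[6], name = s)
      models[[s]] <- mod
      score_train[[s]] <- predict(mod, ztrain)
      score_test[[s]] <- predict(mod, ztest)
      thresholds[[s]] <- mod$threshold
    }
  }

  if ("Clinical" %in% config$signatures) {
    ct_train <- clinical_table(train)
    ct_test <- clinical_table(test)
    uni <- suppressWarnings(univariate_screen(ct_train, y_train))
    cand <- uni$variable[!is.na(uni$p) & uni$p < config$alpha]
    if (!length(cand)) {
      cand <- uni$variable[which.min(uni$p)]
    }
    multi <- suppressWarnings(
      multivariate_screen(ct_train, y_train, cand, config$alpha))
    retained <- attr(multi, "retained")
    if (!length(retained)) retained <- cand[which.min(multi$p)]
    enc_train <- as.matrix(encode_clinical(ct_train)[, retained,
                                                     drop = FALSE])
    enc_test <- as.matrix(encode_clinical(ct_test)[, retained,
                                                   drop = FALSE])
    zc <- zscore_fit(enc_train)
    mod <- fit_signature(zscore_apply(enc_train, zc), y_train,
                         family = unname(config$families["Clinical"]),
                         folds = config$cv_folds, seed = seeds[6],
                         name = "Clinical")
    models$Clinical <- mod
    score_train$Clinical <- predict(mod, zscore_apply(enc_train, zc))
    score_test$Clinical <- predict(mod, zscore_apply(enc_test, zc))
    thresholds$Clinical <- mod$threshold
    selected$Clinical <- retained
    trace$screening <- list(univariate = uni, multivariate = multi)
  }

  report_train <- evaluation_report(score_train, y_train,
                                    thresholds = thresholds)
  report_test <- evaluation_report(score_test, y_test,
                                   thresholds = thresholds)
  trace$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  res <- structure(list(report_train = report_train,
                        report_test = report_test,
                        models = models, selected = selected,
                        trace = trace, habitat_k = habitat_k,
                        n_train = length(train), n_test = length(test),
                        config = config),
                   class = "run_result")
  if (!is.null(config$output_dir)) write_run_artifacts(res)
  res
}

write_run_artifacts <- function(res) {
  dir.create(res$config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- res$config$output_dir
  write.csv(report_table(res$report_train),
            file.path(od, "summary_train.csv"), row.names = FALSE)
  write.csv(report_table(res$report_test),
            file.path(od, "summary_test.csv"), row.names = FALSE)
  report_write(res$report_test, file.path(od, "report_test.json"))
  jsonlite::write_json(res$selected, file.path(od, "selected_features.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  # provenance: config echo, its hash, and the selection trace
  cfg_path <- file.path(od, "config.yaml")
  yaml::write_yaml(res$config[setdiff(names(res$config), "families")],
                   cfg_path)
  cat("families:", yaml::as.yaml(as.list(res$config$families)),
      file = cfg_path, append = TRUE, sep = "\n")
  trace <- res$trace
  trace$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(trace, file.path(od, "trace.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null", pretty = TRUE)
  invisible(od)
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>", x$n_train, "train /", x$n_test, "test lesions\n")
  tb <- report_table(x$report_test)
  cat("test-set performance:\n")
  print(tb[, c("signature", "acc", "auc", "ci_lo", "ci_hi")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
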