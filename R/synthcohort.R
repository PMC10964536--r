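# Synthetic-cohort module: seeded generation of paired pre-/post-ablation
# volumes with tumor, ablation-zone and lung masks plus a clinical
# covariate table, moment-matched to the published cohort's training-set
# marginals. The generator is the test substrate for every downstream
# stage: patient imaging is not redistributable, so all statistical
# structure the analysis assumes (three latent texture subregions, a
# residual-tumor wedge in non-CR ablation zones, CA19-9 elevation in
# non-CR lesions, ~20% non-CR prevalence) is planted here explicitly.

# Training-set marginals of the reference cohort (counts -> fractions),
# split by response class where the class difference matters.
tab1_marginals <- function() {
  list(
    age = c(mean = 57.91, sd = 10.42),
    sex_male = 234 / 412,
    cea = list(cr = c(mean = 12.48, sd = 37.91),
               noncr = c(mean = 27.13, sd = 65.92)),
    ca199 = list(cr = c(mean = 25.41, sd = 48.32),
                 noncr = c(mean = 51.75, sd = 88.38)),
    lymphadenopathy = c(cr = 218 / 330, noncr = 64 / 82),
    systemic = c(cr = 231 / 330, noncr = 45 / 82),
    site = list(levels = c("rectum", "sigmoid_left", "transverse_right",
                           "caecum"),
                cr = c(216, 50, 60, 4) / 330,
                noncr = c(58, 8, 15, 1) / 82),
    size_cm = list(cr = c(mean = 1.12, sd = 0.38),
                   noncr = c(mean = 1.35, sd = 0.42)),
    lobe = list(levels = c("RUL", "RML", "RLL", "LUL", "LLL"),
                cr = c(87, 32, 57, 79, 75) / 330,
                noncr = c(11, 7, 21, 15, 28) / 82),
    near_vessels = c(cr = 53 / 330, noncr = 19 / 82),
    near_pleura = c(cr = 199 / 330, noncr = 52 / 82),
    electrode_expandable = c(cr = 310 / 330, noncr = 70 / 82),
    pneumothorax = c(cr = 93 / 330, noncr = 22 / 82),
    iah = c(cr = 93 / 330, noncr = 15 / 82))
}

# HU texture populations. Pre-ablation tumors carry `L` concentric
# latent zones (equal-volume shells); post-ablation zones carry an
# inner (coagulation necrosis), middle (effusion) and edge (congested,
# ground-glass-like) shell, plus a peripheral halo.
zone_params <- function(L, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  if (phase == "pre") {
    # necrotic core -> heterogeneous perinecrotic transition -> viable rim
    base_mean <- c(-60, 25, 95)
    base_sd <- c(15, 45, 25)
  } else {
    # coagulation necrosis -> heterogeneous effusion/hemorrhage ->
    # congested ground-glass-like edge
    base_mean <- c(35, -150, -350)
    base_sd <- c(15, 60, 25)
  }
  if (L == 3) return(list(mean = base_mean, sd = base_sd))
  at <- if (L == 1) 0.5 else seq(0, 1, length.out = L)
  list(mean = stats::approx(c(0, 0.5, 1), base_mean, at)$y,
       sd = stats::approx(c(0, 0.5, 1), base_sd, at)$y)
}

LUNG_HU <- c(mean = -850, sd = 40)
HALO_HU <- c(mean = -550, sd = 60)
HALO_MM <- 4
RESIDUAL_HU <- c(mean = 22.5, sd = 25)  # tumor-interior (middle zone)

# lognormal parameters matched to a target mean/sd
lnorm_pars <- function(m, s) {
  m <- unname(m); s <- unname(s)
  sdlog <- sqrt(log(1 + (s / m)^2))
  c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

rlnorm_ms <- function(n, m, s) {
  p <- lnorm_pars(m, s)
  rlnorm(n, p[["meanlog"]], p[["sdlog"]])
}

rnorm_trunc <- function(n, m, s, lo, hi) {
  x <- rnorm(n, m, s)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), m, s)
    bad <- x < lo | x > hi
  }
  x
}

# class-conditional parameter under a clinical effect multiplier:
# e = 1 reproduces the published class difference, e = 0 removes it.
interp_effect <- function(cr, noncr, e) cr + e * (noncr - cr)

#' Cohort configuration
#'
#' Defaults reproduce the reference study conditions: 515 lesions, 20%
#' non-complete-response prevalence, 1 mm isotropic grid, three latent
#' texture subregions. `effect_sizes` holds two standardized effect
#' multipliers: `residual` scales the residual-tumor wedge texture shift
#' in non-CR ablation zones, `clinical` scales every class difference in
#' the clinical covariates; both 0 yield a label-free null cohort.
#'
#' @param n_lesions number of lesions.
#' @param noncr_prevalence non-CR fraction, in (0, 1).
#' @param spacing_mm voxel spacing of the generated grids.
#' @param latent_subregions number of planted texture zones (>= 1).
#' @param effect_sizes list with `residual` and `clinical` multipliers.
#' @param seed integer seed; equal configs and seeds give byte-identical
#'   cohorts.
#' @param diameter_range_cm admissible nodule diameters (inclusion
#'   criterion: at most 3 cm).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_lesions = 515, noncr_prevalence = 0.2,
                          spacing_mm = c(1, 1, 1), latent_subregions = 3,
                          effect_sizes = list(residual = 1, clinical = 1),
                          seed = 1, diameter_range_cm = c(0.4, 3)) {
  if (!is.numeric(noncr_prevalence) || noncr_prevalence <= 0 ||
      noncr_prevalence >= 1) {
    stop("noncr_prevalence must lie in (0, 1)")
  }
  if (n_lesions < 1) stop("n_lesions must be positive")
  if (latent_subregions < 1) stop("latent_subregions must be >= 1")
  structure(list(n_lesions = as.integer(n_lesions),
                 noncr_prevalence = noncr_prevalence,
                 spacing_mm = as.numeric(spacing_mm),
                 latent_subregions = as.integer(latent_subregions),
                 effect_sizes = list(
                   residual = effect_sizes$residual %||% 1,
                   clinical = effect_sizes$clinical %||% 1),
                 seed = as.integer(seed),
                 diameter_range_cm = diameter_range_cm),
            class = "cohort_config")
}

# One clinical record, class-conditional where the published table
# shows a class difference, attenuated by the clinical effect size.
draw_clinical <- function(label, e) {
  tb <- tab1_marginals()
  noncr <- label == "nonCR"
  pick <- function(x) if (noncr) interp_effect(x["cr"], x["noncr"], e) else x["cr"]
  pick2 <- function(x, f) if (noncr) interp_effect(x$cr[f], x$noncr[f], e) else x$cr[f]
  cea_m <- pick2(tb$cea, "mean"); cea_s <- pick2(tb$cea, "sd")
  ca_m <- pick2(tb$ca199, "mean"); ca_s <- pick2(tb$ca199, "sd")
  size_m <- pick2(tb$size_cm, "mean"); size_s <- pick2(tb$size_cm, "sd")
  site_p <- if (noncr) interp_effect(tb$site$cr, tb$site$noncr, e) else tb$site$cr
  lobe_p <- if (noncr) interp_effect(tb$lobe$cr, tb$lobe$noncr, e) else tb$lobe$cr
  list(
    age = round(rnorm_trunc(1, tb$age["mean"], tb$age["sd"], 18, 90), 1),
    sex = sample(c("M", "F"), 1, prob = c(tb$sex_male, 1 - tb$sex_male)),
    cea = round(rlnorm_ms(1, cea_m, cea_s), 2),
    ca199 = round(rlnorm_ms(1, ca_m, ca_s), 2),
    lymphadenopathy = runif(1) < pick(tb$lymphadenopathy),
    systemic_treatment = runif(1) < pick(tb$systemic),
    primary_site = sample(tb$site$levels, 1, prob = site_p),
    nodule_size = round(rnorm_trunc(1, size_m, size_s, 0.4, 3), 2),
    lobe = sample(tb$lobe$levels, 1, prob = lobe_p),
    near_vessels = runif(1) < pick(tb$near_vessels),
    near_pleura = runif(1) < pick(tb$near_pleura),
    electrode = if (runif(1) < pick(tb$electrode_expandable))
      "expandable" else "straight",
    pneumothorax = runif(1) < pick(tb$pneumothorax),
    iah = runif(1) < pick(tb$iah))
}

# Gaussian smoothing by separable 5-tap convolution (edge-replicated).
smooth3d <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  for (ax in 1:3) {
    sig <- sigma_mm / spacing[ax]
    w <- dnorm(-2:2, sd = max(sig, 1e-6))
    w <- w / sum(w)
    n <- d[ax]
    acc <- array(0, d)
    for (t in -2:2) {
      idx <- pmin(pmax(seq_len(n) + t, 1L), n)
      sl <- switch(ax,
                   arr[idx, , , drop = FALSE],
                   arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
      acc <- acc + w[t + 3] * sl
    }
    arr <- acc
  }
  arr
}

#' Generate one synthetic lesion
#'
#' Builds a paired pre/post grid around an ellipsoidal tumor with
#' concentric latent texture zones; the post-ablation image carries an
#' ablation zone (tumor support enlarged by a random 3-8 mm margin) with
#' its own concentric texture shells and a ground-glass halo. Non-CR
#' lesions additionally receive a residual-tumor wedge occupying 5-30%
#' of the ablation-zone boundary shell, sampled from the tumor-interior
#' texture distribution; CR lesions receive none.
#'
#' @param params list with at least `diameter_cm`, `label` (`"CR"` or
#'   `"nonCR"`); optional `spacing_mm`, `latent_subregions`,
#'   `residual_effect`, `margin_mm`, `wedge_frac`, `extent_mm`,
#'   `clinical`, `lesion_id`, `patient_id`.
#' @param seed integer seed.
#' @return A `lesion_case` with pre/post [image_volume()]s (HU), tumor,
#'   ablation and lung [mask_volume()]s, clinical record and label.
#' @export
generate_lesion <- function(params, seed = 1) {
  with_seed(seed, {
    d_mm <- params$diameter_cm * 10
    label <- match.arg(params$label, c("CR", "nonCR"))
    sp <- params$spacing_mm %||% c(1, 1, 1)
    L <- params$latent_subregions %||% 3L
    e_res <- params$residual_effect %||% 1
    margin <- params$margin_mm %||% runif(1, 3, 8)
    wedge_frac <- params$wedge_frac %||% runif(1, 0.05, 0.30)
    half <- d_mm / 2 + margin + 12
    if (!is.null(params$extent_mm)) {
      if (d_mm + 2 * margin > params$extent_mm) {
        stop("lesion diameter exceeds the requested volume extent")
      }
      half <- params$extent_mm / 2
    }
    nvox <- pmax(9L, as.integer(2 * ceiling(half / sp) + 1))
    ax <- lapply(1:3, function(a) (seq_len(nvox[a]) - (nvox[a] + 1) / 2) * sp[a])
    d <- nvox
    X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
    Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
    Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)

    # ellipsoid: principal semi-axis = d/2 along x, mildly flattened
    semi <- c(d_mm / 2, d_mm / 2 * runif(1, 0.8, 1), d_mm / 2 * runif(1, 0.8, 1))
    r <- sqrt((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2)
    tumor <- r <= 1
    if (!any(tumor)) stop("degenerate lesion: no tumor voxels")

    zp_pre <- params$zones_pre %||% zone_params(L, "pre")
    zp_post <- params$zones_post %||% zone_params(L, "post")
    smooth_mm <- params$smooth_mm %||% 0.4
    shell_breaks <- params$shell_breaks %||% (seq_len(L - 1) / L)^(1 / 3)
    # concentric shells on the normalized radial coordinate (default
    # breaks approximate equal shell volumes)
    zone_of <- function(rr, L) {
      if (L == 1) return(rep(1L, length(rr)))
      findInterval(rr, c(-Inf, shell_breaks, Inf), all.inside = TRUE)
    }
    pre <- array(rnorm(prod(d), LUNG_HU["mean"], LUNG_HU["sd"]), d)
    zi <- zone_of(r[tumor], L)
    pre[tumor] <- rnorm(sum(tumor), zp_pre$mean[zi], zp_pre$sd[zi])
    pre <- smooth3d(pre, smooth_mm, sp)

    # ablation zone: tumor support enlarged by `margin` mm
    dist_t <- sqrt(array(.edt_sq(tumor, as.integer(d), sp), d))
    abl <- dist_t <= margin
    depth <- sqrt(array(.edt_sq(!abl, as.integer(d), sp), d))  # into zone
    maxdep <- max(depth[abl])
    rho <- 1 - depth / max(maxdep, 1e-9)                       # 0 centre, 1 edge
    post <- array(rnorm(prod(d), LUNG_HU["mean"], LUNG_HU["sd"]), d)
    za <- zone_of(rho[abl], L)
    post[abl] <- rnorm(sum(abl), zp_post$mean[za], zp_post$sd[za])
    halo <- !abl & dist_t <= margin + HALO_MM
    post[halo] <- rnorm(sum(halo), HALO_HU["mean"], HALO_HU["sd"])

    if (label == "nonCR") {
      # residual tumor manifests as a wedge of tumor-interior texture
      # straddling the ablation margin: a boundary shell reaching 2 mm
      # into the zone and 3 mm outward into the halo — the peripheral
      # nodular enhancement pattern by which non-CR is read, which
      # makes the peritumoral shell informative beyond the zone itself
      shell <- (abl & depth <= 2) | (!abl & dist_t <= margin + 3)
      inner <- shell & abl
      pos_in <- cbind(X[inner], Y[inner], Z[inner])
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      proj_in <- pos_in %*% u / pmax(sqrt(rowSums(pos_in^2)), 1e-9)
      cut <- quantile(proj_in, 1 - wedge_frac)
      pos <- cbind(X[shell], Y[shell], Z[shell])
      proj <- pos %*% u / pmax(sqrt(rowSums(pos^2)), 1e-9)
      wedge <- which(shell)[proj >= cut]
      res <- rnorm(length(wedge), RESIDUAL_HU["mean"], RESIDUAL_HU["sd"])
      post[wedge] <- (1 - e_res) * post[wedge] + e_res * res
    }
    post <- smooth3d(post, smooth_mm, sp)

    # lung = large ellipsoid around the lesion (rings clip to it)
    lung <- (X / (half - 1))^2 + (Y / (half - 1))^2 + (Z / (half - 1))^2 <= 1

    structure(list(
      lesion_id = params$lesion_id %||% "lesion_1",
      patient_id = params$patient_id %||% "patient_1",
      pre_image = image_volume(pre, sp),
      post_image = image_volume(post, sp),
      tumor_mask = mask_volume(array(as.integer(tumor), d), sp),
      ablation_mask = mask_volume(array(as.integer(abl), d), sp),
      lung_mask = mask_volume(array(as.integer(lung), d), sp),
      clinical = params$clinical %||% NULL,
      label = label,
      margin_mm = margin),
      class = "lesion_case")
  })
}

#' Generate a seeded synthetic cohort
#'
#' Draws labels at the configured non-CR prevalence, class-conditional
#' clinical covariates moment-matched to the reference cohort's
#' training-set marginals (CA19-9 stochastically larger in non-CR at
#' full clinical effect), and one paired pre/post lesion per case.
#'
#' @param config a [cohort_config()].
#' @param images generate image volumes (`TRUE`, default) or a
#'   clinical-only cohort (`FALSE`; volumes are `NULL`), which is
#'   sufficient for split and screening analyses at large `n`.
#' @return A list of `lesion_case` objects.
#' @export
generate_cohort <- function(config, images = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_lesions
  e_cli <- config$effect_sizes$clinical
  with_seed(config$seed, {
    labels <- ifelse(runif(n) < config$noncr_prevalence, "nonCR", "CR")
    n_pat <- max(1L, round(n * 233 / 515))
    pat <- sprintf("P%03d", sample.int(n_pat, n, replace = TRUE))
    clin <- lapply(seq_len(n), function(i) draw_clinical(labels[i], e_cli))
    lesion_seeds <- sample.int(2147483646L, n)
  })
  lo <- config$diameter_range_cm[1]
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- clin[[i]]
    params <- list(diameter_cm = max(ci$nodule_size, lo),
                   label = labels[i],
                   spacing_mm = config$spacing_mm,
                   latent_subregions = config$latent_subregions,
                   residual_effect = config$effect_sizes$residual,
                   clinical = ci,
                   lesion_id = sprintf("L%04d", i),
                   patient_id = pat[i])
    if (images) {
      cases[[i]] <- generate_lesion(params, seed = lesion_seeds[i])
    } else {
      cases[[i]] <- structure(
        c(params[c("lesion_id", "patient_id", "clinical", "label")],
          list(pre_image = NULL, post_image = NULL, tumor_mask = NULL,
               ablation_mask = NULL, lung_mask = NULL)),
        class = "lesion_case")
      cases[[i]]$label <- labels[i]
    }
  }
  cases
}

#' Clinical covariate table of a cohort
#'
#' @param cases list of `lesion_case` objects.
#' @return A data.frame with one row per lesion (ids, covariates,
#'   label).
#' @export
clinical_table <- function(cases) {
  rows <- lapply(cases, function(cs) {
    data.frame(lesion_id = cs$lesion_id, patient_id = cs$patient_id,
               as.data.frame(cs$clinical, stringsAsFactors = FALSE),
               label = cs$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split a cohort into training and test sets
#'
#' Lesion-level random split with `|train| = round(ratio * n)` (half
#' rounds toward the training set), stratified by label so both
#' partitions contain both classes whenever sizes permit.
#'
#' @param cases list of `lesion_case` objects (`n >= 2`).
#' @param ratio_train training fraction in (0, 1); default 0.8 (a 4:1
#'   split, e.g. 515 lesions -> 412 training / 103 test).
#' @param seed integer seed; equal seeds give identical membership.
#' @return list with elements `train` and `test`.
#' @export
split_cohort <- function(cases, ratio_train = 0.8, seed = 1) {
  n <- length(cases)
  if (n < 2) stop("need at least 2 cases to split")
  if (ratio_train <= 0 || ratio_train >= 1) stop("ratio_train must be in (0,1)")
  n_train <- as.integer(floor(ratio_train * n + 0.5))
  n_train <- min(max(n_train, 1L), n - 1L)
  labels <- vapply(cases, function(cs) cs$label, character(1))
  classes <- unique(labels)
  quota <- n_train * table(labels)[classes] / n
  base <- pmin(floor(quota), table(labels)[classes])
  left <- n_train - sum(base)
  if (left > 0) {
    ordr <- order(quota - base, decreasing = TRUE)
    for (j in ordr) {
      if (left == 0) break
      if (base[j] < sum(labels == classes[j])) {
        base[j] <- base[j] + 1
        left <- left - 1
      }
    }
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(j) {
      pool <- which(labels == classes[j])
      sample(pool, base[j])
    }))
  })
  train_idx <- sort(train_idx)
  list(train = cases[train_idx], test = cases[setdiff(seq_len(n), train_idx)])
}

#' Write a cohort to disk
#'
#' Writes per-case NIfTI volumes and masks, one clinical CSV and a JSON
#' manifest; [read_cohort()] round-trips the result.
#'
#' @param cases list of `lesion_case` objects (with images).
#' @param directory output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cases, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  vols <- c("pre_image", "post_image", "tumor_mask", "ablation_mask",
            "lung_mask")
  entries <- lapply(cases, function(cs) {
    files <- stats::setNames(vector("list", length(vols)), vols)
    for (vn in vols) {
      v <- cs[[vn]]
      fn <- file.path(directory, paste0(cs$lesion_id, "_", vn, ".nii.gz"))
      img <- RNifti::asNifti(v$values, internal = FALSE)
      RNifti::pixdim(img) <- v$spacing
      RNifti::writeNifti(img, fn)
      files[[vn]] <- basename(fn)
    }
    list(lesion_id = cs$lesion_id, patient_id = cs$patient_id,
         label = cs$label, files = files,
         spacing = cs$pre_image$spacing, origin = cs$pre_image$origin)
  })
  write.csv(clinical_table(cases),
            file.path(directory, "clinical.csv"), row.names = FALSE)
  manifest <- list(n_lesions = length(cases), lesions = entries)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory cohort directory containing `manifest.json`.
#' @return A list of `lesion_case` objects.
#' @export
read_cohort <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  clin <- read.csv(file.path(directory, "clinical.csv"),
                   stringsAsFactors = FALSE)
  lapply(manifest$lesions, function(en) {
    sp <- as.numeric(unlist(en$spacing))
    org <- as.numeric(unlist(en$origin))
    rd <- function(fn, mask) {
      arr <- array(as.numeric(RNifti::readNifti(file.path(directory, fn))),
                   dim = dim(RNifti::readNifti(file.path(directory, fn))))
      if (mask) mask_volume(array(as.integer(arr > 0.5), dim = dim(arr)),
                            sp, org)
      else image_volume(arr, sp, org)
    }
    row <- clin[clin$lesion_id == en$lesion_id, , drop = FALSE]
    structure(list(
      lesion_id = en$lesion_id, patient_id = en$patient_id,
      pre_image = rd(en$files$pre_image, FALSE),
      post_image = rd(en$files$post_image, FALSE),
      tumor_mask = rd(en$files$tumor_mask, TRUE),
      ablation_mask = rd(en$files$ablation_mask, TRUE),
      lung_mask = rd(en$files$lung_mask, TRUE),
      clinical = as.list(row[setdiff(names(row),
                                     c("lesion_id", "patient_id", "label"))]),
      label = en$label), class = "lesion_case")
  })
}
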