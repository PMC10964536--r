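# Radiomics module: IBSI-aligned geometry, first-order, GLCM and GLRLM
# features from an (image, mask) pair, with fixed-bin-width
# discretization and direction-merged 3D texture aggregation.

# The 13 unique 3D offsets (half of the 26-neighbourhood).
offsets13 <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Fixed-bin-width quantization anchored at the ROI minimum: bin
# `floor((v - min) / bw) + 1`, so shifted intensities land in shifted
# but identically-shaped bins.
quantize_fbw <- function(v, bin_width) {
  q <- floor((v - min(v)) / bin_width) + 1L
  storage.mode(q) <- "integer"
  q
}

# Full co-occurrence feature set from count columns. `counts` is a
# G^2 x B matrix (code = (a-1)*G + b); returns an 18 x B matrix of
# named features. Degenerate distributions (zero joint variance) take
# correlation 1 by convention.
glcm_features_from_counts <- function(counts, G) {
  counts <- as.matrix(counts)
  B <- ncol(counts)
  tot <- colSums(counts)
  tot[tot == 0] <- NA_real_
  P <- sweep(counts, 2, tot, "/")
  code <- seq_len(G * G) - 1L
  a <- code %/% G + 1L
  b <- code %% G + 1L
  mu <- colSums(P * a)
  plog <- P * log2(P)
  plog[!is.finite(plog)] <- 0
  svals <- 2:(2 * G)
  dvals <- 0:(G - 1)
  S <- outer(svals, a + b, "==") %*% P     # p_{i+j}
  D <- outer(dvals, abs(a - b), "==") %*% P  # p_{|i-j|}
  slog <- S * log2(S); slog[!is.finite(slog)] <- 0
  dlog <- D * log2(D); dlog[!is.finite(dlog)] <- 0
  jvar <- colSums(P * a^2) - mu^2
  autoc <- colSums(P * a * b)
  corr <- ifelse(jvar > 1e-12, (autoc - mu^2) / jvar, 1)
  sumavg <- 2 * mu
  Z <- outer(svals, rep(1, B)) -
    matrix(sumavg, nrow = length(svals), ncol = B, byrow = TRUE)
  out <- rbind(
    contrast      = colSums(P * (a - b)^2),
    dissimilarity = colSums(P * abs(a - b)),
    homogeneity   = colSums(P / (1 + abs(a - b))),
    idm           = colSums(P / (1 + (a - b)^2)),
    correlation   = corr,
    asm           = colSums(P^2),
    joint_entropy = -colSums(plog),
    max_prob      = apply(P, 2, max),
    joint_average = mu,
    joint_variance = jvar,
    autocorrelation = autoc,
    sum_average   = sumavg,
    sum_entropy   = -colSums(slog),
    sum_variance  = colSums(S * svals^2) - sumavg^2,
    diff_entropy  = -colSums(dlog),
    diff_variance = colSums(D * dvals^2) - colSums(D * dvals)^2,
    cluster_shade = colSums(S * Z^3),
    cluster_prominence = colSums(S * Z^4))
  out
}

# Maximum 3D diameter from surface-voxel coordinates (mm). Exact for
# moderate surfaces; large surfaces are reduced to directional extreme
# points first (exact for convex shapes, tight in practice).
max_diameter <- function(xyz) {
  n <- nrow(xyz)
  if (n == 1L) return(0)
  if (n > 300L) {
    dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    dirs <- dirs[rowSums(abs(dirs)) > 0, ]
    proj <- xyz %*% t(dirs)
    keep <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    xyz <- xyz[keep, , drop = FALSE]
    n <- nrow(xyz)
  }
  gg <- xyz %*% t(xyz)
  sq <- diag(gg)
  sqrt(max(outer(sq, sq, "+") - 2 * gg))
}

#' Extract radiomics features from an (image, mask) pair
#'
#' Computes geometry (volume, surface area from exposed voxel faces,
#' sphericity, maximum 3D diameter, elongation), intensity first-order
#' (mean, median, SD, energy, entropy, skewness, kurtosis, P10, P90,
#' IQR), GLCM texture (contrast, correlation, joint entropy,
#' homogeneity) and GLRLM texture (SRE, LRE, GLN, RLN). Texture uses
#' fixed-bin-width discretization anchored at the ROI minimum and
#' symmetric co-occurrence/run statistics merged over the 13 unique 3D
#' directions, following IBSI conventions.
#'
#' @param image an [image_volume()] (expected preprocessed: isotropic,
#'   windowed/rescaled intensities).
#' @param mask a nonempty [mask_volume()] on the same grid.
#' @param bin_width intensity bin width for texture discretization
#'   (default 25 on a 0-255 scale).
#' @return A named numeric vector with `family.name` feature names.
#'   Texture features of a single-voxel mask are `NA`.
#' @export
extract_features <- function(image, mask, bin_width = 25) {
  stopifnot_same_grid(image, mask)
  if (sum(mask$values) == 0) stop("mask is empty")
  sp <- image$spacing

  # crop both volumes to the mask bounding box (features are
  # translation-invariant; this only trims background)
  co_all <- arrayInd(which(mask$values > 0), dim(mask$values))
  lo <- apply(co_all, 2, min)
  hi <- apply(co_all, 2, max)
  vals <- image$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] > 0
  dim(vals) <- dim(m) <- hi - lo + 1L
  idx <- which(m)
  v <- vals[idx]
  n <- length(v)

  # --- geometry ---
  d <- dim(m)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  shift_neg <- function(arr, ax) {
    out <- array(FALSE, dim(arr))
    if (dim(arr)[ax] < 2L) return(out)
    idx_src <- lapply(dim(arr), seq_len)
    idx_dst <- idx_src
    idx_src[[ax]] <- seq_len(dim(arr)[ax] - 1L)
    idx_dst[[ax]] <- seq(2L, dim(arr)[ax])
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  shift_pos <- function(arr, ax) {
    out <- array(FALSE, dim(arr))
    if (dim(arr)[ax] < 2L) return(out)
    idx_src <- lapply(dim(arr), seq_len)
    idx_dst <- idx_src
    idx_src[[ax]] <- seq(2L, dim(arr)[ax])
    idx_dst[[ax]] <- seq_len(dim(arr)[ax] - 1L)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  sa <- 0
  exposed <- array(FALSE, d)
  for (ax in 1:3) {
    e1 <- m & !shift_neg(m, ax)
    e2 <- m & !shift_pos(m, ax)
    sa <- sa + (sum(e1) + sum(e2)) * face_area[ax]
    exposed <- exposed | e1 | e2
  }
  vol <- n * prod(sp)
  sphericity <- (pi^(1 / 3) * (6 * vol)^(2 / 3)) / sa
  surf_xyz <- sweep(arrayInd(which(exposed), d), 2, sp, "*")
  maxdiam <- max_diameter(surf_xyz)
  all_xyz <- sweep(arrayInd(idx, d), 2, sp, "*")
  if (n > 1) {
    ev <- eigen(stats::cov(all_xyz), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 1e-12) sqrt(ev[2] / ev[1]) else 1
  } else elong <- 1
  geom <- c(volume_mm3 = vol, surface_area_mm2 = sa, sphericity = sphericity,
            max_diameter_mm = maxdiam, elongation = elong)

  # --- first-order ---
  mu <- mean(v)
  cv <- v - mu
  m2 <- mean(cv^2)
  skew <- if (m2 > 1e-12) mean(cv^3) / m2^1.5 else 0
  kurt <- if (m2 > 1e-12) mean(cv^4) / m2^2 else 0
  qb <- quantize_fbw(v, bin_width)
  fo <- c(mean = mu, median = median(v), sd = if (n > 1) sd(v) else 0,
          energy = sum(v^2), entropy = shannon_entropy(tabulate(qb)),
          skewness = skew, kurtosis = kurt,
          p10 = unname(quantile(v, 0.10)), p90 = unname(quantile(v, 0.90)),
          iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)))
  if (n == 1) fo["sd"] <- 0

  # --- texture ---
  if (n == 1) {
    glcm <- c(contrast = NA_real_, correlation = NA_real_,
              joint_entropy = NA_real_, homogeneity = NA_real_)
    glrlm <- c(sre = NA_real_, lre = NA_real_, gln = NA_real_,
               rln = NA_real_)
  } else {
    G <- max(qb)
    qarr <- array(0L, d)
    qarr[idx] <- qb
    counts <- .glcm_counts(qarr, as.integer(d), G)
    if (sum(counts) == 0) {
      glcm <- c(contrast = NA_real_, correlation = NA_real_,
                joint_entropy = NA_real_, homogeneity = NA_real_)
    } else {
      gf <- glcm_features_from_counts(matrix(counts, ncol = 1), G)
      glcm <- c(contrast = unname(gf["contrast", 1]),
                correlation = unname(gf["correlation", 1]),
                joint_entropy = unname(gf["joint_entropy", 1]),
                homogeneity = unname(gf["homogeneity", 1]))
    }
    st <- .glrlm_stats(qarr, as.integer(d), G)
    glrlm <- c(sre = st[2] / st[1], lre = st[3] / st[1],
               gln = st[4] / st[1], rln = st[5] / st[1])
  }
  out <- c(stats::setNames(geom, paste0("geometry.", names(geom))),
           stats::setNames(fo, paste0("firstorder.", names(fo))),
           stats::setNames(glcm, paste0("glcm.", names(glcm))),
           stats::setNames(glrlm, paste0("glrlm.", names(glrlm))))
  out
}

#' Fuse pre- and post-phase feature vectors
#'
#' Concatenates two feature vectors extracted with identical
#' configuration, prefixing names with their phase.
#'
#' @param pre,post named numeric feature vectors.
#' @param prefixes length-2 character, phase prefixes.
#' @return A named numeric vector of length `length(pre) + length(post)`.
#' @export
fuse_phases <- function(pre, post, prefixes = c("pre", "post")) {
  nm <- c(paste0(prefixes[1], ".", names(pre)),
          paste0(prefixes[2], ".", names(post)))
  if (anyDuplicated(nm)) {
    stop("duplicate fully-qualified feature name after fusion: ",
         nm[duplicated(nm)][1])
  }
  stats::setNames(c(pre, post), nm)
}
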