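# Habitat module: 77-dimensional block feature vectors on non-overlapping
# 3x3x3 windows, Calinski-Harabasz cluster-number selection, K-means
# habitat maps with canonical intensity-ordered labels, and per-habitat
# radiomics summaries.

# Voxel pair lists (within a 3x3x3 block) for each of the 13 offsets,
# computed once and cached.
.block_env <- new.env(parent = emptyenv())

block_pairs <- function() {
  if (!is.null(.block_env$pairs)) return(.block_env$pairs)
  co <- as.matrix(expand.grid(x = 1:3, y = 1:3, z = 1:3))
  lin <- function(p) p[, 1] + 3L * (p[, 2] - 1L) + 9L * (p[, 3] - 1L)
  offs <- offsets13()
  pairs <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    q <- sweep(co, 2, offs[r, ], "+")
    ok <- q[, 1] >= 1 & q[, 1] <= 3 & q[, 2] >= 1 & q[, 2] <= 3 &
      q[, 3] >= 1 & q[, 3] <= 3
    pairs[[r]] <- cbind(lin(co[ok, , drop = FALSE]),
                        lin(q[ok, , drop = FALSE]))
  }
  .block_env$pairs <- pairs
  pairs
}

# The documented 77-name composition: 17 first-order moments and order
# statistics, local entropy and uniformity at 3 bin depths, and the full
# 18-feature co-occurrence set at the same 3 bin depths.
block_feature_names <- function(bins = c(8, 16, 32)) {
  fo <- c("mean", "sd", "variance", "median", "min", "max", "range",
          "p10", "p25", "p75", "p90", "iqr", "skewness", "kurtosis",
          "energy", "rms", "mad")
  glcm <- c("contrast", "dissimilarity", "homogeneity", "idm",
            "correlation", "asm", "joint_entropy", "max_prob",
            "joint_average", "joint_variance", "autocorrelation",
            "sum_average", "sum_entropy", "sum_variance", "diff_entropy",
            "diff_variance", "cluster_shade", "cluster_prominence")
  c(paste0("fo_", fo),
    paste0("entropy_b", bins), paste0("uniformity_b", bins),
    unlist(lapply(bins, function(b) paste0("glcm_b", b, "_", glcm))))
}

#' Local feature vectors on non-overlapping 3x3x3 blocks
#'
#' Tiles the ROI bounding box with non-overlapping 3x3x3 voxel blocks
#' and computes a 77-dimensional local feature vector per block:
#' first-order statistics, local Shannon entropy and uniformity over
#' fixed bins on the 0-255 scale (8/16/32 grey levels), and
#' co-occurrence texture merged over the 13 unique 3D directions at the
#' same three grey-level depths. Only blocks with at least 50% of their
#' voxels inside the ROI are retained.
#'
#' @param image preprocessed [image_volume()] (1 mm isotropic, 0-255).
#' @param roi [mask_volume()] on the same grid.
#' @return A `block_feature_set`: list with `vectors` (blocks x 77
#'   matrix), `feature_names`, `block_index` (blocks x 3 lattice
#'   coordinates), `voxel_index` (27 x blocks matrix of linear voxel
#'   indices into the volume) and `roi_mask` (27 x blocks logical).
#' @export
block_features <- function(image, roi) {
  stopifnot_same_grid(image, roi)
  d <- dim(image$values)
  idx <- which(roi$values > 0)
  if (!length(idx)) stop("ROI is empty")
  co <- arrayInd(idx, d)
  lo <- apply(co, 2, min)
  hi <- apply(co, 2, max)
  nb <- ceiling((hi - lo + 1) / 3)
  ax_idx <- lapply(1:3, function(a) {
    pmin(pmax(lo[a] + 0:(3 * nb[a] - 1), 1L), d[a])  # clamp at edges
  })
  gx <- ax_idx[[1]]; gy <- ax_idx[[2]]; gz <- ax_idx[[3]]
  # linear indices of the cropped lattice in the full volume
  full_lin <- outer(outer(gx, (gy - 1) * d[1], "+"),
                    (gz - 1) * d[1] * d[2], "+")
  vals <- image$values[full_lin]
  inroi <- roi$values[full_lin] > 0
  nxc <- 3 * nb[1]; nyc <- 3 * nb[2]
  ii <- rep(seq_len(nxc), times = nyc * 3 * nb[3])
  jj <- rep(rep(seq_len(nyc), each = nxc), times = 3 * nb[3])
  kk <- rep(seq_len(3 * nb[3]), each = nxc * nyc)
  bid <- ((ii - 1) %/% 3) + nb[1] * ((jj - 1) %/% 3) +
    nb[1] * nb[2] * ((kk - 1) %/% 3) + 1L
  ord <- order(bid)
  B_all <- nb[1] * nb[2] * nb[3]
  M <- matrix(vals[ord], nrow = 27L, ncol = B_all)
  R <- matrix(inroi[ord], nrow = 27L, ncol = B_all)
  V <- matrix(full_lin[ord], nrow = 27L, ncol = B_all)
  keep <- colSums(R) >= 14L
  if (!any(keep)) stop("ROI smaller than one 3x3x3 block")
  M <- M[, keep, drop = FALSE]
  R <- R[, keep, drop = FALSE]
  V <- V[, keep, drop = FALSE]
  block_index <- arrayInd(which(keep), nb)
  Bn <- ncol(M)

  # first-order block statistics (columns sorted in one vectorized pass)
  srt <- matrix(M[order(rep(seq_len(Bn), each = 27L), M)], nrow = 27L)
  qrow <- function(p) {
    h <- 1 + p * 26
    fl <- floor(h); fr <- h - fl
    srt[fl, ] * (1 - fr) + srt[pmin(fl + 1, 27), ] * fr
  }
  mu <- colMeans(M)
  cen <- sweep(M, 2, mu)
  m2 <- colMeans(cen^2)
  vr <- m2 * 27 / 26
  skew <- ifelse(m2 > 1e-12, colMeans(cen^3) / m2^1.5, 0)
  kurt <- ifelse(m2 > 1e-12, colMeans(cen^4) / m2^2, 0)
  p10 <- qrow(0.10); p25 <- qrow(0.25); p75 <- qrow(0.75); p90 <- qrow(0.90)
  fo <- rbind(mean = mu, sd = sqrt(vr), variance = vr,
              median = srt[14, ], min = srt[1, ], max = srt[27, ],
              range = srt[27, ] - srt[1, ], p10 = p10, p25 = p25,
              p75 = p75, p90 = p90, iqr = p75 - p25,
              skewness = skew, kurtosis = kurt,
              energy = colSums((M / 255)^2), rms = sqrt(colMeans(M^2)),
              mad = colMeans(abs(cen)))

  bins <- c(8L, 16L, 32L)
  pairs <- block_pairs()
  ent <- NULL; unif <- NULL; glcm <- NULL
  for (G in bins) {
    lv <- pmin(M %/% (256 / G), G - 1) + 1L
    storage.mode(lv) <- "integer"
    codes <- lv + rep((seq_len(Bn) - 1L) * G, each = 27L)
    cnt <- matrix(tabulate(codes, G * Bn), nrow = G)
    p <- cnt / 27
    pl <- p * log2(p); pl[!is.finite(pl)] <- 0
    ent <- rbind(ent, -colSums(pl))
    unif <- rbind(unif, colSums(p^2))
    pall <- do.call(rbind, pairs)
    acc <- .block_glcm_counts(lv, pall[, 1], pall[, 2], G)
    glcm <- rbind(glcm, glcm_features_from_counts(acc, G))
  }
  vectors <- t(rbind(fo, ent, unif, glcm))
  colnames(vectors) <- block_feature_names(bins)
  structure(list(vectors = vectors,
                 feature_names = colnames(vectors),
                 block_index = block_index,
                 voxel_index = V, roi_mask = R,
                 dim = d, spacing = image$spacing, origin = image$origin),
            class = "block_feature_set")
}

#' Calinski-Harabasz score of a clustering
#'
#' `CH = (B / (k - 1)) / (W / (n - k))` where `B` is the between-cluster
#' and `W` the within-cluster sum of squared distances to centroids.
#' Returns `Inf` when `W = 0` (perfectly tight clusters).
#'
#' @param vectors numeric matrix (points x features).
#' @param labels integer cluster labels, `k >= 2` nonempty clusters and
#'   `n > k`.
#' @return The CH score (scalar, possibly `Inf`).
#' @export
ch_score <- function(vectors, labels) {
  vectors <- as.matrix(vectors)
  labels <- as.integer(factor(labels))
  n <- nrow(vectors)
  k <- max(labels)
  if (k < 2) stop("need at least 2 clusters")
  if (any(tabulate(labels, k) == 0)) stop("empty cluster")
  if (n <= k) stop("need more points than clusters")
  grand <- colMeans(vectors)
  W <- 0; B <- 0
  for (c in seq_len(k)) {
    xc <- vectors[labels == c, , drop = FALSE]
    ctr <- colMeans(xc)
    W <- W + sum(sweep(xc, 2, ctr)^2)
    B <- B + nrow(xc) * sum((ctr - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of habitats by Calinski-Harabasz score
#'
#' Runs seeded, restarted K-means for each candidate `k` and returns the
#' `k` maximizing the CH score (ties broken toward the smallest `k`).
#'
#' @param vectors numeric matrix (points x features); standardize before
#'   calling if features are on different scales.
#' @param k_range integer candidates, constrained to `[2, n - 1]`.
#' @param seed integer seed for the K-means restarts.
#' @param n_init number of K-means restarts per candidate.
#' @return The selected `k`, with the CH curve attached as
#'   `attr(, "ch")`.
#' @export
select_k <- function(vectors, k_range = 2:6, seed = 1, n_init = 10) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("empty cluster-number range")
  ch <- with_seed(seed, vapply(k_range, function(k) {
    km <- suppressWarnings(
      kmeans(vectors, centers = k, nstart = n_init, iter.max = 100))
    ch_score(vectors, km$cluster)
  }, numeric(1)))
  k <- k_range[which.max(ch)]  # which.max takes the first (smallest k) tie
  structure(k, ch = stats::setNames(ch, k_range))
}

#' Cluster block features into a canonical habitat map
#'
#' Z-scores the block feature vectors (per lesion), runs seeded K-means,
#' broadcasts block labels to member ROI voxels, and renumbers labels in
#' ascending order of mean block intensity, so habitat 1 is always the
#' darkest subregion.
#'
#' @param features a `block_feature_set` from [block_features()].
#' @param K number of habitats (`1 <= K <=` number of blocks).
#' @param seed integer seed.
#' @param n_init number of K-means restarts.
#' @return A `habitat_map`: list with `labels` (integer volume, 0
#'   outside), `K` and grid metadata.
#' @export
cluster_habitats <- function(features, K, seed = 1, n_init = 10) {
  X <- features$vectors
  B <- nrow(X)
  if (K < 1) stop("K must be >= 1")
  if (K > B) stop("K exceeds the number of blocks")
  if (K == 1) {
    lab <- rep(1L, B)
  } else {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv < 1e-12] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    km <- with_seed(seed, suppressWarnings(
      kmeans(Z, centers = K, nstart = n_init, iter.max = 100)))
    lab <- km$cluster
    # canonical order: ascending mean (unstandardized) block intensity
    mean_int <- tapply(X[, "fo_mean"], lab, mean)
    relabel <- integer(K)
    relabel[as.integer(names(sort(mean_int)))] <- seq_len(K)
    lab <- relabel[lab]
  }
  vol <- array(0L, features$dim)
  vox <- features$voxel_index
  inroi <- features$roi_mask
  lab_mat <- matrix(rep(lab, each = 27L), nrow = 27L)
  vol[vox[inroi]] <- lab_mat[inroi]
  structure(list(labels = vol, K = as.integer(K),
                 block_labels = lab,
                 spacing = features$spacing, origin = features$origin),
            class = "habitat_map")
}

#' Per-habitat radiomics features and their across-habitat mean
#'
#' Extracts the full radiomics feature set within each habitat label and
#' adds the across-habitat mean of every feature. Habitats with fewer
#' than 8 voxels are marked missing and excluded from the mean.
#'
#' @param image preprocessed [image_volume()].
#' @param map a `habitat_map` from [cluster_habitats()].
#' @param bin_width texture bin width passed to [extract_features()].
#' @return A named numeric vector with `habitat<k>.` and `habitatmean.`
#'   prefixes.
#' @export
habitat_features <- function(image, map, bin_width = 25) {
  per <- vector("list", map$K)
  for (k in seq_len(map$K)) {
    sub <- map$labels == k
    if (sum(sub) < 8) {
      per[[k]] <- NULL
      next
    }
    msk <- mask_volume(array(as.integer(sub), dim = dim(sub)),
                       map$spacing, map$origin)
    per[[k]] <- extract_features(image, msk, bin_width = bin_width)
  }
  template <- per[!vapply(per, is.null, logical(1))]
  if (!length(template)) stop("no habitat has enough voxels")
  feat_names <- names(template[[1]])
  out <- numeric(0)
  for (k in seq_len(map$K)) {
    v <- if (is.null(per[[k]])) {
      stats::setNames(rep(NA_real_, length(feat_names)), feat_names)
    } else per[[k]]
    out <- c(out, stats::setNames(v, paste0("habitat", k, ".", feat_names)))
  }
  valid <- do.call(rbind, template)
  mean_feat <- colMeans(valid, na.rm = TRUE)
  c(out, stats::setNames(mean_feat, paste0("habitatmean.", feat_names)))
}
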