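test_that("block feature vectors have exactly 77 named dimensions", {
  img <- noise_image(12, seed = 2)
  roi <- cube_mask(12, 9)
  bf <- block_features(img, roi)
  expect_equal(ncol(bf$vectors), 77)
  expect_equal(length(unique(bf$feature_names)), 77)
  expect_true(all(is.finite(bf$vectors)))
  expect_equal(nrow(bf$vectors), 27)  # 9^3 ROI -> 3^3 full blocks
})

test_that("blocks below 50% ROI coverage are excluded", {
  img <- noise_image(12, seed = 5)
  arr <- array(0L, c(12, 12, 12))
  arr[1:3, 1:3, 1:3] <- 1L       # one full block
  arr[7:9, 7:9, 7] <- 1L         # 9/27 voxels: below threshold
  bf <- block_features(img, mask_volume(arr))
  expect_equal(nrow(bf$vectors), 1)
  expect_error(block_features(img, mask_volume(array(
    c(1L, rep(0L, 12^3 - 1)), c(12, 12, 12)))), "block")
})

test_that("constant and two-valued blocks give closed-form local stats", {
  arr <- array(50, c(3, 3, 3))
  img <- image_volume(arr)
  roi <- mask_volume(array(1L, c(3, 3, 3)))
  bf <- block_features(img, roi)
  v <- bf$vectors[1, ]
  expect_equal(unname(v["fo_mean"]), 50)
  expect_equal(unname(v["fo_sd"]), 0)
  expect_equal(unname(v["fo_skewness"]), 0)
  expect_equal(unname(v["entropy_b8"]), 0)
  expect_equal(unname(v["uniformity_b8"]), 1)

  # 13 voxels at 10, 14 voxels at 200: entropy = -sum p log2 p
  arr2 <- array(c(rep(10, 13), rep(200, 14)), c(3, 3, 3))
  bf2 <- block_features(image_volume(arr2), roi)
  p <- c(13, 14) / 27
  expect_equal(unname(bf2$vectors[1, "entropy_b8"]),
               -sum(p * log2(p)))
  expect_equal(unname(bf2$vectors[1, "uniformity_b8"]), sum(p^2))
})

test_that("CH score matches pencil-and-paper and brute-force dispersion", {
  # 6 points, 2 clusters: {(0,0),(0,1),(1,0)} and {(5,5),(5,6),(6,5)}
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(5, 5), c(5, 6), c(6, 5))
  lab <- c(1, 1, 1, 2, 2, 2)
  # by hand: centroids (1/3,1/3) and (16/3,16/3); W = 4/3 per cluster;
  # grand (17/6,17/6); B = 2 * 3 * ((5/2)^2 + (5/2)^2) = 75
  ch_hand <- (75 / 1) / ((8 / 3) / 4)
  expect_equal(ch_score(x, lab), ch_hand)
  expect_equal(ch_score(x, lab), ch_brute(x, lab))

  set.seed(8)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    xx <- matrix(rnorm(n * 3), n)
    ll <- sample(1:3, n, replace = TRUE)
    if (length(unique(ll)) < 2) next
    expect_equal(ch_score(xx, ll), ch_brute(xx, ll))
  }
})

test_that("CH score separation property and degenerate cases", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 20),
             matrix(rnorm(40, 5, 0.2), 20))
  true_lab <- rep(1:2, each = 20)
  rand_lab <- sample(true_lab)
  expect_gt(ch_score(x, true_lab), ch_score(x, rand_lab))
  # zero within-cluster dispersion -> +Inf sentinel
  xx <- rbind(matrix(0, 5, 2), matrix(1, 5, 2))
  expect_equal(ch_score(xx, rep(1:2, each = 5)), Inf)
  expect_error(ch_score(x, rep(1, 40)), "2 clusters")
  expect_error(ch_score(x[1:3, ], c(1, 2, 3)), "more points")
})

test_that("select_k recovers planted Gaussian mixtures", {
  set.seed(31)
  ok3 <- 0
  for (s in 1:20) {
    x <- rbind(matrix(rnorm(60 * 5, 0), ncol = 5),
               matrix(rnorm(60 * 5, 4), ncol = 5),
               matrix(rnorm(60 * 5, 8), ncol = 5))
    if (select_k(x, 2:6, seed = s) == 3) ok3 <- ok3 + 1
  }
  expect_gte(ok3, 19)
  x2 <- rbind(matrix(rnorm(50 * 4, 0), ncol = 4),
              matrix(rnorm(50 * 4, 6), ncol = 4))
  expect_equal(as.integer(select_k(x2, 2:6, seed = 1)), 2L)
  # single Gaussian: some K comes back, no crash
  x1 <- matrix(rnorm(200), ncol = 4)
  expect_true(select_k(x1, c(2, 3), seed = 1) %in% 2:3)
  expect_error(select_k(x1, integer(0)), "empty")
})

test_that("habitat maps are canonical, deterministic and order-independent", {
  set.seed(12)
  img <- noise_image(12, seed = 12)
  # plant two intensity blobs inside the ROI
  img$values[2:6, 2:10, 2:10] <- 40 + rnorm(5 * 9 * 9, 0, 4)
  img$values[7:11, 2:10, 2:10] <- 210 + rnorm(5 * 9 * 9, 0, 4)
  roi <- mask_volume(array(as.integer(
    slice.index(array(0, c(12, 12, 12)), 1) %in% 2:11 &
    slice.index(array(0, c(12, 12, 12)), 2) %in% 2:10 &
    slice.index(array(0, c(12, 12, 12)), 3) %in% 2:10), c(12, 12, 12)))
  bf <- block_features(img, roi)
  map1 <- cluster_habitats(bf, 2, seed = 4)
  map2 <- cluster_habitats(bf, 2, seed = 99)
  # canonical ordering: label 1 is the darker habitat, any seed
  m1 <- mean(img$values[map1$labels == 1])
  m2 <- mean(img$values[map1$labels == 2])
  expect_lt(m1, m2)
  expect_identical(map1$labels, map2$labels)
  expect_error(cluster_habitats(bf, nrow(bf$vectors) + 1, 1), "exceeds")
  # K = 1: everything is habitat 1
  map0 <- cluster_habitats(bf, 1, seed = 1)
  expect_equal(sort(unique(as.vector(map0$labels))), c(0L, 1L))
})

test_that("two-blob clustering equals the brute-force min-SSE labeling", {
  set.seed(13)
  # <= 12 blocks: exhaustive assignment oracle
  img <- image_volume(array(0, c(6, 6, 3)))
  img$values[1:3, , ] <- 20
  img$values[4:6, , ] <- 230
  roi <- mask_volume(array(1L, c(6, 6, 3)))
  bf <- block_features(img, roi)
  B <- nrow(bf$vectors)
  map <- cluster_habitats(bf, 2, seed = 2)
  Z <- scale(bf$vectors); Z[!is.finite(Z)] <- 0
  # brute force over all 2-partitions
  best <- NULL; best_sse <- Inf
  for (code in 1:(2^B - 2)) {
    lab <- as.integer(intToBits(code))[1:B] + 1L
    if (length(unique(lab)) < 2) next
    sse <- sum(vapply(1:2, function(c) {
      xc <- Z[lab == c, , drop = FALSE]
      if (!nrow(xc)) return(0)
      sum(sweep(xc, 2, colMeans(xc))^2)
    }, numeric(1)))
    if (sse < best_sse) { best_sse <- sse; best <- lab }
  }
  # compare partitions up to label swap
  got <- map$block_labels
  agree <- max(mean(got == best), mean(got == (3L - best)))
  expect_equal(agree, 1)
})

test_that("habitat features include per-habitat values and their mean", {
  img <- image_volume(array(0, c(6, 6, 3)))
  img$values[1:3, , ] <- 20
  img$values[4:6, , ] <- 230
  roi <- mask_volume(array(1L, c(6, 6, 3)))
  bf <- block_features(img, roi)
  map <- cluster_habitats(bf, 2, seed = 2)
  hf <- habitat_features(img, map)
  m1 <- hf["habitat1.firstorder.mean"]
  m2 <- hf["habitat2.firstorder.mean"]
  expect_equal(unname(hf["habitatmean.firstorder.mean"]),
               unname((m1 + m2) / 2))
  # K = 1: per-habitat features equal whole-ROI features
  map1 <- cluster_habitats(bf, 1, seed = 1)
  hf1 <- habitat_features(img, map1)
  whole <- extract_features(img, roi)
  expect_equal(unname(hf1["habitat1.firstorder.mean"]),
               unname(whole["firstorder.mean"]))
  expect_equal(unname(hf1["habitatmean.glcm.contrast"]),
               unname(whole["glcm.contrast"]))
})

test_that("habitat structure in generated lesions is recovered per lesion", {
  ks <- integer(0)
  for (s in 1:6) {
    les <- generate_lesion(list(diameter_cm = 1.6, label = "CR"),
                           seed = 500 + s)
    post <- window_scale(les$post_image)
    bf <- block_features(post, les$ablation_mask)
    Z <- scale(bf$vectors); Z[!is.finite(Z)] <- 0
    ks <- c(ks, as.integer(select_k(Z, 2:6, seed = s)))
  }
  expect_gte(sum(ks == 3), 5)
})
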