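# Small in-code fixtures shared across test files.

# a cube mask of side `side` centred in a volume of side `n`
cube_mask <- function(n = 16, side = 10, spacing = c(1, 1, 1)) {
  arr <- array(0L, c(n, n, n))
  lo <- floor((n - side) / 2) + 1
  arr[lo:(lo + side - 1), lo:(lo + side - 1), lo:(lo + side - 1)] <- 1L
  mask_volume(arr, spacing)
}

# constant-intensity image on the same grid as a mask
const_image <- function(mask, value = 100) {
  image_volume(array(value, dim(mask$values)), mask$spacing, mask$origin)
}

# deterministic pseudo-random image
noise_image <- function(n = 16, seed = 1, spacing = c(1, 1, 1),
                        mean = 128, sd = 20) {
  set.seed(seed)
  image_volume(array(pmin(pmax(rnorm(n^3, mean, sd), 0), 255), c(n, n, n)),
               spacing)
}

# brute-force AUC by exhaustive concordant-pair counting
auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# brute-force CH score from dispersion sums
ch_brute <- function(x, lab) {
  x <- as.matrix(x)
  g <- colMeans(x)
  k <- length(unique(lab))
  W <- 0; B <- 0
  for (c in unique(lab)) {
    xc <- x[lab == c, , drop = FALSE]
    ctr <- colMeans(xc)
    W <- W + sum(t(t(xc) - ctr)^2)
    B <- B + nrow(xc) * sum((ctr - g)^2)
  }
  (B / (k - 1)) / (W / (nrow(x) - k))
}

# rotate a 3D array 90 degrees about the z axis (transpose + flip)
rot90_z <- function(arr) {
  out <- aperm(arr, c(2, 1, 3))
  out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
}
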