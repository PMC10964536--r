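# Imaging module: volume containers, isotropic resampling, intensity
# windowing, and physical-unit peritumoral ring construction.

#' Construct a 3D image volume
#'
#' A minimal container for a 3D scalar grid with physical voxel spacing
#' and origin (both in mm). The array is indexed `(x, y, z)` with `x`
#' fastest; the centre of voxel `(i, j, k)` sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values numeric 3D array of finite voxel values.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of the first
#'   voxel centre.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite numbers (mm)")
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a binary mask volume
#'
#' @param values array of 0/1 (or logical) values on the same lattice as
#'   a companion [image_volume()].
#' @inheritParams image_volume
#' @return An object of class `mask_volume` (also an `image_volume`).
#' @export
mask_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.logical(values)) {
    values <- array(as.integer(values), dim = dim(values))
  }
  if (!all(values %in% c(0L, 1L))) stop("mask values must be 0/1")
  vol <- image_volume(array(as.integer(values), dim = dim(values)),
                      spacing, origin)
  class(vol) <- c("mask_volume", class(vol))
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
  invisible(TRUE)
}

# Resample one axis of a 3D array by cubic-spline (per line) or nearest
# neighbour. `u` gives the old (fractional) index coordinate of each new
# sample along `axis`.
resample_axis <- function(arr, axis, u, mode) {
  d <- dim(arr)
  n_old <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n_old)
  if (mode == "nearest") {
    idx <- pmin(pmax(round(u), 1L), n_old)
    out <- m[idx, , drop = FALSE]
  } else {
    uc <- pmin(pmax(u, 1), n_old)
    if (n_old == 1L) {
      out <- m[rep(1L, length(u)), , drop = FALSE]
    } else {
      out <- apply(m, 2L, function(col) {
        splinefun(seq_len(n_old), col, method = "natural")(uc)
      })
      out <- matrix(out, nrow = length(u))
    }
  }
  newd <- d
  newd[axis] <- length(u)
  aperm(array(out, dim = newd[perm]), order(perm))
}

#' Resample a volume to a target (typically isotropic) spacing
#'
#' Resamples by separable cubic-spline interpolation (`mode =
#' "bspline"`) or nearest neighbour (`mode = "nearest"`; mandatory for
#' masks). The output grid keeps the input origin and spans the input's
#' physical extent: the new size along each axis is
#' `ceiling(size * spacing / target)`, so the extent is preserved to
#' within one voxel per axis. An input already at the target spacing is
#' returned with its values unchanged.
#'
#' @param image an [image_volume()] or [mask_volume()].
#' @param target_spacing numeric length-3 target spacing in mm
#'   (default 1 mm isotropic).
#' @param mode `"bspline"` for intensities, `"nearest"` for masks.
#' @return A volume of the same class on the new grid.
#' @export
resample_isotropic <- function(image, target_spacing = c(1, 1, 1),
                               mode = c("bspline", "nearest")) {
  mode <- match.arg(mode)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0)) {
    stop("target spacing must be positive")
  }
  if (inherits(image, "mask_volume") && mode != "nearest") {
    stop("masks must be resampled with mode = \"nearest\"")
  }
  d <- dim(image$values)
  if (all(abs(image$spacing - target_spacing) < 1e-9)) return(image)
  new_d <- pmax(1L, as.integer(ceiling(d * image$spacing / target_spacing)))
  arr <- image$values
  for (ax in 1:3) {
    if (new_d[ax] == dim(arr)[ax] &&
        abs(image$spacing[ax] - target_spacing[ax]) < 1e-9) next
    # physical position of new sample j: origin + (j-1)*target
    u <- (seq_len(new_d[ax]) - 1) * target_spacing[ax] / image$spacing[ax] + 1
    arr <- resample_axis(arr, ax, u, mode)
  }
  if (inherits(image, "mask_volume")) {
    mask_volume(array(as.integer(arr > 0.5), dim = dim(arr)),
                target_spacing, image$origin)
  } else {
    image_volume(arr, target_spacing, image$origin)
  }
}

#' Window and rescale CT intensities
#'
#' Affine map of the HU window `[lo, hi]` onto `[0, out_max]` with
#' clamping outside the window. Defaults follow a wide lung window of
#' -1200 to 600 HU scaled to 0-255.
#'
#' @param image an [image_volume()] in HU.
#' @param lo,hi window bounds in HU (`lo < hi`).
#' @param out_max upper bound of the output intensity range.
#' @return An [image_volume()] with values in `[0, out_max]`.
#' @export
window_scale <- function(image, lo = -1200, hi = 600, out_max = 255) {
  if (lo >= hi) stop("`lo` must be strictly less than `hi`")
  v <- pmin(pmax(image$values, lo), hi)
  image_volume(array((v - lo) / (hi - lo) * out_max, dim = dim(v)),
               image$spacing, image$origin)
}

#' Euclidean distance map of a binary mask
#'
#' Distance (mm) from every voxel centre to the nearest foreground voxel
#' centre, computed by a separable exact squared-distance transform that
#' honours anisotropic spacing.
#'
#' @param mask a nonempty [mask_volume()].
#' @return An [image_volume()] of distances in mm (0 inside the mask).
#' @export
distance_map <- function(mask) {
  d <- dim(mask$values)
  if (sum(mask$values) == 0) stop("mask is empty")
  sq <- .edt_sq(as.logical(mask$values), as.integer(d),
                as.numeric(mask$spacing))
  image_volume(array(sqrt(sq), dim = d), mask$spacing, mask$origin)
}

#' Construct a peritumoral ring in physical units
#'
#' The ring is the set of voxels whose Euclidean distance to the mask is
#' in `(0, thickness]` mm, intersected with the lung mask (if supplied)
#' and with any exclusion mask removed. The ring is always disjoint from
#' the input mask, and rings are nested in `thickness`.
#'
#' @param mask nonempty [mask_volume()] to dilate around.
#' @param thickness ring thickness in mm (default 5).
#' @param lung optional lung [mask_volume()]; the ring is clipped to it.
#' @param exclusion optional [mask_volume()] of structures to exclude
#'   (heart, major vessels, diaphragm).
#' @return A [mask_volume()] for the ring.
#' @export
dilate_ring <- function(mask, thickness = 5, lung = NULL, exclusion = NULL) {
  if (thickness <= 0) stop("ring thickness must be positive")
  if (sum(mask$values) == 0) stop("mask is empty")
  if (!is.null(lung)) stopifnot_same_grid(mask, lung)
  if (!is.null(exclusion)) stopifnot_same_grid(mask, exclusion)
  d <- distance_map(mask)$values
  ring <- d > 0 & d <= thickness + 1e-9
  if (!is.null(lung)) ring <- ring & lung$values > 0
  if (!is.null(exclusion)) ring <- ring & exclusion$values == 0
  mask_volume(array(as.integer(ring), dim = dim(ring)),
              mask$spacing, mask$origin)
}

#' Union of a region mask and its peritumoral ring
#'
#' The "Peri-X" region used for signature construction: the intratumoral
#' (or ablation) mask together with its X-mm ring.
#'
#' @param mask region [mask_volume()].
#' @param ring ring [mask_volume()] from [dilate_ring()].
#' @return A [mask_volume()] of the union.
#' @export
peri_union <- function(mask, ring) {
  stopifnot_same_grid(mask, ring)
  mask_volume(array(as.integer(mask$values > 0 | ring$values > 0),
                    dim = dim(mask$values)),
              mask$spacing, mask$origin)
}
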