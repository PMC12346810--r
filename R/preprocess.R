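#' Merge mask labels into a binary ROI
#'
#' Produces a binary mask that is 1 where the input label belongs to
#' `include_labels` and 0 elsewhere. Used to pool the anatomical structures
#' that make up the region of interest (e.g. parenchyma, duct, lesion) while
#' excluding others (vessels, adjacent organs).
#'
#' @param mask a [mask_grid()].
#' @param include_labels non-empty integer vector of labels to keep; must not
#'   contain 0 (background).
#' @return A binary [mask_grid()] on the same grid.
#' @export
merge_labels <- function(mask, include_labels) {
  stopifnot(inherits(mask, "mask_grid"))
  include_labels <- as.integer(include_labels)
  if (length(include_labels) == 0L)
    stop("include_labels must be non-empty", call. = FALSE)
  if (any(include_labels == 0L))
    stop("include_labels must not contain 0 (background)", call. = FALSE)
  out <- array(0L, dim = dim(mask$labels))
  out[mask$labels %in% include_labels] <- 1L
  if (all(out == 0L))
    message("merge_labels: none of the requested labels are present; ",
            "result is an empty mask")
  mask_grid(out, spacing = mask$spacing, origin = mask$origin)
}

#' Remove sub-zero-HU voxels from a mask
#'
#' Drops mask voxels whose volume intensity is strictly below 0 HU. On
#' abdominal CT this removes fat (approx. -100 HU) that segmentation left
#' inside the ROI border. The threshold is meaningful only on calibrated
#' Hounsfield units, so the volume must not have been windowed or rescaled
#' yet; voxels at exactly 0 HU are retained.
#'
#' @param mask a [mask_grid()] aligned with `volume`.
#' @param volume a [volume_grid()] with `intensity_kind == "HU"`.
#' @return The edited [mask_grid()].
#' @export
remove_subzero_voxels <- function(mask, volume) {
  stopifnot(inherits(mask, "mask_grid"), inherits(volume, "volume_grid"))
  if (volume$intensity_kind != "HU")
    stop("remove_subzero_voxels requires HU intensities; volume is ",
         volume$intensity_kind, call. = FALSE)
  check_aligned(volume, mask)
  out <- mask$labels
  out[volume$data < 0] <- 0L
  if (sum(mask$labels > 0L) > 0L && all(out == 0L))
    warning("remove_subzero_voxels: all ROI voxels were below 0 HU; ",
            "mask is now empty", call. = FALSE)
  mask_grid(out, spacing = mask$spacing, origin = mask$origin)
}

#' Windowing / intensity-rescale parameters
#'
#' @param level window center in HU (soft tissue default: 50).
#' @param width window width in HU (> 0; soft tissue default: 500).
#' @param out_min,out_max output range of the affine rescale (default 0-255).
#' @return A `window_params` list.
#' @export
window_params <- function(level = 50, width = 500, out_min = 0, out_max = 255) {
  if (width <= 0) stop("window width must be > 0", call. = FALSE)
  if (out_max <= out_min) stop("out_max must exceed out_min", call. = FALSE)
  structure(list(level = level, width = width,
                 out_min = out_min, out_max = out_max),
            class = "window_params")
}

#' Apply a CT intensity window and/or rescale
#'
#' With `clip = TRUE` intensities are limited to the window range
#' `[level - width/2, level + width/2]` (the soft-tissue default gives
#' `[-200, 300]` HU). With `rescale = TRUE` an affine map sends `[lo, hi]`
#' onto `[out_min, out_max]`, where `[lo, hi]` is the window range if
#' clipping was applied and the volume's own min/max otherwise. No integer
#' rounding is applied (an optional 8-bit quantization is available via
#' `round_to_int`, default off, since reference behaviour is continuous).
#'
#' @param volume a [volume_grid()] with `intensity_kind == "HU"`.
#' @param params a [window_params()].
#' @param clip limit intensities to the window range.
#' @param rescale affinely map onto `[out_min, out_max]`.
#' @param round_to_int round rescaled intensities to whole numbers.
#' @return A [volume_grid()] with `intensity_kind` `"rescaled"` if rescaled,
#'   `"windowed_HU"` if only clipped, unchanged if neither flag is set.
#' @export
apply_window <- function(volume, params = window_params(), clip = TRUE,
                         rescale = TRUE, round_to_int = FALSE) {
  stopifnot(inherits(volume, "volume_grid"))
  if (volume$intensity_kind != "HU")
    stop("apply_window requires HU intensities; volume is ",
         volume$intensity_kind, call. = FALSE)
  x <- volume$data
  kind <- volume$intensity_kind
  lo <- params$level - params$width / 2
  hi <- params$level + params$width / 2
  if (clip) {
    x <- pmin(pmax(x, lo), hi)
    kind <- "windowed_HU"
  }
  if (rescale) {
    if (!clip) {
      lo <- min(x)
      hi <- max(x)
    }
    if (hi == lo)
      stop("degenerate intensity range: lo == hi == ", lo, call. = FALSE)
    x <- (x - lo) / (hi - lo) * (params$out_max - params$out_min) + params$out_min
    if (round_to_int) x <- round(x)
    kind <- "rescaled"
  }
  dim(x) <- dim(volume$data)
  volume_grid(x, spacing = volume$spacing, origin = volume$origin,
              intensity_kind = kind)
}

#' Spatial resampling parameters
#'
#' @param target_spacing length-3 positive spacing in mm (default 1 mm
#'   isotropic).
#' @param interpolator `"trilinear"`, `"bspline3"` (interpolating cubic
#'   B-spline with recursive prefilter) or `"nearest"`.
#' @param implementation `"native"` uses corner-aligned grid placement (the
#'   centers of voxel (0,0,0) coincide before and after); `"alt"` uses
#'   center-aligned placement (volume centers coincide). The two conventions
#'   are both legitimate and deliberately give different sampled values,
#'   modelling the discrepancies observed between resampling libraries.
#' @return A `resample_params` list.
#' @export
resample_params <- function(target_spacing = c(1, 1, 1),
                            interpolator = c("trilinear", "bspline3", "nearest"),
                            implementation = c("native", "alt")) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be three strictly positive numbers", call. = FALSE)
  structure(list(target_spacing = target_spacing,
                 interpolator = match.arg(interpolator),
                 implementation = match.arg(implementation)),
            class = "resample_params")
}

#' Resample a volume onto a new voxel grid
#'
#' Output dimensions are `ceiling(dim_in * spacing_in / spacing_out)` per
#' axis. Samples outside the input support take the nearest-edge value
#' (clamp-to-edge). Trilinear interpolation is exact on globally affine
#' intensity fields; `bspline3` is an interpolating cubic B-spline (recursive
#' prefilter, mirror boundary).
#'
#' @param volume a [volume_grid()].
#' @param params a [resample_params()]; `interpolator` must be `"trilinear"`
#'   or `"bspline3"`.
#' @return The resampled [volume_grid()] (same `intensity_kind`).
#' @export
resample_volume <- function(volume, params = resample_params()) {
  stopifnot(inherits(volume, "volume_grid"))
  if (!params$interpolator %in% c("trilinear", "bspline3"))
    stop("volume resampling supports trilinear or bspline3 interpolation",
         call. = FALSE)
  geo <- resample_geometry(dim(volume$data), volume$spacing, params)
  dat <- if (params$interpolator == "trilinear") {
    interp_trilinear(volume$data, geo$coords)
  } else {
    interp_bspline3(volume$data, geo$coords)
  }
  volume_grid(dat, spacing = params$target_spacing,
              origin = volume$origin + geo$origin_shift,
              intensity_kind = volume$intensity_kind)
}

#' Resample a mask onto a new voxel grid
#'
#' Uses nearest-neighbour interpolation regardless of `params$interpolator`,
#' so output labels are a subset of the input labels (plus background). The
#' output grid is identical to [resample_volume()] under the same parameters.
#'
#' @param mask a [mask_grid()].
#' @param params a [resample_params()].
#' @return The resampled [mask_grid()].
#' @export
resample_mask <- function(mask, params = resample_params()) {
  stopifnot(inherits(mask, "mask_grid"))
  geo <- resample_geometry(dim(mask$labels), mask$spacing, params)
  idx <- lapply(1:3, function(a) {
    pmin(pmax(round(geo$coords[[a]]), 0), dim(mask$labels)[a] - 1L) + 1L
  })
  dat <- mask$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  mask_grid(dat, spacing = params$target_spacing,
            origin = mask$origin + geo$origin_shift)
}

# Continuous source index coordinates (0-based, unclamped) of the output
# voxel centers, one vector per axis, plus the origin shift of the new grid.
resample_geometry <- function(dims_in, spacing_in, params) {
  t <- params$target_spacing
  dims_out <- pmax(as.integer(ceiling(dims_in * spacing_in / t)), 1L)
  coords <- vector("list", 3L)
  shift <- numeric(3L)
  for (a in 1:3) {
    i <- seq_len(dims_out[a]) - 1
    r <- t[a] / spacing_in[a]
    if (params$implementation == "native") {
      coords[[a]] <- i * r
      shift[a] <- 0
    } else {
      coords[[a]] <- (i - (dims_out[a] - 1) / 2) * r + (dims_in[a] - 1) / 2
      shift[a] <- (dims_in[a] - 1) / 2 * spacing_in[a] -
        (dims_out[a] - 1) / 2 * t[a]
    }
  }
  list(dims_out = dims_out, coords = coords, origin_shift = shift)
}

# separable gather: vol[ix, iy, iz] with per-axis index vectors produces the
# full output grid, so an n-tap kernel costs n^3 clamped gathers. Nested
# lerp form (a + t*(b - a)) keeps constants bit-exact.
interp_trilinear <- function(vol, coords) {
  d <- dim(vol)
  i0 <- f <- i1 <- vector("list", 3L)
  for (a in 1:3) {
    x <- pmin(pmax(coords[[a]], 0), d[a] - 1L)  # clamp-to-edge
    lo <- floor(x)
    f[[a]] <- x - lo
    i0[[a]] <- as.integer(lo) + 1L
    i1[[a]] <- pmin(i0[[a]] + 1L, d[a])
  }
  n_out <- lengths(i0)
  corner <- function(cx, cy, cz) {
    vol[if (cx == 0) i0[[1]] else i1[[1]],
        if (cy == 0) i0[[2]] else i1[[2]],
        if (cz == 0) i0[[3]] else i1[[3]], drop = FALSE]
  }
  fx <- f[[1]]                               # recycles along dim 1
  fy <- rep(f[[2]], each = n_out[1])         # recycles along dims 1:2
  fz <- rep(f[[3]], each = n_out[1] * n_out[2])
  lerp <- function(a, b, t) a + t * (b - a)
  c00 <- lerp(corner(0, 0, 0), corner(1, 0, 0), fx)
  c10 <- lerp(corner(0, 1, 0), corner(1, 1, 0), fx)
  c01 <- lerp(corner(0, 0, 1), corner(1, 0, 1), fx)
  c11 <- lerp(corner(0, 1, 1), corner(1, 1, 1), fx)
  out <- lerp(lerp(c00, c10, fy), lerp(c01, c11, fy), fz)
  dim(out) <- n_out
  out
}

interp_bspline3 <- function(vol, coords) {
  coef <- bspline_prefilter(vol)
  d <- dim(vol)
  idx <- w <- vector("list", 3L)
  for (a in 1:3) {
    x <- pmin(pmax(coords[[a]], 0), d[a] - 1L)
    lo <- floor(x)
    t <- x - lo
    # cubic B-spline basis at offsets -1, 0, 1, 2 from floor(x)
    w[[a]] <- list((1 - t)^3 / 6,
                   (3 * t^3 - 6 * t^2 + 4) / 6,
                   (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
                   t^3 / 6)
    idx[[a]] <- lapply(-1:2, function(o) {
      i <- as.integer(lo) + o
      # mirror taps at the boundary, matching the prefilter's boundary model
      i <- ifelse(i < 0L, -i, i)
      i <- ifelse(i > d[a] - 1L, 2L * (d[a] - 1L) - i, i)
      pmin(pmax(i, 0L), d[a] - 1L) + 1L
    })
  }
  out <- 0
  for (cx in 1:4) for (cy in 1:4) for (cz in 1:4) {
    wt <- outer(outer(w[[1]][[cx]], w[[2]][[cy]]), w[[3]][[cz]])
    out <- out + wt * coef[idx[[1]][[cx]], idx[[2]][[cy]], idx[[3]][[cz]],
                           drop = FALSE]
  }
  out
}

# Recursive interpolating-spline prefilter (pole sqrt(3) - 2), applied along
# each axis with mirror boundary, so that B-spline reconstruction
# interpolates the original samples.
bspline_prefilter <- function(vol) {
  d <- dim(vol)
  out <- vol
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    m <- aperm(out, perm)
    dm <- dim(m)
    dim(m) <- c(dm[1], dm[2] * dm[3])
    m <- bspline_filter_cols(m)
    dim(m) <- dm
    out <- aperm(m, order(perm))
  }
  out
}

bspline_filter_cols <- function(m) {
  z <- sqrt(3) - 2
  n <- nrow(m)
  if (n == 1L) return(m)
  lambda <- 6
  m <- m * lambda
  # causal init: geometric sum over the mirror-extended signal
  horizon <- ceiling(log(1e-14) / log(abs(z)))
  k <- seq_len(horizon) - 1L
  period <- 2L * n - 2L
  mir <- abs(((k + n - 1L) %% period) - (n - 1L)) + 1L  # mirror w/o repeat
  zp <- z^k
  cp <- m
  cp[1, ] <- as.numeric(zp %*% m[mir, , drop = FALSE])
  for (i in 2:n) cp[i, ] <- m[i, ] + z * cp[i - 1, ]
  cm <- cp
  cm[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z * (cm[i + 1, ] - cp[i, ])
  cm
}
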