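#' 3-D scalar volume with voxel geometry
#'
#' A `volume_grid` holds a 3-D scalar field together with its voxel spacing
#' (mm), grid origin (mm) and the semantics of its intensities. Voxel indices
#' are 0-based in the geometry convention: the world coordinate of voxel
#' `(i, j, k)` is `origin + (i * sx, j * sy, k * sz)`. Orientation beyond
#' scaling is carried as opaque metadata and never used for resampling.
#'
#' @param data 3-D numeric array.
#' @param spacing numeric length-3, strictly positive voxel spacing in mm.
#' @param origin numeric length-3 world position of voxel (0,0,0), in mm.
#' @param intensity_kind one of `"HU"` (calibrated Hounsfield units),
#'   `"windowed_HU"` (clipped to a window, still HU-scaled) or `"rescaled"`
#'   (affinely mapped to an arbitrary output range, dimensionless).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        intensity_kind = "HU") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3-D volume: `data` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers", call. = FALSE)
  intensity_kind <- match.arg(intensity_kind, c("HU", "windowed_HU", "rescaled"))
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin,
                 intensity_kind = intensity_kind),
            class = "volume_grid")
}

#' 3-D integer label mask on a voxel grid
#'
#' Labels are non-negative integers; 0 is background. When paired with a
#' [volume_grid()] the two must share shape, spacing and origin.
#'
#' @param labels 3-D array of non-negative integers.
#' @param spacing,origin as in [volume_grid()].
#' @return An object of class `mask_grid`.
#' @export
mask_grid <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("not a 3-D volume: `labels` must be a 3-D array", call. = FALSE)
  if (anyNA(labels)) stop("mask labels contain missing values", call. = FALSE)
  if (any(labels != round(labels)))
    stop("mask labels must be integers", call. = FALSE)
  if (any(labels < 0)) stop("mask labels must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "mask_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, spacing %s mm, %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$intensity_kind))
  invisible(x)
}

#' @export
print.mask_grid <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("<mask_grid> %s voxels, labels {%s}, %d foreground voxels\n",
              paste(dim(x$labels), collapse = "x"),
              paste(labs, collapse = ","), sum(x$labels > 0L)))
  invisible(x)
}

# shared grid-compatibility check (shape, spacing, origin)
check_aligned <- function(volume, mask, tol = 1e-6) {
  if (!identical(dim(volume$data), dim(mask$labels)))
    stop("grids misaligned: volume and mask shapes differ", call. = FALSE)
  if (max(abs(volume$spacing - mask$spacing)) > tol ||
      max(abs(volume$origin - mask$origin)) > tol)
    stop("grids misaligned: volume and mask geometry differs", call. = FALSE)
  invisible(TRUE)
}
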