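#' Feature extraction configuration
#'
#' @param families subset of `"first_order"`, `"shape"`, `"glcm"`,
#'   `"glrlm"`, `"glszm"` to compute.
#' @param bin_width fixed bin width for intensity discretization (default
#'   25, matching a 0-255 rescaled soft-tissue window).
#' @param dialect discretization dialect, see [discretize()].
#' @param distance texture offset distance in voxels.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(families = c("first_order", "shape", "glcm",
                                           "glrlm", "glszm"),
                              bin_width = 25, dialect = "ibsi", distance = 1) {
  families <- match.arg(families, several.ok = TRUE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  structure(list(families = families, bin_width = bin_width,
                 dialect = match.arg(dialect, c("ibsi", "edge_variant")),
                 distance = as.integer(distance)),
            class = "extraction_config")
}

#' Extract a radiomics feature row
#'
#' Orchestrates discretization (range anchored at the ROI minimum) and the
#' enabled feature families over the binary ROI (`labels > 0`). Output is
#' deterministic: the same volume, mask and configuration give a
#' bit-identical row. The configuration hash is attached as the
#' `config_hash` attribute for provenance.
#'
#' The grids are cropped to the ROI bounding box before texture analysis;
#' this does not change any feature value because co-occurrences, runs and
#' zones are confined to the ROI.
#'
#' @param volume a [volume_grid()].
#' @param mask an aligned [mask_grid()]; non-empty ROI required.
#' @param config an [extraction_config()].
#' @return Named numeric vector with names `family.feature` (e.g.
#'   `first_order.mean`, `glcm.contrast`).
#' @export
extract_features <- function(volume, mask, config = extraction_config()) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "mask_grid"))
  check_aligned(volume, mask)
  roi <- mask$labels > 0L
  if (!any(roi)) stop("empty ROI", call. = FALSE)

  cropped <- crop_to_roi(volume, mask)
  volume <- cropped$volume
  mask <- cropped$mask
  roi <- mask$labels > 0L

  v <- volume$data[roi]
  binned_vals <- discretize(v, bin_width = config$bin_width,
                            dialect = config$dialect)
  bins <- array(0L, dim = dim(volume$data))
  bins[roi] <- binned_vals
  tcfg <- texture_config(distance = config$distance)

  out <- numeric(0)
  if ("first_order" %in% config$families)
    out <- c(out, prefixed(first_order_values(v, binned_vals), "first_order"))
  if ("shape" %in% config$families)
    out <- c(out, prefixed(shape_features(mask), "shape"))
  if ("glcm" %in% config$families)
    out <- c(out, prefixed(glcm_features(bins, tcfg), "glcm"))
  if ("glrlm" %in% config$families)
    out <- c(out, prefixed(glrlm_features(bins, tcfg), "glrlm"))
  if ("glszm" %in% config$families)
    out <- c(out, prefixed(glszm_features(bins, tcfg), "glszm"))
  attr(out, "config_hash") <- hash_object(unclass(config))
  out
}

prefixed <- function(x, prefix) {
  names(x) <- paste0(prefix, ".", names(x))
  x
}

# crop volume+mask to the ROI bounding box padded by one voxel; preserves
# every ROI-confined feature while shrinking texture scans
crop_to_roi <- function(volume, mask) {
  roi <- mask$labels > 0L
  d <- dim(roi)
  rng <- lapply(1:3, function(a) {
    pres <- which(apply(roi, a, any))
    max(min(pres) - 1L, 1L):min(max(pres) + 1L, d[a])
  })
  vol2 <- volume_grid(volume$data[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
                      spacing = volume$spacing,
                      origin = volume$origin +
                        (vapply(rng, min, numeric(1)) - 1) * volume$spacing,
                      intensity_kind = volume$intensity_kind)
  mk2 <- mask_grid(mask$labels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
                   spacing = mask$spacing, origin = vol2$origin)
  list(volume = vol2, mask = mk2)
}
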