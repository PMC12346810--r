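#' Texture matrix configuration
#'
#' @param distance voxel offset distance for co-occurrence and run
#'   directions (default 1).
#' @return A `texture_config` list carrying the distance and the 13 unique
#'   3-D direction offsets.
#' @export
texture_config <- function(distance = 1) {
  distance <- as.integer(distance)
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  structure(list(distance = distance, directions = texture_directions()),
            class = "texture_config")
}

# the 13 unique 3-D directions (the other 13 are their negations and are
# covered by matrix symmetry / run equivalence)
texture_directions <- function() {
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0),
             c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(m) <- "integer"
  m
}

# bins array with 0 outside ROI, from a volume/mask pair + discretization
binned_roi_array <- function(volume, mask, bin_width = 25, dialect = "ibsi") {
  check_aligned(volume, mask)
  roi <- mask$labels > 0L
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  v <- volume$data[roi]
  bins <- array(0L, dim = dim(volume$data))
  bins[roi] <- discretize(v, bin_width = bin_width, dialect = dialect)
  bins
}

#' Gray-level co-occurrence matrix features
#'
#' Builds, for each of the 13 unique 3-D directions, the symmetric
#' co-occurrence matrix of in-ROI voxel pairs at the configured distance,
#' normalizes it to probabilities, computes the matrix features, and averages
#' them over directions (unweighted; directions with no pairs are skipped).
#' For a degenerate matrix with zero marginal variance the correlation is
#' defined as 1.
#'
#' @param binned 3-D integer array of bin indices, 0 outside the ROI (see
#'   [discretize()]), or the output of `binned_roi_array`.
#' @param config a [texture_config()].
#' @return Named numeric vector: `joint_energy`, `joint_entropy`,
#'   `contrast`, `correlation`, `idm` (inverse difference moment),
#'   `cluster_tendency`.
#' @export
glcm_features <- function(binned, config = texture_config()) {
  ngray <- max(binned)
  if (ngray < 1L) stop("empty ROI", call. = FALSE)
  offs <- config$directions * config$distance
  counts <- cpp_glcm_counts(as.integer(binned), dim(binned), offs, ngray)
  per_dir <- lapply(seq_len(dim(counts)[3]), function(o) {
    glcm_features_one(matrix(counts[, , o], nrow = ngray))
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  if (length(per_dir) == 0L)
    stop("no co-occurrences: ROI has no voxel pairs in any direction",
         call. = FALSE)
  rowMeans(do.call(cbind, per_dir))
}

# features of one symmetric count matrix; NULL when it holds no pairs
glcm_features_one <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(NULL)
  p <- counts / total
  ngray <- nrow(p)
  i <- matrix(seq_len(ngray), ngray, ngray)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum(seq_len(ngray) * px)
  var_x <- sum((seq_len(ngray) - mu_x)^2 * px)
  nz <- p > 0
  corr <- if (var_x > 0) {
    (sum(i * j * p) - mu_x^2) / var_x  # symmetric: mu_x = mu_y, var_x = var_y
  } else 1
  c(joint_energy = sum(p^2),
    joint_entropy = -sum(p[nz] * log2(p[nz])),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    idm = sum(p / (1 + (i - j)^2)),
    cluster_tendency = sum((i + j - 2 * mu_x)^2 * p))
}

#' Gray-level run-length matrix features
#'
#' Counts maximal runs of equal bin index within the ROI along each of the
#' 13 directions, computes the run-length features per direction, and
#' averages them (unweighted).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector: `sre` (short-run emphasis), `lre` (long-run
#'   emphasis), `gln` (gray-level non-uniformity), `rln` (run-length
#'   non-uniformity), `run_pct`, `lglre`, `hglre` (low/high gray-level run
#'   emphasis).
#' @export
glrlm_features <- function(binned, config = texture_config()) {
  ngray <- max(binned)
  if (ngray < 1L) stop("empty ROI", call. = FALSE)
  n_vox <- sum(binned > 0L)
  offs <- config$directions * config$distance
  counts <- cpp_glrlm_counts(as.integer(binned), dim(binned), offs, ngray)
  per_dir <- lapply(seq_len(dim(counts)[3]), function(o) {
    glrlm_features_one(matrix(counts[, , o], nrow = ngray), n_vox)
  })
  rowMeans(do.call(cbind, per_dir))
}

glrlm_features_one <- function(counts, n_vox) {
  nr <- sum(counts)
  g <- seq_len(nrow(counts))
  l <- seq_len(ncol(counts))
  rg <- rowSums(counts)
  rl <- colSums(counts)
  c(sre = sum(t(counts) / l^2) / nr,
    lre = sum(t(counts) * l^2) / nr,
    gln = sum(rg^2) / nr,
    rln = sum(rl^2) / nr,
    run_pct = nr / n_vox,
    lglre = sum(rg / g^2) / nr,
    hglre = sum(rg * g^2) / nr)
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal bin index within the ROI; the
#' size-zone matrix counts zones by gray level and size. Unlike the GLCM and
#' GLRLM there is a single matrix, not one per direction.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector: `sae` (small-area emphasis), `lae`
#'   (large-area emphasis), `zone_pct`, `gln`, `szn` (size-zone
#'   non-uniformity).
#' @export
glszm_features <- function(binned, config = texture_config()) {
  ngray <- max(binned)
  if (ngray < 1L) stop("empty ROI", call. = FALSE)
  zones <- cpp_label_zones26(as.integer(binned), dim(binned))
  nz_ids <- zones[zones > 0L]
  sizes <- tabulate(nz_ids)
  gl <- binned[match(seq_along(sizes), zones)]
  n_vox <- length(nz_ids)
  n_zones <- length(sizes)
  zg <- vapply(split(rep(1, n_zones), factor(gl, levels = seq_len(ngray))),
               sum, numeric(1))
  zs <- tabulate(sizes)
  s <- seq_along(zs)
  c(sae = sum(zs / s^2) / n_zones,
    lae = sum(zs * s^2) / n_zones,
    zone_pct = n_zones / n_vox,
    gln = sum(zg^2) / n_zones,
    szn = sum(zs^2) / n_zones)
}
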