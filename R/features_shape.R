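#' Shape features of a binary region of interest
#'
#' Geometric descriptors of the ROI (`labels > 0`) in physical units:
#'
#' * `volume_mm3`: voxel-count volume, `N * prod(spacing)`.
#' * `surface_mm2`: face-count surface area — every voxel face exposed to
#'   background (or the grid boundary) contributes its physical face area.
#'   This differs from mesh-based surface definitions, which smooth the
#'   voxel staircase; the face-count value is exactly reproducible.
#' * `sphericity`: `pi^(1/3) * (6V)^(2/3) / A`, 1 for a perfect sphere and
#'   smaller for rougher or elongated shapes (face counting overestimates A,
#'   so voxelized spheres stay well below 1).
#' * `max_diameter_mm`: exact maximum pairwise Euclidean distance between
#'   the centers of surface voxels.
#' * `elongation`, `flatness`: `sqrt(lambda2/lambda1)` and
#'   `sqrt(lambda3/lambda1)` of the principal-axis second moments
#'   (population covariance of voxel center coordinates, mm).
#'
#' @param mask a [mask_grid()] with non-empty ROI.
#' @return Named numeric vector of the six descriptors.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "mask_grid"))
  roi <- mask$labels > 0L
  n <- sum(roi)
  if (n == 0L) stop("empty ROI", call. = FALSE)
  sp <- mask$spacing
  d <- dim(roi)
  vol <- n * prod(sp)

  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- roi
  exposed_any <- array(FALSE, dim = d)
  surf <- 0
  shifts <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L), c(0L, -1L, 0L),
                 c(0L, 0L, 1L), c(0L, 0L, -1L))
  for (s in shifts) {
    nb <- pad[2:(d[1] + 1L) + s[1], 2:(d[2] + 1L) + s[2], 2:(d[3] + 1L) + s[3],
              drop = FALSE]
    ex <- roi & !nb
    surf <- surf + sum(ex) * face_area[which(s != 0L)]
    exposed_any <- exposed_any | ex
  }

  sphericity <- (pi^(1 / 3) * (6 * vol)^(2 / 3)) / surf

  idx <- which(roi, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, `*`)
  surf_pts <- sweep(which(exposed_any, arr.ind = TRUE) - 1, 2, sp, `*`)
  maxdiam <- cpp_max_pairwise_dist(as.matrix(surf_pts))

  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  cov <- crossprod(cen) / n
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  c(volume_mm3 = vol,
    surface_mm2 = surf,
    sphericity = sphericity,
    max_diameter_mm = maxdiam,
    elongation = elong,
    flatness = flat)
}
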