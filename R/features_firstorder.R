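#' First-order intensity statistics of a region of interest
#'
#' Computes the standard first-order radiomics statistics over the voxels
#' where `mask > 0`. Conventions: variance, skewness and kurtosis use
#' population moments (N denominator); kurtosis is reported non-excess
#' (Pearson; a normal distribution scores 3); entropy is computed in bits
#' (base 2) on fixed-bin-width discretized intensities; percentiles use R's
#' default quantile definition (type 7); robust mean absolute deviation is
#' the mean absolute deviation from the mean of the values lying within the
#' 10th-90th percentile range.
#'
#' @param volume a [volume_grid()].
#' @param mask an aligned [mask_grid()]; the ROI is `labels > 0`.
#' @param bin_width bin width for the entropy discretization.
#' @param dialect discretization dialect, see [discretize()].
#' @return Named numeric vector (`mean`, `variance`, `skewness`, `kurtosis`,
#'   `min`, `max`, `median`, `p10`, `p90`, `iqr`, `energy`, `entropy`,
#'   `robust_mad`).
#' @export
first_order <- function(volume, mask, bin_width = 25, dialect = "ibsi") {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "mask_grid"))
  check_aligned(volume, mask)
  v <- volume$data[mask$labels > 0L]
  if (length(v) == 0L) stop("empty ROI", call. = FALSE)
  binned <- discretize(v, bin_width = bin_width, dialect = dialect)
  first_order_values(v, binned)
}

# core on raw ROI values + their bin indices (used by extract_features so the
# same discretization feeds entropy and the texture families)
first_order_values <- function(v, binned) {
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 else 0
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inband <- v[v >= q[1] & v <= q[5]]
  rmad <- mean(abs(inband - mean(inband)))
  p <- tabulate(binned) / n
  p <- p[p > 0]
  c(mean = m,
    variance = m2,
    skewness = skew,
    kurtosis = kurt,
    min = min(v),
    max = max(v),
    median = q[3],
    p10 = q[1],
    p90 = q[5],
    iqr = q[4] - q[2],
    energy = sum(v^2),
    entropy = -sum(p * log2(p)),
    robust_mad = rmad)
}
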