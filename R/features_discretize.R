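#' Fixed-bin-width intensity discretization
#'
#' Maps continuous intensities to positive integer bin indices using bins of
#' constant width anchored at `range_min` (by default the ROI minimum, set by
#' the caller). Two dialects are provided:
#'
#' * `"ibsi"`: `bin(x) = floor((x - range_min) / bin_width) + 1`, clamped so
#'   that a maximum lying exactly on the top edge of the highest populated
#'   bin falls into that bin instead of opening an empty overflow bin; the
#'   number of bins is `max(ceiling((max - min) / bin_width), 1)`.
#' * `"edge_variant"`: assignment by explicit right-exclusive edges
#'   `e_k = range_min + k * bin_width`, with the maximum kept in the bin its
#'   edge opens (plain floor rule, no top clamp). This reproduces the
#'   behaviour of generic histogram/binning utilities.
#'
#' The dialects can differ only for values lying exactly on a bin edge.
#'
#' @param values non-empty numeric vector.
#' @param bin_width positive bin width in intensity units (default 25).
#' @param dialect `"ibsi"` or `"edge_variant"`.
#' @param range_min left edge of the first bin; must not exceed `min(values)`.
#' @return Integer vector of bin indices (>= 1).
#' @export
discretize <- function(values, bin_width = 25,
                       dialect = c("ibsi", "edge_variant"),
                       range_min = min(values)) {
  dialect <- match.arg(dialect)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  if (range_min > min(values))
    stop("range_min exceeds the smallest value", call. = FALSE)
  raw <- floor((values - range_min) / bin_width) + 1
  if (dialect == "ibsi") {
    nbins <- max(ceiling((max(values) - range_min) / bin_width), 1)
    raw <- pmin(raw, nbins)
  }
  as.integer(raw)
}
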