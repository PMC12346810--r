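#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (optionally gzip-compressed) into a [volume_grid()].
#' Spacing is taken from `pixdim`, the origin from the qform/sform
#' translation. Axis order follows the file: array index `(i, j, k)` (1-based
#' in R) maps to header dimensions 1, 2, 3. Intensities are read as doubles;
#' integer-valued inputs stay integer-valued.
#'
#' The intensity semantics (`HU`, `windowed_HU`, `rescaled`) are recovered
#' from the header `descrip` field when the file was written by
#' [write_volume()]; otherwise `intensity_kind` is used.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param intensity_kind fallback intensity semantics for files without a
#'   recognizable `descrip` tag.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, intensity_kind = "HU") {
  img <- read_nifti_raw(path)
  kind <- kind_from_descrip(img, intensity_kind)
  volume_grid(img$data, spacing = img$spacing, origin = img$origin,
              intensity_kind = kind)
}

#' Write a volume to NIfTI
#'
#' Intensities are stored as 64-bit floats, so `read_volume(write_volume(v))`
#' reproduces the data bit-exactly. Spacing and origin are stored in the
#' NIfTI-1 header (32-bit floats, so geometry round-trips to single
#' precision). The intensity kind is recorded in the `descrip` field.
#'
#' @param volume a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  write_nifti_raw(volume$data, volume$spacing, volume$origin, path,
                  datatype = "double",
                  descrip = paste0("radpipe:", volume$intensity_kind))
  invisible(path)
}

#' Read a NIfTI label mask
#'
#' As [read_volume()] but values are validated as non-negative integers and
#' stored as an integer array.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [mask_grid()].
#' @export
read_mask <- function(path) {
  img <- read_nifti_raw(path)
  if (any(img$data != round(img$data)))
    stop("mask contains non-integer voxel values: ", path, call. = FALSE)
  if (any(img$data < 0))
    stop("mask contains negative labels: ", path, call. = FALSE)
  mask_grid(img$data, spacing = img$spacing, origin = img$origin)
}

#' Write a label mask to NIfTI
#'
#' @param mask a [mask_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_grid"))
  write_nifti_raw(mask$labels, mask$spacing, mask$origin, path,
                  datatype = "int32", descrip = "radpipe:mask")
  invisible(path)
}

# -- low-level helpers ------------------------------------------------------

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("not a 3-D volume: ", path, " has ", length(d), " dimensions",
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3L)]
  if (any(spacing <= 0))
    stop("non-positive voxel spacing in ", path, call. = FALSE)
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  dat <- as.array(img)
  attributes(dat) <- list(dim = d)
  list(data = dat, spacing = as.numeric(spacing), origin = origin, image = img)
}

write_nifti_raw <- function(data, spacing, origin, path, datatype, descrip) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::qform(img) <- structure(m, code = 2L)
  img$descrip <- descrip
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

kind_from_descrip <- function(img, fallback) {
  descrip <- tryCatch(RNifti::niftiHeader(img$image)$descrip,
                      error = function(e) "")
  kinds <- c("HU", "windowed_HU", "rescaled")
  tag <- sub("^radpipe:", "", descrip)
  if (nzchar(descrip) && startsWith(descrip, "radpipe:") && tag %in% kinds)
    tag
  else
    match.arg(fallback, kinds)
}
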