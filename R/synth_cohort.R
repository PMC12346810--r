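#' Synthetic CT phantom cohort parameters
#'
#' Defines the study conditions for the digital phantom cohort: an
#' ellipsoidal soft-tissue "organ" with Gaussian texture on an anisotropic
#' grid, hyper-enhancing spherical lesions in case subjects, a rim of
#' sub-zero-HU fat deliberately left inside the mask border (so fat removal
#' is non-trivial), a thin fluid duct and a bright vascular structure (so
#' label merging is non-trivial), and a two-level "reconstruction kernel"
#' batch effect realized in image space as differing smoothing and noise.
#'
#' @param n_train,n_test subject counts per split.
#' @param case_fraction fraction of case subjects in each split.
#' @param grid_dims voxel grid dimensions (default 48^3).
#' @param spacing anisotropic voxel spacing in mm (default 0.7 x 0.7 x 3.0,
#'   typical axial CT).
#' @param organ_semiaxes_mm ellipsoid semi-axes of the organ, mm.
#' @param organ_hu_mean,organ_hu_sd organ tissue HU mean and texture SD.
#' @param organ_mean_jitter_sd between-subject SD of the organ mean (HU).
#' @param lesion_hu_shift lesion HU offset over organ tissue (arterial-phase
#'   hyper-enhancement).
#' @param lesion_hu_sd lesion texture SD (coarser than organ tissue).
#' @param lesion_radius_mm lesion sphere radius, mm.
#' @param fat_hu,fat_rim_voxels HU of the intramask fat rim and its
#'   thickness in voxels (0 disables the rim).
#' @param batch_levels two or more kernel labels; the first is the sharp
#'   "iterative" kernel used as the harmonization reference downstream.
#' @param batch_smoothing_sigma_mm named per-level Gaussian smoothing sigma
#'   (mm); levels must differ or there is no batch effect.
#' @param batch_noise_sd named per-level additive noise SD (HU); sharper
#'   kernels carry more noise.
#' @param seed master seed; per-subject seeds are derived by stable hashing.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_train = 20L, n_test = 10L, case_fraction = 0.5,
                          grid_dims = c(48L, 48L, 48L),
                          spacing = c(0.7, 0.7, 3.0),
                          organ_semiaxes_mm = c(11, 11, 30),
                          organ_hu_mean = 80, organ_hu_sd = 15,
                          organ_mean_jitter_sd = 1.5,
                          lesion_hu_shift = 40, lesion_hu_sd = 25,
                          lesion_radius_mm = 8,
                          fat_hu = -100, fat_rim_voxels = 1L,
                          batch_levels = c("iterative", "standard"),
                          batch_smoothing_sigma_mm = c(iterative = 0.4,
                                                       standard = 1.5),
                          batch_noise_sd = c(iterative = 10, standard = 3),
                          seed = 7L) {
  stopifnot(n_train >= 1L, n_test >= 1L,
            case_fraction > 0, case_fraction < 1,
            all(spacing > 0), all(grid_dims >= 8L),
            length(batch_levels) >= 2L)
  if (anyDuplicated(batch_smoothing_sigma_mm[batch_levels]) > 0L ||
      length(unique(batch_smoothing_sigma_mm[batch_levels])) <
        length(batch_levels))
    stop("batch smoothing sigmas must differ across levels ",
         "(otherwise there is no batch effect)", call. = FALSE)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 case_fraction = case_fraction,
                 grid_dims = as.integer(grid_dims), spacing = spacing,
                 organ_semiaxes_mm = organ_semiaxes_mm,
                 organ_hu_mean = organ_hu_mean, organ_hu_sd = organ_hu_sd,
                 organ_mean_jitter_sd = organ_mean_jitter_sd,
                 lesion_hu_shift = lesion_hu_shift,
                 lesion_hu_sd = lesion_hu_sd,
                 lesion_radius_mm = lesion_radius_mm,
                 fat_hu = fat_hu, fat_rim_voxels = as.integer(fat_rim_voxels),
                 batch_levels = batch_levels,
                 batch_smoothing_sigma_mm = batch_smoothing_sigma_mm,
                 batch_noise_sd = batch_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Generate one phantom subject
#'
#' Fully determined by `(params, subject_seed, label, batch)`. Mask labels:
#' 1 organ tissue, 2 lesion (cases only), 3 duct, 4 vessel (the vessel is
#' the structure the reference pipeline excludes when merging labels).
#'
#' @param params a [cohort_params()].
#' @param subject_seed integer seed for this subject.
#' @param label 0 (control) or 1 (case: a lesion is inserted).
#' @param batch one of `params$batch_levels`; selects the kernel's
#'   smoothing/noise.
#' @return List with `volume` ([volume_grid()], HU), `mask`
#'   ([mask_grid()]), `label`, `batch`.
#' @export
generate_phantom <- function(params, subject_seed, label = 0L,
                             batch = params$batch_levels[1]) {
  stopifnot(inherits(params, "cohort_params"))
  if (!batch %in% params$batch_levels)
    stop("unknown batch level: ", batch, call. = FALSE)
  if (params$lesion_radius_mm >= min(params$organ_semiaxes_mm))
    stop("lesion radius exceeds organ extent", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(subject_seed))

  d <- params$grid_dims
  sp <- params$spacing
  ctr <- (d - 1) / 2 * sp
  ax <- axis_coords_mm(d, sp)
  X <- ax[[1]][slice.index(array(0, d), 1)]
  Y <- ax[[2]][slice.index(array(0, d), 2)]
  Z <- ax[[3]][slice.index(array(0, d), 3)]

  # per-subject anatomical variability (about +/-10% per axis) so shape
  # descriptors vary across subjects like real organs do
  semi <- params$organ_semiaxes_mm * stats::runif(3, 0.9, 1.1)
  ell <-((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
    ((Z - ctr[3]) / semi[3])^2
  organ <- ell <= 1
  inner_semi <- pmax(semi - params$fat_rim_voxels * sp, 0.5)
  inner <- ((X - ctr[1]) / inner_semi[1])^2 + ((Y - ctr[2]) / inner_semi[2])^2 +
    ((Z - ctr[3]) / inner_semi[3])^2 <= 1
  fat_rim <- organ & !inner & params$fat_rim_voxels > 0L

  # duct: thin fluid cylinder along the long (z) axis through the center
  duct <- organ & sqrt((X - ctr[1])^2 + (Y - ctr[2])^2) <= 1.5 &
    abs(Z - ctr[3]) <= semi[3] * 0.6
  # vessel: bright cylinder adjacent to (outside) the organ
  vx <- ctr[1] + semi[1] + 3
  vessel <- sqrt((X - vx)^2 + (Y - ctr[2])^2) <= 2 &
    abs(Z - ctr[3]) <= semi[3] * 0.8

  organ_mean <- params$organ_hu_mean +
    stats::rnorm(1, 0, params$organ_mean_jitter_sd)
  n <- prod(d)
  hu <- -80 + stats::rnorm(n, 0, 20)        # fat-like background
  dim(hu) <- d
  hu[organ] <- organ_mean + stats::rnorm(sum(organ), 0, params$organ_hu_sd)
  hu[duct] <- 10 + stats::rnorm(sum(duct), 0, 10)
  hu[vessel] <- 150 + stats::rnorm(sum(vessel), 0, 15)

  lesion <- array(FALSE, d)
  if (label == 1L) {
    margin <- 1 - params$lesion_radius_mm / semi
    u <- stats::runif(3, -0.6, 0.6) * margin
    lc <- ctr + u * semi
    lesion <- organ &
      (X - lc[1])^2 + (Y - lc[2])^2 + (Z - lc[3])^2 <=
        params$lesion_radius_mm^2
    hu[lesion] <- organ_mean + params$lesion_hu_shift +
      stats::rnorm(sum(lesion), 0, params$lesion_hu_sd)
  }

  sig <- params$batch_smoothing_sigma_mm[[batch]]
  hu <- gauss_smooth3(hu, sig, sp)
  hu <- hu + stats::rnorm(n, 0, params$batch_noise_sd[[batch]])

  # fat rim carved after smoothing so sub-zero HU inside the mask is certain
  if (any(fat_rim))
    hu[fat_rim] <- pmin(params$fat_hu + stats::rnorm(sum(fat_rim), 0, 5), -20)

  labels <- array(0L, d)
  labels[organ] <- 1L
  labels[duct] <- 3L
  labels[lesion] <- 2L
  labels[vessel] <- 4L

  list(volume = volume_grid(hu, spacing = sp, intensity_kind = "HU"),
       mask = mask_grid(labels, spacing = sp),
       label = as.integer(label), batch = batch)
}

#' Generate a phantom cohort on disk
#'
#' Writes `<id>_vol.nii` / `<id>_mask.nii` pairs (uncompressed, so
#' regeneration with the same master seed is byte-identical) plus a
#' `covariates.csv` with columns `subject_id`, `batch`, `split`, `label`.
#' Case labels follow a Bresenham spread of `case_fraction` within each
#' split (`round(n * fraction)` cases, documented rounding); batch levels
#' alternate in an ABBA pattern within each split so batch is balanced
#' across splits and not confounded with the label.
#'
#' @param params a [cohort_params()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the covariate `data.frame` and the paths.
#' @export
generate_cohort <- function(params, out_dir) {
  stopifnot(inherits(params, "cohort_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0L)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  n <- params$n_train + params$n_test
  split <- rep(c("train", "test"), c(params$n_train, params$n_test))
  assign_in_split <- function(ns) {
    i <- seq_len(ns)
    lab <- as.integer(floor(i * params$case_fraction) -
                        floor((i - 1) * params$case_fraction))
    bpat <- params$batch_levels[c(1, 2, 2, 1)[(i - 1) %% 4 + 1]]
    list(label = lab, batch = bpat)
  }
  a_tr <- assign_in_split(params$n_train)
  a_te <- assign_in_split(params$n_test)
  cov <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                    batch = c(a_tr$batch, a_te$batch),
                    split = split,
                    label = c(a_tr$label, a_te$label),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ph <- generate_phantom(params, subject_seed = derive_seed(params$seed, i),
                           label = cov$label[i], batch = cov$batch[i])
    write_volume(ph$volume, file.path(out_dir,
                                      paste0(cov$subject_id[i], "_vol.nii")))
    write_mask(ph$mask, file.path(out_dir,
                                  paste0(cov$subject_id[i], "_mask.nii")))
  }
  cov_path <- file.path(out_dir, "covariates.csv")
  utils::write.csv(cov, cov_path, row.names = FALSE, quote = FALSE)
  invisible(list(covariates = cov, covariates_path = cov_path,
                 dir = out_dir, params = params))
}

# stable per-subject seed below 2^31
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 1000003 + index * 7919) %% 2147483629)
}

axis_coords_mm <- function(dims, spacing) {
  lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
}

# separable Gaussian smoothing with edge replication; sigma in mm
gauss_smooth3 <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  for (a in 1:3) {
    sv <- sigma_mm / spacing[a]
    if (sv < 0.05) next
    r <- max(1L, ceiling(3 * sv))
    k <- stats::dnorm(seq(-r, r), sd = sv)
    k <- k / sum(k)
    perm <- c(a, setdiff(1:3, a))
    m <- aperm(arr, perm)
    dm <- dim(m)
    dim(m) <- c(dm[1], dm[2] * dm[3])
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(dm[1], r), , drop = FALSE])
    sm <- stats::filter(mp, k, sides = 2)
    m2 <- as.matrix(sm[(r + 1):(r + dm[1]), , drop = FALSE])
    dim(m2) <- dm
    arr <- aperm(m2, order(perm))
  }
  arr
}
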