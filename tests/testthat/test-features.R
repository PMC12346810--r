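test_that("fixed-bin-width discretization follows both dialect rules", {
  expect_identical(discretize(c(0, 24.9, 25, 255), 25, "ibsi", 0),
                   c(1L, 1L, 2L, 11L))
  expect_identical(discretize(c(7, 7, 7), 25), c(1L, 1L, 1L))
  # top edge: the maximum on a bin edge stays in the highest populated bin
  expect_identical(discretize(c(0, 50), 25, "ibsi", 0), c(1L, 2L))
  expect_identical(discretize(c(0, 50), 25, "edge_variant", 0), c(1L, 3L))
  # dialects agree for values strictly inside bins
  for (seed in 1:25) {
    set.seed(seed)
    w <- stats::runif(1, 0.5, 30)
    x <- stats::runif(50, 0, 300)
    x <- x[abs(x / w - round(x / w)) > 1e-6]
    stopifnot(identical(discretize(x, w, "ibsi", 0),
                        discretize(x, w, "edge_variant", 0)))
  }
  # ibsi bin range respects the ceiling-based bin count
  for (seed in 1:25) {
    set.seed(seed)
    x <- stats::runif(40, -50, 400)
    b <- discretize(x, 25, "ibsi")
    stopifnot(min(b) >= 1,
              max(b) <= max(ceiling((max(x) - min(x)) / 25), 1))
  }
  expect_error(discretize(1:3, 0), "bin_width")
  succeed()
})

test_that("first-order statistics match hand computations", {
  mk <- mask_grid(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)))
  fo <- first_order(volume_grid(array(c(1, 2, 3, 4, 9, 9, 9, 9), c(2, 2, 2))),
                    mk)
  expect_equal(fo[["mean"]], 2.5)
  expect_equal(fo[["variance"]], 1.25)  # population, N denominator
  expect_equal(fo[["energy"]], 30)
  expect_equal(fo[["min"]], 1)
  expect_equal(fo[["max"]], 4)

  # symmetric values have zero skewness
  fo2 <- first_order(volume_grid(array(c(1, 2, 2, 3, 0, 0, 0, 0), c(2, 2, 2))),
                     mk)
  expect_equal(fo2[["skewness"]], 0)

  # constant ROI: zero variance and zero entropy
  foc <- first_order(volume_grid(array(7, c(2, 2, 2))), mk)
  expect_equal(foc[["mean"]], 7)
  expect_equal(foc[["variance"]], 0)
  expect_equal(foc[["entropy"]], 0)

  expect_error(first_order(volume_grid(array(1, c(2, 2, 2))),
                           mask_grid(array(0L, c(2, 2, 2)))), "empty ROI")
})

test_that("shape features match hand geometry", {
  m1 <- array(0L, c(3, 3, 3)); m1[2, 2, 2] <- 1L
  s1 <- shape_features(mask_grid(m1))
  expect_equal(s1[["volume_mm3"]], 1)
  expect_equal(s1[["surface_mm2"]], 6)
  expect_equal(s1[["max_diameter_mm"]], 0)

  m2 <- array(0L, c(4, 4, 4)); m2[2:3, 2:3, 2:3] <- 1L
  s2 <- shape_features(mask_grid(m2))
  expect_equal(s2[["volume_mm3"]], 8)
  expect_equal(s2[["surface_mm2"]], 24)
  expect_equal(s2[["max_diameter_mm"]], sqrt(3))
  expect_equal(s2[["sphericity"]], pi^(1 / 3) * 48^(2 / 3) / 24)
  expect_equal(s2[["elongation"]], 1)  # cube: equal principal moments
  expect_equal(s2[["flatness"]], 1)

  # anisotropic spacing scales the physical measurements
  s3 <- shape_features(mask_grid(m1, spacing = c(0.7, 0.7, 3.0)))
  expect_equal(s3[["volume_mm3"]], 0.7 * 0.7 * 3.0)
  expect_equal(s3[["surface_mm2"]], 2 * (0.7 * 0.7 + 2 * 0.7 * 3.0))
})

test_that("GLCM features match hand counts and the pair-enumeration oracle", {
  # single in-ROI row [1,1,2], one direction: counts {(1,1):2,(1,2):1,(2,1):1}
  bins <- array(0L, c(3, 1, 1)); bins[, 1, 1] <- c(1L, 1L, 2L)
  cnt <- radpipe:::cpp_glcm_counts(as.integer(bins), dim(bins),
                                   matrix(c(1L, 0L, 0L), 1), 2L)
  expect_equal(cnt[, , 1], matrix(c(2, 1, 1, 0), 2))
  expect_equal(radpipe:::glcm_features_one(cnt[, , 1])[["joint_energy"]],
               0.375)

  # constant ROI: degenerate matrix
  fc <- glcm_features(array(1L, c(2, 2, 2)))
  expect_equal(fc[["joint_energy"]], 1)
  expect_equal(fc[["contrast"]], 0)
  expect_equal(fc[["joint_entropy"]], 0)

  expect_error(glcm_features(array(c(1L, rep(0L, 26)), c(3, 3, 3))),
               "no co-occurrences")

  for (seed in 1:40) {
    bins <- random_binned_roi(seed)
    got <- tryCatch(glcm_features(bins), error = function(e) NULL)
    want <- if (!is.null(got)) oracle_glcm_features(bins)
    if (!is.null(got)) stopifnot(max(abs(got - want[names(got)])) < 1e-9)
  }
  succeed()
})

test_that("GLRLM features match hand runs and the run-scanner oracle", {
  bins <- array(0L, c(3, 1, 1)); bins[, 1, 1] <- c(1L, 1L, 2L)
  m <- radpipe:::cpp_glrlm_counts(as.integer(bins), dim(bins),
                                  matrix(c(1L, 0L, 0L), 1), 2L)[, , 1]
  expect_equal(m, matrix(c(0, 1, 1, 0, 0, 0), 2))  # (1,len2), (2,len1)
  expect_equal(radpipe:::glrlm_features_one(matrix(m, 2), 3)[["run_pct"]],
               2 / 3)

  # constant N-voxel line: one run of length N, LRE = N^2
  b5 <- array(0L, c(5, 1, 1)); b5[, 1, 1] <- 1L
  m5 <- radpipe:::cpp_glrlm_counts(as.integer(b5), dim(b5),
                                   matrix(c(1L, 0L, 0L), 1), 1L)[, , 1]
  expect_equal(radpipe:::glrlm_features_one(matrix(m5, 1), 5)[["lre"]], 25)

  for (seed in 41:80) {
    bins <- random_binned_roi(seed)
    got <- glrlm_features(bins)
    want <- oracle_glrlm_features(bins)
    stopifnot(max(abs(got - want[names(got)])) < 1e-9)
  }
  succeed()
})

test_that("GLSZM features match hand zones and the flood-fill oracle", {
  # two disjoint single-voxel zones of the same gray level
  bz <- array(0L, c(5, 1, 1)); bz[c(1, 5), 1, 1] <- 1L
  fz <- glszm_features(bz)
  expect_equal(fz[["zone_pct"]], 1)
  expect_equal(fz[["gln"]], 2)  # both zones share one gray level: 2^2 / 2

  # constant ROI is one zone
  expect_equal(glszm_features(array(1L, c(2, 2, 2)))[["zone_pct"]], 1 / 8)

  for (seed in 81:120) {
    bins <- random_binned_roi(seed)
    got <- glszm_features(bins)
    want <- oracle_glszm_features(bins)
    stopifnot(max(abs(got - want[names(got)])) < 1e-9)
  }
  succeed()
})

test_that("extraction is deterministic, family-selective and shape-invariant to shifts", {
  set.seed(9)
  d <- c(7, 7, 5)
  vol <- volume_grid(array(stats::runif(prod(d), 0, 255), d))
  labs <- array(0L, d); labs[2:6, 2:6, 2:4] <- 1L
  mk <- mask_grid(labs)

  r1 <- extract_features(vol, mk)
  r2 <- extract_features(vol, mk)
  expect_identical(r1, r2)

  sub <- extract_features(vol, mk, extraction_config(families = c("first_order",
                                                                  "glcm")))
  expect_false(any(startsWith(names(sub), "shape.")))
  expect_identical(sub[names(sub)], r1[names(sub)])

  shifted <- volume_grid(vol$data + 10)
  rs <- extract_features(shifted, mk)
  shape_cols <- grep("^shape\\.", names(r1), value = TRUE)
  expect_identical(rs[shape_cols], r1[shape_cols])

  # voxel visit order cannot matter: transposing the grid (and mask with it)
  # permutes voxels but leaves direction-averaged features unchanged
  pv <- volume_grid(aperm(vol$data, c(2, 1, 3)))
  pm <- mask_grid(aperm(labs, c(2, 1, 3)))
  rp <- extract_features(pv, pm)
  expect_equal(rp[names(r1)], r1[names(r1)], tolerance = 1e-12)
})
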