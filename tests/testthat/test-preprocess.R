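test_that("merge_labels pools the requested labels and nothing else", {
  set.seed(2)
  labs <- array(sample(0:4, 6^3, replace = TRUE), c(6, 6, 6))
  m <- mask_grid(labs)
  out <- merge_labels(m, c(1, 2, 4))
  expect_identical(sum(out$labels), sum(labs %in% c(1, 2, 4)))
  expect_true(all(out$labels %in% c(0L, 1L)))

  all_present <- merge_labels(m, 1:4)
  expect_identical(all_present$labels > 0L, labs > 0L)

  expect_message(absent <- merge_labels(m, 9L), "empty mask")
  expect_identical(sum(absent$labels), 0L)
  expect_error(merge_labels(m, c(0, 1)), "background")
  expect_error(merge_labels(m, integer(0)), "non-empty")
})

test_that("sub-zero-HU fat removal is count-exact, idempotent and HU-only", {
  hu <- array(50, c(4, 4, 4))
  hu[1:3, 1, 1] <- -100
  v <- volume_grid(hu)
  labs <- array(0L, c(4, 4, 4))
  labs[1:10] <- 1L  # 10-voxel ROI covering the 3 fat voxels
  m <- mask_grid(labs)
  out <- remove_subzero_voxels(m, v)
  expect_identical(sum(out$labels), 7L)
  expect_identical(remove_subzero_voxels(out, v)$labels, out$labels)

  # exactly 0 HU is retained; no sub-zero voxels leaves the mask unchanged
  v0 <- volume_grid(array(0, c(4, 4, 4)))
  expect_identical(remove_subzero_voxels(m, v0)$labels, m$labels)

  vneg <- volume_grid(array(-50, c(4, 4, 4)))
  expect_warning(empty <- remove_subzero_voxels(m, vneg), "empty")
  expect_identical(sum(empty$labels), 0L)

  expect_error(remove_subzero_voxels(m, apply_window(v)), "HU")
})

test_that("windowing maps boundaries, midpoint and saturation correctly", {
  x <- c(-200, 300, 50, 1000, -500, 0, 175, 49)
  v <- volume_grid(array(x, c(2, 2, 2)))
  w <- apply_window(v)
  expect_equal(w$data[1:4], c(0, 255, 127.5, 255))
  expect_identical(w$intensity_kind, "rescaled")

  # monotone non-decreasing and bounded under clip + rescale
  set.seed(4)
  xs <- sort(stats::runif(64, -1500, 1500))
  ws <- apply_window(volume_grid(array(xs, c(4, 4, 4))))
  expect_true(all(diff(as.vector(ws$data)) >= 0))
  expect_true(all(ws$data >= 0 & ws$data <= 255))

  # clip-only keeps HU scale; rescale-only uses the volume's min/max
  wc <- apply_window(v, clip = TRUE, rescale = FALSE)
  expect_identical(wc$intensity_kind, "windowed_HU")
  expect_equal(range(wc$data), c(-200, 300))
  wr <- apply_window(v, clip = FALSE, rescale = TRUE)
  expect_equal(range(wr$data), c(0, 255))
  expect_equal(wr$data[5], 0)  # volume min -500 maps to 0

  expect_error(apply_window(volume_grid(array(5, c(2, 2, 2))),
                            clip = FALSE, rescale = TRUE), "degenerate")
})

test_that("trilinear resampling is exact on constant and affine fields", {
  vc <- volume_grid(array(100, c(6, 6, 6)), spacing = c(0.7, 0.7, 3.0))
  oc <- resample_volume(vc, resample_params())
  expect_identical(dim(oc$data), c(5L, 5L, 18L))  # ceil(dim * in / out)
  expect_true(all(oc$data == 100))
  expect_equal(oc$spacing, c(1, 1, 1))

  # identity grid reproduces the input exactly
  set.seed(5)
  a <- array(stats::runif(4 * 5 * 6), c(4, 5, 6))
  v <- volume_grid(a, spacing = c(0.7, 0.7, 3.0))
  expect_equal(resample_volume(v, resample_params(c(0.7, 0.7, 3.0)))$data, a,
               tolerance = 1e-12)

  # globally affine field: sampled values equal the analytic ramp
  d <- c(8, 7, 6); sp <- c(0.9, 1.1, 2.0)
  co <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * sp[ax])
  aff <- outer(outer(2 * co[[1]], 3 * co[[2]], "+"), 5 * co[[3]], "+") + 7
  for (impl in c("native", "alt")) {
    prm <- resample_params(c(1, 1, 1), implementation = impl)
    out <- resample_volume(volume_grid(aff, spacing = sp), prm)
    geo <- radpipe:::resample_geometry(d, sp, prm)
    cx <- pmin(pmax(geo$coords[[1]], 0), d[1] - 1) * sp[1]
    cy <- pmin(pmax(geo$coords[[2]], 0), d[2] - 1) * sp[2]
    cz <- pmin(pmax(geo$coords[[3]], 0), d[3] - 1) * sp[3]
    want <- outer(outer(2 * cx, 3 * cy, "+"), 5 * cz, "+") + 7
    expect_equal(out$data, want, tolerance = 1e-6)
  }
  expect_error(resample_params(c(0, 1, 1)), "positive")
})

test_that("cubic B-spline resampling interpolates the original samples", {
  set.seed(6)
  a <- array(stats::runif(5 * 6 * 4), c(5, 6, 4))
  v <- volume_grid(a, spacing = c(1, 2, 1.5))
  same <- resample_volume(v, resample_params(c(1, 2, 1.5),
                                             interpolator = "bspline3"))
  expect_equal(same$data, a, tolerance = 1e-10)
  # and differs from trilinear at off-grid sample points
  p1 <- resample_volume(v, resample_params(c(1, 1, 1)))
  p2 <- resample_volume(v, resample_params(c(1, 1, 1),
                                           interpolator = "bspline3"))
  expect_gt(max(abs(p1$data - p2$data)), 1e-4)
})

test_that("mask resampling is nearest-neighbour, label-closed and volume-preserving", {
  set.seed(7)
  labs <- array(sample(0:3, 6^3, replace = TRUE), c(6, 6, 6))
  m <- mask_grid(labs, spacing = c(0.7, 0.7, 3.0))
  idm <- resample_mask(m, resample_params(c(0.7, 0.7, 3.0)))
  expect_identical(idm$labels, labs)

  out <- resample_mask(m, resample_params(c(1, 1, 1),
                                          interpolator = "bspline3"))
  expect_true(all(out$labels %in% c(0L, sort(unique(as.vector(labs))))))
  # same grid as the volume path under identical params
  ov <- resample_volume(volume_grid(array(0, c(6, 6, 6)),
                                    spacing = c(0.7, 0.7, 3.0)),
                        resample_params(c(1, 1, 1)))
  expect_identical(dim(out$labels), dim(ov$data))

  # sphere volume within 15% at 2x upsampling (brute-force voxel count)
  d <- c(20, 20, 20); ctr <- (d - 1) / 2
  co <- lapply(1:3, function(ax) seq_len(d[ax]) - 1)
  r2 <- outer(outer((co[[1]] - ctr[1])^2, (co[[2]] - ctr[2])^2, "+"),
              (co[[3]] - ctr[3])^2, "+")
  sph <- mask_grid(array(as.integer(r2 <= 49), d))
  up <- resample_mask(sph, resample_params(c(0.5, 0.5, 0.5)))
  expect_lt(abs(sum(up$labels) * 0.125 / sum(sph$labels) - 1), 0.15)
  expect_true(all(up$labels %in% c(0L, 1L)))
})

test_that("stage order matters: resample-then-window differs from window-then-resample", {
  set.seed(8)
  hu <- array(stats::rnorm(16^3, 80, 120), c(16, 16, 16))  # noisy phantom
  v <- volume_grid(hu, spacing = c(0.7, 0.7, 3.0))
  a <- resample_volume(apply_window(v), resample_params())
  b_raw <- resample_volume(v, resample_params())
  b <- apply_window(b_raw)
  expect_gt(max(abs(a$data - b$data)), 1e-6)
})
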