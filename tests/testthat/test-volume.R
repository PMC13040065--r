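# small helper: digital ball mask at given spacing (mm), radius in mm
digital_ball <- function(r_mm, spacing, margin_vox = 4L) {
  n <- 2L * ceiling(r_mm / min(spacing)) + 2L * margin_vox
  ctr <- (n + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(n) - ctr) * spacing[a])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  r2 <= r_mm^2
}

test_that("label volumes validate their inputs", {
  g <- array(0L, c(4, 4, 4))
  g[2, 2, 2] <- 99L
  expect_error(label_volume(g), "unknown label")
  expect_error(label_volume(array(0L, c(4, 4)), 0.6), "3D")
  expect_error(label_volume(array(0L, c(4, 4, 4)), -1), "positive")
  g[2, 2, 2] <- 3L
  v <- label_volume(g, 0.6)
  expect_s3_class(v, "label_volume")
  expect_output(print(v), "label_volume 4x4x4")
})

test_that("structure masks follow the label dictionary", {
  lm <- fb_label_map()
  g <- array(0L, c(6, 6, 6))
  g[2, 2, 2] <- lm[["WM"]]
  g[3, 3, 3] <- lm[["CoP"]]
  g[4, 4, 4] <- lm[["FL"]]
  g[5, 5, 5] <- lm[["TB"]]
  v <- label_volume(g, 0.6)
  expect_equal(sum(fb_mask(v, "TB")), 4)          # every labelled voxel
  expect_equal(sum(fb_mask(v, "CoP")), 2)         # generic CoP + lobe
  expect_equal(sum(fb_mask(v, "WM")), 1)
  expect_equal(sum(fb_mask(v, "FL")), 1)
  expect_error(fb_mask(v, "XX"), "unknown structure")
})

test_that("label volumes round-trip bit-exactly through NIfTI", {
  set.seed(1)
  g <- array(sample(c(0L, 2L, 3L, 12L), 9 * 8 * 7, replace = TRUE), c(9, 8, 7))
  v <- label_volume(g, c(0.6, 0.6, 0.6))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_s3_class(v2, "label_volume")
  expect_identical(v2$grid, v$grid)
  # pixdim is float32 in the NIfTI header
  expect_equal(v2$spacing_mm, v$spacing_mm, tolerance = 1e-6)
})

test_that("intensity volumes keep their anisotropic spacing in NIfTI", {
  set.seed(2)
  g <- array(runif(6 * 5 * 4), c(6, 5, 4))
  v <- intensity_volume(g, c(0.32, 0.51, 0.85))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path, type = "intensity")
  expect_s3_class(v2, "intensity_volume")
  expect_equal(v2$grid, v$grid, tolerance = 1e-12)
  expect_equal(v2$spacing_mm, c(0.32, 0.51, 0.85), tolerance = 1e-6)
})

test_that("resampling a volume already at the target is the identity", {
  g <- array(sample(c(0L, 3L), 5^3, replace = TRUE), c(5, 5, 5))
  v <- label_volume(g, 0.6)
  expect_identical(resample_isotropic(v, 0.6), v)
})

test_that("resampling a ball from 0.3 mm to 0.6 mm preserves its volume", {
  r_mm <- 6
  mask <- digital_ball(r_mm, rep(0.3, 3))
  v <- label_volume(array(3L * mask, dim(mask)), 0.3)
  out <- resample_isotropic(v, 0.6)
  expect_equal(out$spacing_mm, rep(0.6, 3))
  analytic <- 4 / 3 * pi * r_mm^3
  expect_lt(abs(structure_volume(out, "WM") / analytic - 1), 0.02)
})

test_that("anisotropic scans resample to 0.6 iso with preserved extent", {
  sp <- c(0.32, 0.51, 0.85)
  d <- c(40L, 30L, 20L)
  set.seed(3)
  v <- intensity_volume(array(runif(prod(d)), d), sp)
  out <- resample_isotropic(v, 0.6)
  expect_equal(out$spacing_mm, rep(0.6, 3))
  extent_in <- d * sp
  extent_out <- dim(out$grid) * 0.6
  expect_true(all(abs(extent_out - extent_in) <= 0.6 + 1e-9))
  expect_error(resample_isotropic(v, 0), "positive")
})

test_that("trilinear resampling is exact on a linear ramp", {
  d <- c(12L, 10L, 8L)
  sp <- c(0.4, 0.5, 0.8)
  ix <- array(rep(0:(d[1] - 1), times = prod(d[2:3])), d)
  iy <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), d)
  iz <- array(rep(0:(d[3] - 1), each = prod(d[1:2])), d)
  ramp <- 2 * ix * sp[1] + 3 * iy * sp[2] - iz * sp[3] + 5
  out <- resample_isotropic(intensity_volume(ramp, sp), 0.6)
  do <- dim(out$grid)
  ox <- array(rep(0:(do[1] - 1), times = prod(do[2:3])), do)
  oy <- array(rep(rep(0:(do[2] - 1), each = do[1]), times = do[3]), do)
  oz <- array(rep(0:(do[3] - 1), each = prod(do[1:2])), do)
  want <- 2 * ox * 0.6 + 3 * oy * 0.6 - oz * 0.6 + 5
  # interior only: clamping at the grid edge breaks linearity there
  interior <- ox * 0.6 <= (d[1] - 1) * sp[1] & oy * 0.6 <= (d[2] - 1) * sp[2] &
    oz * 0.6 <= (d[3] - 1) * sp[3]
  expect_equal(out$grid[interior], want[interior], tolerance = 1e-9)
})

test_that("min-max normalisation maps onto [0, 1] and is idempotent", {
  set.seed(4)
  v <- intensity_volume(array(rnorm(4^3, 50, 10), c(4, 4, 4)), 0.6)
  n1 <- minmax_normalize(v)
  expect_equal(range(n1$grid), c(0, 1))
  n2 <- minmax_normalize(n1)
  expect_equal(n2$grid, n1$grid, tolerance = 1e-12)
  flat <- intensity_volume(array(7, c(3, 3, 3)), 0.6)
  expect_error(minmax_normalize(flat), "constant volume")
})

test_that("centre cropping yields the requested cube around the brain", {
  g <- array(0L, c(40, 40, 40))
  g[10:20, 12:22, 14:24] <- 3L
  v <- label_volume(g, 0.6)
  out <- crop_center(v, 24L)
  expect_equal(dim(out$grid), rep(24L, 3))
  expect_equal(sum(out$grid == 3L), sum(g == 3L))  # nothing clipped
  ctr <- colMeans(which(out$grid > 0L, arr.ind = TRUE))
  expect_true(all(abs(ctr - 12.5) <= 1))
  expect_error(crop_center(label_volume(array(0L, c(4, 4, 4)), 0.6)),
               "empty foreground")
})

test_that("cropping pads with background when the brain is near the border", {
  g <- array(0L, c(10, 10, 10))
  g[1:3, 1:3, 1:3] <- 3L
  out <- crop_center(label_volume(g, 0.6), 8L)
  expect_equal(dim(out$grid), rep(8L, 3))
  expect_equal(sum(out$grid == 3L), 27)
})

test_that("distal restriction keeps TB bilateral and CSP intact", {
  lm <- fb_label_map()
  g <- array(0L, c(30, 20, 20))
  g[4:27, 5:16, 5:16] <- lm[["WM"]]      # x is the widest (left-right) axis
  g[4:9, 8:12, 8:12] <- lm[["DGM"]]      # proximal-side structure
  g[22:27, 8:12, 8:12] <- lm[["CB"]]     # distal-side structure
  g[15:16, 9:11, 9:11] <- lm[["CSP"]]    # midline structure
  v <- label_volume(g, 0.6)
  out <- restrict_to_distal(v, "right")
  expect_equal(out$hemisphere, "right")
  # total-brain mask unchanged
  expect_equal(fb_mask(out, "TB"), fb_mask(v, "TB"))
  # CSP survives on both sides
  expect_equal(structure_volume(out, "CSP"), structure_volume(v, "CSP"))
  # proximal DGM demoted to generic TB, distal CB untouched
  expect_equal(structure_volume(out, "DGM"), 0)
  expect_equal(structure_volume(out, "CB"), structure_volume(v, "CB"))
  expect_gt(sum(out$grid == lm[["TB"]]), 0)
  # idempotent
  expect_identical(restrict_to_distal(out, "right")$grid, out$grid)
})

test_that("distal restriction of the left hemisphere mirrors the right", {
  lm <- fb_label_map()
  g <- array(0L, c(30, 20, 20))
  g[4:27, 5:16, 5:16] <- lm[["WM"]]
  g[4:9, 8:12, 8:12] <- lm[["DGM"]]
  v <- label_volume(g, 0.6)
  out <- restrict_to_distal(v, "left")
  expect_equal(structure_volume(out, "DGM"), structure_volume(v, "DGM"))
  expect_error(restrict_to_distal(label_volume(array(0L, c(4, 4, 4)), 0.6)),
               "empty volume")
})
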