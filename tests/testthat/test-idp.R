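# digital ball mask: radius in voxels, isotropic spacing in mm
ball_mask <- function(r_vox, spacing = 0.6, margin_vox = 4L) {
  n <- 2L * ceiling(r_vox) + 2L * margin_vox
  ctr <- (n + 1) / 2
  dx <- seq_len(n) - ctr
  r2 <- outer(outer(dx^2, dx^2, "+"), dx^2, "+")
  list(mask = r2 <= r_vox^2, r_mm = r_vox * spacing, spacing = spacing,
       centre = ctr)
}

test_that("digital ball volume is within 2% of the analytic value", {
  b <- ball_mask(20)
  vol <- sum(b$mask) * b$spacing^3
  expect_lt(abs(vol / (4 / 3 * pi * b$r_mm^3) - 1), 0.02)
})

test_that("mesh surface area of a ball is within 3% of 4*pi*r^2", {
  for (r_vox in c(20, 25)) {
    b <- ball_mask(r_vox)
    mesh <- extract_surface(b$mask, b$spacing)
    area <- mesh_surface_area(mesh)
    expect_lt(abs(area / (4 * pi * b$r_mm^2) - 1), 0.03)
    expect_true(fbgrowth:::mesh_is_closed(mesh))
    expect_equal(mesh_euler(mesh), 2)
  }
})

test_that("a hollow shell meshes as two closed components", {
  b <- ball_mask(15)
  inner <- ball_mask(10, margin_vox = 4L + 5L)  # same grid size
  shell <- b$mask & !inner$mask
  mesh <- extract_surface(shell, 0.6)
  expect_true(fbgrowth:::mesh_is_closed(mesh))
  expect_equal(mesh_euler(mesh), 4)
  want <- 4 * pi * (15 * 0.6)^2 + 4 * pi * (10 * 0.6)^2
  expect_lt(abs(mesh_surface_area(mesh) / want - 1), 0.03)
})

test_that("surface extraction rejects an empty mask", {
  expect_error(extract_surface(array(FALSE, c(4, 4, 4))), "empty mask")
})

test_that("depth map on a spherical brain equals R - rho within a voxel diagonal", {
  b <- ball_mask(18)
  sp <- b$spacing
  d <- dim(b$mask)
  ctr <- b$centre
  # targets: a thin spherical shell of cortical voxels near the surface
  dx <- seq_len(d[1]) - ctr
  r2 <- outer(outer(dx^2, dx^2, "+"), dx^2, "+")
  rho <- sqrt(r2) * sp
  target <- b$mask & rho > (18 - 4) * sp
  dm <- depth_map(b$mask, target, sp)
  want <- b$r_mm - rho[dm$index]
  diag_mm <- sqrt(3) * sp
  expect_lt(max(abs(dm$values - want)), diag_mm)
})

test_that("depth at a voxel adjacent to background is at most one diagonal", {
  m <- array(FALSE, c(8, 8, 8))
  m[3:6, 3:6, 3:6] <- TRUE
  target <- array(FALSE, c(8, 8, 8))
  target[3, 3, 3] <- TRUE  # corner voxel, 6-adjacent to background
  dm <- depth_map(m, target, 0.6)
  expect_lte(dm$values, sqrt(3) * 0.6)
})

test_that("depth map contract violations raise errors", {
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- TRUE
  bad_target <- array(FALSE, c(6, 6, 6)); bad_target[1, 1, 1] <- TRUE
  expect_error(depth_map(m, bad_target, 0.6), "not contained")
  full <- array(TRUE, c(6, 6, 6))
  expect_error(depth_map(full, full, 0.6), "fills the grid")
})

test_that("slab thickness is recovered within half a voxel", {
  # full-extent slabs: the only pial face is the top, as for a closed shell
  d3 <- c(40L, 16L, 16L)
  sp <- 0.6
  grid <- array(0L, d3)
  grid[3:25, , ] <- fb_label_map()[["WM"]]
  grid[26:30, , ] <- fb_label_map()[["CoP"]]  # 5 voxels = 3.0 mm
  vol <- label_volume(grid, sp)
  tm <- thickness_map(fb_mask(vol, "CoP"), fb_mask(vol, "WM"), sp)
  expect_equal(sum(is.na(tm$values)), 0)
  expect_lt(max(abs(tm$values - 3.0)), 0.5 * sp + 1e-9)
})

test_that("thickness map contract violations raise errors", {
  m <- array(FALSE, c(6, 6, 6))
  cop <- m; cop[4, 3:4, 3:4] <- TRUE
  wm <- m; wm[3, 3:4, 3:4] <- TRUE
  expect_error(thickness_map(cop, cop, 0.6), "overlap")
  far_wm <- m; far_wm[1, 1, 1] <- TRUE
  expect_error(thickness_map(cop, far_wm, 0.6), "not adjacent")
  expect_error(thickness_map(m, wm, 0.6), "empty cortical-plate")
})

test_that("shell thickness on the phantom matches the specification", {
  ph <- generate_phantom(phantom_spec(22))
  cop <- fb_mask(ph, "CoP")
  wm <- fb_mask(ph, "WM")
  tm <- thickness_map(cop, wm, ph$spacing_mm, tbv_mask = fb_mask(ph, "TB"))
  med <- median(tm$values, na.rm = TRUE)
  # 2.5 mm shell, half-voxel tolerance on each side
  expect_lt(abs(med - 2.5), 0.5)
  expect_lt(mean(is.na(tm$values)), 0.05)
})

test_that("lobe summaries aggregate map values over the lobe mask", {
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- TRUE
  target <- array(FALSE, c(6, 6, 6)); target[2:5, 2, 2] <- TRUE
  dm <- depth_map(m, target, 0.6)
  lobe <- array(FALSE, c(6, 6, 6)); lobe[2:3, 2, 2] <- TRUE
  ls <- lobe_summary(dm, lobe, 0.6)
  expect_equal(ls$n, 2)
  expect_equal(ls$volume, 2 * 0.6^3)
  expect_equal(ls$mean, mean(dm$values[lobe[dm$index]]))
  empty <- array(FALSE, c(6, 6, 6))
  expect_true(is.na(lobe_summary(dm, empty, 0.6)$mean))
})

test_that("Sylvian fissure depth is the median insular depth", {
  m <- array(FALSE, c(8, 8, 8)); m[2:7, 2:7, 2:7] <- TRUE
  target <- array(FALSE, c(8, 8, 8)); target[2:7, 4, 4] <- TRUE
  dm <- depth_map(m, target, 0.6)
  insula <- target
  expect_equal(sylvian_fissure_depth(dm, insula), median(dm$values))
  expect_true(is.na(sylvian_fissure_depth(dm, array(FALSE, c(8, 8, 8)))))
})

test_that("all 28 IDPs extract from a phantom with consistent values", {
  ph <- generate_phantom(phantom_spec(22))
  rec <- extract_all_idps(ph, meta = list(fetus_id = "F00001", ga_weeks = 22))
  expect_equal(nrow(rec), 1)
  expect_true(all(idp_names() %in% names(rec)))
  expect_equal(rec$TBV, structure_volume(ph, "TB"))
  expect_equal(rec$FLV + rec$TLV + rec$PLV + rec$OLV + rec$ILV, rec$CoPV)
  # the shell has two boundaries: outer plus inner analytic area
  R <- (3 * rec$TBV / (4 * pi))^(1 / 3)
  want_area <- 4 * pi * R^2 + 4 * pi * (R - 2.5)^2
  expect_lt(abs(rec$CoPSA / want_area - 1), 0.03)
  # depth of shell voxels lies within [0, shell thickness + a voxel]
  depths <- c(rec$FLD, rec$TLD, rec$PLD, rec$OLD, rec$ILD)
  expect_true(all(depths > 0 & depths < 2.5 + 0.6))
  expect_true(rec$SFD > 0 && rec$SFD < 2.5 + 0.6)
  thick <- c(rec$FLT, rec$TLT, rec$PLT, rec$OLT, rec$ILT)
  expect_true(all(abs(thick - 2.5) < 0.5))
  expect_identical(rec$fetus_id, "F00001")
})

test_that("missing structures yield NA rather than failure", {
  lm <- fb_label_map()
  g <- array(0L, c(20, 20, 20))
  g[5:16, 5:16, 5:16] <- lm[["WM"]]
  g[8:13, 8:13, 16] <- lm[["FL"]]  # a patch of cortex, no other structures
  rec <- extract_all_idps(label_volume(g, 0.6))
  expect_true(is.na(rec$CBV))
  expect_true(is.na(rec$CSPV))
  expect_true(is.na(rec$TLV))
  expect_false(is.na(rec$TBV))
  expect_false(is.na(rec$FLV))
})

test_that("relative volumes and the insular ratio are consistent", {
  ph <- generate_phantom(phantom_spec(22))
  rec <- extract_all_idps(ph)
  rel <- relative_volumes(rec)
  expect_equal(rel$rCoPV_TBV, rec$CoPV / rec$TBV)
  lobe_rel <- c(rel$rFLV, rel$rTLV, rel$rPLV, rel$rOLV, rel$rILV)
  expect_equal(sum(lobe_rel), 1, tolerance = 1e-9)
  # equal sectors: insular and parietal relative volumes are equal
  expect_equal(rel$rILV_over_rPLV, 1, tolerance = 0.02)
  bad <- rec; bad$TBV <- NA_real_
  expect_error(relative_volumes(bad), "TBV")
})
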