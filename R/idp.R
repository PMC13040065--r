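#' Structure volume in mm^3
#'
#' Count of labelled voxels times the voxel volume (product of the per-axis
#' spacings).
#'
#' @param vol a [label_volume()].
#' @param structure structure name from the label dictionary ("TB" for the
#'   whole brain).
#' @return volume in mm^3 (0 for an absent structure).
#' @export
structure_volume <- function(vol, structure) {
  sum(fb_mask(vol, structure)) * prod(vol$spacing_mm)
}

#' Extract a triangulated surface from a binary mask
#'
#' The mask is zero-padded by one voxel plus the smoothing support (so
#' border-touching masks still yield closed meshes), smoothed with a Gaussian
#' of `smooth_sigma` voxels to place vertices at sub-voxel positions, and
#' isosurfaced at level 0.5 with a topology-consistent tetrahedral marching
#' scheme.  Vertices are in mm.
#'
#' @param mask logical 3D array.
#' @param spacing_mm per-axis voxel spacing in mm (length 1 or 3).
#' @param smooth_sigma Gaussian pre-smoothing bandwidth in voxels; 0 disables
#'   smoothing (vertices then sit at edge midpoints, which inflates the area
#'   of curved surfaces).
#' @return a `surface_mesh`: list with `vertices` (n x 3, mm) and `faces`
#'   (m x 3, 1-based vertex indices).
#' @export
extract_surface <- function(mask, spacing_mm = 0.6, smooth_sigma = 0.8) {
  abort_if(!any(mask), "empty mask: no surface to extract")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  pad <- as.integer(ceiling(3 * smooth_sigma) + 1)
  d <- dim(mask)
  padded <- array(0, d + 2L * pad)
  padded[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  if (smooth_sigma > 0)
    padded <- .smooth3d(padded, dim(padded), smooth_sigma)
  res <- .march_tets(padded, dim(padded), 0.5, spacing_mm)
  # shift vertices back to the unpadded frame
  res$vertices <- sweep(res$vertices, 2, pad * spacing_mm)
  structure(res, class = "surface_mesh")
}

#' Total surface area of a triangle mesh
#'
#' Sum of the triangle areas; degenerate faces contribute zero.
#'
#' @param mesh a `surface_mesh` from [extract_surface()].
#' @return area in mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}

#' Euler characteristic of a mesh
#'
#' V - E + F with welded vertices; 2 for a single closed genus-0 component,
#' 4 for two such components (e.g. the two boundaries of a hollow shell).
#'
#' @param mesh a `surface_mesh`.
#' @return integer Euler characteristic.
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- t(apply(edges, 1, sort))
  ne <- nrow(unique(edges))
  nrow(mesh$vertices) - ne + nrow(f)
}

# TRUE when every edge is shared by exactly two faces
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2)
}

#' Distance-transform depth map
#'
#' Exact Euclidean distance (in mm, spacing-aware) from each voxel of
#' `target_mask` to the nearest voxel outside `tbv_mask`: the cortical depth
#' construction, in which the distance transform of the total-brain mask is
#' read out at the cortical-plate voxels.
#'
#' @param tbv_mask logical 3D array: the total brain.
#' @param target_mask logical 3D array, contained in `tbv_mask`, where depths
#'   are recorded.
#' @param spacing_mm per-axis spacing in mm (length 1 or 3).
#' @return a `depth_map`: list with `values` (numeric vector, mm), `index`
#'   (linear voxel indices of the target voxels) and `dim`.
#' @export
depth_map <- function(tbv_mask, target_mask, spacing_mm = 0.6) {
  abort_if(any(target_mask & !tbv_mask),
           "target mask not contained in the total-brain mask")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  abort_if(all(tbv_mask),
           "total-brain mask fills the grid: depth to background undefined")
  d <- .edt3d(tbv_mask, dim(tbv_mask), spacing_mm)
  idx <- which(target_mask)
  structure(list(values = d[idx], index = idx, dim = dim(tbv_mask)),
            class = "depth_map")
}

#' Gradient-projection cortical thickness map
#'
#' For each cortical-plate voxel on the pial boundary (6-adjacent to the
#' background), marches along the interpolated gradient of the exterior
#' distance field until entering white matter and records the path length in
#' mm (plus a half-voxel pial-side correction); rays are capped at `cap_mm`.
#'
#' @param cop_mask logical 3D array: cortical plate.
#' @param wm_mask logical 3D array: white matter; must be disjoint from the
#'   cortical plate and adjacent to its inner boundary.
#' @param spacing_mm per-axis spacing in mm (length 1 or 3).
#' @param tbv_mask total-brain mask used for the exterior distance field;
#'   defaults to `cop_mask | wm_mask`.
#' @param step_vox ray-march step in voxels.
#' @param cap_mm maximum thickness; runaway rays are truncated here.
#' @return a `depth_map` whose `values` are thicknesses at the pial seed
#'   voxels (`index`); NA where a ray left the grid or stalled.
#' @export
thickness_map <- function(cop_mask, wm_mask, spacing_mm = 0.6,
                          tbv_mask = cop_mask | wm_mask,
                          step_vox = 0.25, cap_mm = 10) {
  abort_if(!any(cop_mask), "empty cortical-plate mask")
  abort_if(any(cop_mask & wm_mask),
           "cortical plate and white matter masks overlap")
  abort_if(!any(wm_mask & dilate6(cop_mask)),
           "white matter not adjacent to the cortical plate")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  seeds <- which(cop_mask & dilate6(!tbv_mask))
  abort_if(length(seeds) == 0, "no pial boundary voxels found")
  dfield <- .edt3d(tbv_mask, dim(tbv_mask), spacing_mm)
  vals <- .ray_thickness(dfield, dim(cop_mask), spacing_mm,
                         as.integer(seeds - 1L), wm_mask, step_vox, cap_mm)
  structure(list(values = vals, index = seeds, dim = dim(cop_mask)),
            class = "depth_map")
}

# 6-connected binary dilation by one voxel
dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  sh <- function(m, axis, by) {
    r <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
    else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
    r[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    r
  }
  for (axis in 1:3) for (by in c(-1, 1)) out <- out | sh(mask, axis, by)
  out
}

#' Summaries of a depth or thickness map over a lobe
#'
#' @param map a `depth_map` (depth or thickness values at voxels).
#' @param lobe_mask logical 3D array selecting the lobe.
#' @param spacing_mm per-axis spacing in mm, for the lobe volume.
#' @return list with `volume` (mm^3), `mean` (mm; NA for an empty lobe or
#'   when no map voxels fall inside it) and `n` map voxels used.
#' @export
lobe_summary <- function(map, lobe_mask, spacing_mm = 0.6) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  vol <- sum(lobe_mask) * prod(spacing_mm)
  sel <- lobe_mask[map$index]
  vals <- map$values[sel]
  vals <- vals[is.finite(vals)]
  list(volume = if (sum(lobe_mask) > 0) vol else NA_real_,
       mean = if (length(vals) > 0) mean(vals) else NA_real_,
       n = length(vals))
}

#' Sylvian fissure depth
#'
#' Median cortical depth over the insular voxels (the median, rather than the
#' mean, is robust to the mix of inner- and outer-boundary voxels).  With an
#' even number of voxels the mid-mean convention applies.
#'
#' @param depth a `depth_map` over the cortical plate.
#' @param insula_mask logical 3D array: the insular lobe.
#' @return depth in mm, or NA for an empty insula.
#' @export
sylvian_fissure_depth <- function(depth, insula_mask) {
  sel <- insula_mask[depth$index]
  vals <- depth$values[sel]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(NA_real_)
  median(vals)
}

#' Extract all 28 image-derived phenotypes from a label volume
#'
#' Volumes for the 11 structures (total brain and cavum septum bilaterally,
#' the rest on whichever hemisphere carries labels), cortical plate surface
#' area, Sylvian fissure depth, and per-lobe volume, mean depth and mean
#' thickness.  Structures absent from the volume yield NA for the affected
#' measures rather than failing globally.
#'
#' @param vol a [label_volume()], preprocessed (and hemisphere-restricted for
#'   real data).
#' @param meta optional named list/row with fetus_id, site, sex, ga_weeks,
#'   hemisphere to prepend.
#' @param smooth_sigma surface pre-smoothing bandwidth (voxels), see
#'   [extract_surface()].
#' @return one-row data.frame with metadata and the 28 IDP columns
#'   ([idp_names()]).
#' @export
extract_all_idps <- function(vol, meta = NULL, smooth_sigma = 0.8) {
  stopifnot(inherits(vol, "label_volume"))
  sp <- vol$spacing_mm
  vox <- prod(sp)
  tb <- fb_mask(vol, "TB")
  cop <- fb_mask(vol, "CoP")
  wm <- fb_mask(vol, "WM")

  out <- list()
  out$TBV <- sum(tb) * vox
  vol_structs <- c(CoPV = "CoP", WMV = "WM", DGMV = "DGM", CBV = "CB",
                   ThV = "Th", LVV = "LV", ChPV = "ChP", FHV = "FH",
                   BSV = "BS", CSPV = "CSP")
  for (nm in names(vol_structs)) {
    v <- structure_volume(vol, vol_structs[[nm]])
    out[[nm]] <- if (v > 0) v else NA_real_
  }
  out$CoPV <- if (sum(cop) > 0) sum(cop) * vox else NA_real_

  out$CoPSA <- if (any(cop))
    mesh_surface_area(extract_surface(cop, sp, smooth_sigma)) else NA_real_

  dmap <- if (any(cop) && !all(tb)) depth_map(tb, cop, sp) else NULL
  tmap <- if (any(cop) && any(wm))
    tryCatch(thickness_map(cop, wm, sp, tbv_mask = tb), error = function(e) NULL)
  else NULL

  for (lobe in lobe_names()) {
    lm_mask <- fb_mask(vol, lobe)
    ls_d <- if (!is.null(dmap)) lobe_summary(dmap, lm_mask, sp)
      else list(volume = NA_real_, mean = NA_real_)
    ls_t <- if (!is.null(tmap)) lobe_summary(tmap, lm_mask, sp)
      else list(mean = NA_real_)
    out[[paste0(lobe, "V")]] <- if (sum(lm_mask) > 0) sum(lm_mask) * vox else NA_real_
    out[[paste0(lobe, "D")]] <- ls_d$mean
    out[[paste0(lobe, "T")]] <- ls_t$mean
  }
  out$SFD <- if (!is.null(dmap))
    sylvian_fissure_depth(dmap, fb_mask(vol, "IL")) else NA_real_

  rec <- as.data.frame(out[idp_names()])
  if (!is.null(meta)) rec <- cbind(as.data.frame(meta), rec)
  rec
}

#' Relative volumes and the insular-to-parietal ratio
#'
#' Structure volumes relative to total brain volume, lobe volumes relative to
#' total cortical plate volume (rFLV..rILV), and the asynchrony marker
#' rILV / rPLV.
#'
#' @param rec one-row IDP data.frame from [extract_all_idps()] (or a row of a
#'   simulated table).
#' @return one-row data.frame of relative measures; the ratio is NA when the
#'   relative parietal volume is zero or missing.
#' @export
relative_volumes <- function(rec) {
  abort_if(is.na(rec$TBV) || rec$TBV <= 0, "TBV must be positive")
  abort_if(is.na(rec$CoPV) || rec$CoPV <= 0, "CoPV must be positive")
  out <- list()
  for (nm in c("CoPV", "WMV", "DGMV", "CBV", "ThV", "LVV", "ChPV", "FHV",
               "BSV", "CSPV"))
    out[[paste0("r", nm, "_TBV")]] <- rec[[nm]] / rec$TBV
  for (lobe in lobe_names())
    out[[paste0("r", lobe, "V")]] <- rec[[paste0(lobe, "V")]] / rec$CoPV
  out$rILV_over_rPLV <- if (!is.na(out$rPLV) && out$rPLV > 0)
    out$rILV / out$rPLV else NA_real_
  as.data.frame(out)
}
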