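#' Label dictionary for fetal brain parcellations
#'
#' Integer codes for the 11 brain structures and 5 cortical lobes.  Code 1
#' (`TB`) marks generic brain tissue (used for the proximal hemisphere after
#' distal restriction); cortical-plate voxels carry either the generic `CoP`
#' code or a lobe code, so the CoP mask is the union of `CoP` and the five
#' lobes.  The dictionary is also shipped as
#' `inst/extdata/label_dictionary.json`.
#'
#' @return named integer vector of label codes.
#' @export
fb_label_map <- function() {
  c(TB = 1L, CoP = 2L, WM = 3L, DGM = 4L, CB = 5L, Th = 6L, LV = 7L,
    ChP = 8L, FH = 9L, BS = 10L, CSP = 11L,
    FL = 12L, TL = 13L, PL = 14L, OL = 15L, IL = 16L)
}

lobe_names <- function() c("FL", "TL", "PL", "OL", "IL")

#' Construct a label volume
#'
#' A 3D integer parcellation grid with physical voxel spacing, a label
#' dictionary and a hemisphere annotation.
#'
#' @param grid 3D integer array of label codes (0 = background).
#' @param spacing_mm per-axis voxel spacing in mm (length 1 or 3).
#' @param label_map named integer label dictionary, default [fb_label_map()].
#' @param hemisphere one of "left", "right", "both": which hemisphere carries
#'   structure labels.
#' @return a `label_volume` object.
#' @export
label_volume <- function(grid, spacing_mm = 0.6, label_map = fb_label_map(),
                         hemisphere = c("both", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  abort_if(length(dim(grid)) != 3, "grid must be a 3D array")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  abort_if(any(spacing_mm <= 0), "spacing must be strictly positive")
  vals <- unique(as.integer(grid))
  unknown <- setdiff(vals, c(0L, unname(label_map)))
  abort_if(length(unknown) > 0,
           paste("unknown label values:", paste(sort(unknown), collapse = ", ")))
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, spacing_mm = spacing_mm, label_map = label_map,
                 hemisphere = hemisphere),
            class = "label_volume")
}

#' Construct an intensity volume
#'
#' @param grid 3D numeric array of finite intensities.
#' @param spacing_mm per-axis voxel spacing in mm (length 1 or 3).
#' @return an `intensity_volume` object.
#' @export
intensity_volume <- function(grid, spacing_mm = 0.6) {
  abort_if(length(dim(grid)) != 3, "grid must be a 3D array")
  abort_if(any(!is.finite(grid)), "intensities must be finite")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  abort_if(any(spacing_mm <= 0), "spacing must be strictly positive")
  structure(list(grid = grid, spacing_mm = spacing_mm),
            class = "intensity_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume %s, spacing %s mm, hemisphere %s\n",
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"), x$hemisphere))
  invisible(x)
}

#' Binary mask for a named structure
#'
#' `TB` is the union of all labelled voxels; `CoP` is the union of the
#' generic cortical-plate code and the five lobe codes.
#'
#' @param vol a [label_volume()].
#' @param structure a name from the label dictionary, or "TB".
#' @return logical 3D array.
#' @export
fb_mask <- function(vol, structure) {
  lm <- vol$label_map
  abort_if(!structure %in% names(lm), paste("unknown structure:", structure))
  if (structure == "TB") return(vol$grid > 0L)
  if (structure == "CoP") {
    codes <- lm[c("CoP", lobe_names())]
    return(array(vol$grid %in% codes, dim(vol$grid)))
  }
  vol$grid == lm[[structure]]
}

#' Read / write volumes as NIfTI-1
#'
#' Label volumes round-trip bit-exactly (integer datatype); spacing is kept
#' in the NIfTI header.  On read, a grid whose values all lie in the label
#' dictionary (or 0) is returned as a label volume unless `type` says
#' otherwise; values outside the dictionary raise a validation error for
#' label reads.
#'
#' @param vol a [label_volume()] or [intensity_volume()].
#' @param path a .nii or .nii.gz file path.
#' @param type "auto", "label" or "intensity".
#' @param label_map label dictionary used for validation on label reads.
#' @param hemisphere hemisphere annotation to attach on label reads.
#' @return `read_volume` returns the volume object; `write_volume` the path,
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  grid <- vol$grid
  if (inherits(vol, "label_volume")) storage.mode(grid) <- "integer"
  attr(grid, "pixdim") <- vol$spacing_mm
  img <- RNifti::asNifti(grid, datatype = if (is.integer(grid)) "int32" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, type = c("auto", "label", "intensity"),
                        label_map = fb_label_map(),
                        hemisphere = "both") {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  grid <- array(as.vector(img), dim(img))
  is_int <- all(grid == round(grid))
  if (type == "auto")
    type <- if (is_int && all(grid %in% c(0, label_map))) "label" else "intensity"
  if (type == "label") {
    abort_if(!is_int, "non-integer values in a label volume")
    label_volume(grid, spacing, label_map, hemisphere)
  } else {
    intensity_volume(grid, spacing)
  }
}

# map output voxel centres (target spacing) to source voxel coordinates;
# world position = 0-based index * spacing
resample_coords <- function(dim_in, spacing_in, target) {
  extent <- dim_in * spacing_in
  dim_out <- pmax(1L, as.integer(round(extent / target)))
  coords <- lapply(1:3, function(a) {
    (seq_len(dim_out[a]) - 1) * target / spacing_in[a]
  })
  list(dim_out = dim_out, coords = coords)
}

#' Resample a volume to isotropic spacing
#'
#' Intensity volumes are interpolated trilinearly; label volumes use
#' nearest-neighbour so label identity is preserved.  The physical extent is
#' preserved to within one voxel.  A volume already at the target spacing is
#' returned unchanged.
#'
#' @param vol a [label_volume()] or [intensity_volume()].
#' @param target_mm target isotropic voxel size in mm (default 0.6).
#' @return a volume of the same class at `target_mm` isotropic spacing.
#' @export
resample_isotropic <- function(vol, target_mm = 0.6) {
  abort_if(target_mm <= 0, "target spacing must be positive")
  if (all(abs(vol$spacing_mm - target_mm) < 1e-12)) return(vol)
  rc <- resample_coords(dim(vol$grid), vol$spacing_mm, target_mm)
  if (inherits(vol, "label_volume")) {
    idx <- lapply(1:3, function(a) {
      pmin(pmax(round(rc$coords[[a]]) + 1, 1), dim(vol$grid)[a])
    })
    grid <- vol$grid[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    label_volume(grid, target_mm, vol$label_map, vol$hemisphere)
  } else {
    grid <- trilinear_gather(vol$grid, rc$coords)
    intensity_volume(grid, target_mm)
  }
}

# vectorised trilinear interpolation at the outer product of per-axis
# continuous source coordinates (0-based)
trilinear_gather <- function(grid, coords) {
  d <- dim(grid)
  lo <- lapply(1:3, function(a) pmin(pmax(floor(coords[[a]]), 0), d[a] - 1))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, d[a] - 1))
  fr <- lapply(1:3, function(a) pmin(pmax(coords[[a]] - lo[[a]], 0), 1))
  n <- vapply(coords, length, integer(1))
  out <- array(0, n)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- (if (cx) hi[[1]] else lo[[1]]) + 1
    iy <- (if (cy) hi[[2]] else lo[[2]]) + 1
    iz <- (if (cz) hi[[3]] else lo[[3]]) + 1
    wx <- if (cx) fr[[1]] else 1 - fr[[1]]
    wy <- if (cy) fr[[2]] else 1 - fr[[2]]
    wz <- if (cz) fr[[3]] else 1 - fr[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * grid[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Min-max intensity normalisation
#'
#' Affine map of the intensities onto \[0, 1\] (per-volume min-max scaling);
#' idempotent once the endpoints are attained.  A constant volume is a
#' degenerate input and raises an error.
#'
#' @param vol an [intensity_volume()].
#' @return the normalised intensity volume.
#' @export
minmax_normalize <- function(vol) {
  stopifnot(inherits(vol, "intensity_volume"))
  r <- range(vol$grid)
  abort_if(r[2] <= r[1], "constant volume: min-max normalisation undefined")
  intensity_volume((vol$grid - r[1]) / (r[2] - r[1]), vol$spacing_mm)
}

#' Crop (or pad) a volume to a cube centred on the brain
#'
#' The output is exactly `size`^3 voxels centred on the foreground centroid
#' (labelled voxels for label volumes, positive intensities otherwise);
#' regions outside the input are padded with background.
#'
#' @param vol a [label_volume()] or [intensity_volume()].
#' @param size output edge length in voxels (default 160).
#' @return the cropped volume.
#' @export
crop_center <- function(vol, size = 160L) {
  size <- as.integer(size)
  fg <- if (inherits(vol, "label_volume")) vol$grid > 0L else vol$grid > 0
  abort_if(!any(fg), "empty foreground: cannot locate the brain centre")
  idx <- which(fg, arr.ind = TRUE)
  centroid <- round(colMeans(idx))
  start <- centroid - size %/% 2 + 1
  out <- array(if (inherits(vol, "label_volume")) 0L else 0,
               rep(size, 3))
  src_from <- pmax(start, 1)
  src_to <- pmin(start + size - 1L, dim(vol$grid))
  dst_from <- src_from - start + 1L
  dst_to <- dst_from + (src_to - src_from)
  out[dst_from[1]:dst_to[1], dst_from[2]:dst_to[2], dst_from[3]:dst_to[3]] <-
    vol$grid[src_from[1]:src_to[1], src_from[2]:src_to[2], src_from[3]:src_to[3]]
  if (inherits(vol, "label_volume"))
    label_volume(out, vol$spacing_mm, vol$label_map, vol$hemisphere)
  else intensity_volume(out, vol$spacing_mm)
}

#' Restrict structure labels to the distal hemisphere
#'
#' Zeroes all structure labels except total brain and cavum septum (CSP) on
#' the proximal side of the mid-sagittal plane; proximal brain tissue keeps
#' the generic `TB` code so the total-brain mask stays bilateral.  The
#' mid-sagittal plane passes through the total-brain centroid orthogonal to
#' the grid axis of greatest extent (ties broken towards the first axis).
#'
#' @param vol a [label_volume()].
#' @param distal "left" or "right": the hemisphere that keeps its labels
#'   (lower / upper indices along the left-right axis).
#' @return the restricted label volume, annotated with the distal hemisphere.
#' @export
restrict_to_distal <- function(vol, distal = c("right", "left")) {
  distal <- match.arg(distal)
  tb <- vol$grid > 0L
  abort_if(!any(tb), "empty volume: mid-sagittal plane underivable")
  idx <- which(tb, arr.ind = TRUE)
  extents <- apply(idx, 2, function(v) diff(range(v)))
  axis <- which.max(extents)  # ties -> first axis
  centre <- mean(idx[, axis])
  ax_index <- slice.index(vol$grid, axis)
  proximal <- if (distal == "right") ax_index <= centre else ax_index > centre
  keep <- vol$label_map[["CSP"]]
  grid <- vol$grid
  demote <- proximal & grid > 0L & grid != keep
  grid[demote] <- vol$label_map[["TB"]]
  label_volume(grid, vol$spacing_mm, vol$label_map, hemisphere = distal)
}
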