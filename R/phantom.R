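#' Phantom specification
#'
#' Describes a synthetic, sphere-based fetal brain label phantom.  The total
#' brain is a digital ball whose volume follows the reference TBV growth
#' equation at the requested gestational age; the cortical plate (CoP) is the
#' outer shell, partitioned into five lobes by angular sectors about the
#' left-right axis; white matter fills the interior; subcortical structures
#' are interior balls sized as configurable fractions of total brain volume.
#' The idealisation (no gyrification) is deliberate: every downstream measure
#' has an analytic oracle on spheres and shells.
#'
#' @param ga_weeks gestational age in weeks, within 18-27.
#' @param spacing_mm isotropic voxel size in mm (default 0.6).
#' @param grid_size voxels per axis (default 160).
#' @param structure_fractions named fractions of total brain volume for the
#'   interior structures (defaults are mid-gestation plausible single
#'   -hemisphere constants; only TBV is anchored to the published equation).
#' @param lobe_sector_angles named list of `[start, end)` angular sectors in
#'   radians partitioning `[0, 2*pi)`, one per lobe (FL, TL, PL, OL, IL).
#' @param cop_thickness_mm cortical plate shell thickness in mm.
#' @param mean_model growth model giving the TBV mean curve in cm^3
#'   (default [tbv_reference_model()]).
#' @param seed integer seed (the geometry is deterministic; kept for
#'   interface uniformity with the other generators).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(ga_weeks,
                         spacing_mm = 0.6,
                         grid_size = 160L,
                         structure_fractions = default_structure_fractions(),
                         lobe_sector_angles = default_lobe_sectors(),
                         cop_thickness_mm = 2.5,
                         mean_model = tbv_reference_model(),
                         seed = 1L) {
  abort_if(ga_weeks < mean_model$ga_domain[1] || ga_weeks > mean_model$ga_domain[2],
           "gestational age outside the growth-model domain")
  abort_if(spacing_mm <= 0, "spacing must be positive")
  abort_if(any(structure_fractions <= 0 | structure_fractions >= 1),
           "structure fractions must lie in (0, 1)")
  check_sectors(lobe_sector_angles)
  structure(list(ga_weeks = ga_weeks, spacing_mm = spacing_mm,
                 grid_size = as.integer(grid_size),
                 structure_fractions = structure_fractions,
                 lobe_sector_angles = lobe_sector_angles,
                 cop_thickness_mm = cop_thickness_mm,
                 mean_model = mean_model, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default interior structure fractions of total brain volume
#'
#' Single-hemisphere constants for the distal structures plus the midline
#' cavum septum; configurable in [phantom_spec()].
#'
#' @return named numeric vector of fractions.
#' @export
default_structure_fractions <- function() {
  c(DGM = 0.020, CB = 0.012, BS = 0.008, Th = 0.005,
    LV = 0.004, ChP = 0.003, FH = 0.002, CSP = 0.0015)
}

#' Default equal-angle lobe sectors
#'
#' Five equal angular sectors about the left-right axis, in lobe order FL,
#' TL, PL, OL, IL.
#'
#' @return named list of `c(start, end)` angles in radians.
#' @export
default_lobe_sectors <- function() {
  br <- seq(0, 2 * pi, length.out = 6)
  stats::setNames(lapply(1:5, function(i) c(br[i], br[i + 1])), lobe_names())
}

check_sectors <- function(sectors) {
  abort_if(!all(lobe_names() %in% names(sectors)),
           "lobe sectors must be named FL, TL, PL, OL, IL")
  s <- do.call(rbind, sectors[lobe_names()])
  s <- s[order(s[, 1]), , drop = FALSE]
  ok <- abs(s[1, 1] - 0) < 1e-9 && abs(s[nrow(s), 2] - 2 * pi) < 1e-9 &&
    all(abs(s[-1, 1] - s[-nrow(s), 2]) < 1e-9)
  abort_if(!ok, "lobe sectors must partition [0, 2*pi) without overlap")
}

# placement of the interior structure balls: unit direction (on the
# y/z/x axes; x is the left-right axis) and centre distance as a fraction of
# the brain radius.  CSP sits on the mid-sagittal plane (zero x component).
structure_placement <- function() {
  list(DGM = list(dir = c(0, 1, 0), dist = 0.5),
       CB  = list(dir = c(0, -1, 0), dist = 0.5),
       Th  = list(dir = c(0, 0, 1), dist = 0.5),
       BS  = list(dir = c(0, 0, -1), dist = 0.5),
       LV  = list(dir = c(1, 0, 0), dist = 0.5),
       FH  = list(dir = c(-1, 0, 0), dist = 0.5),
       ChP = list(dir = c(0, 0, 0), dist = 0),
       CSP = list(dir = c(0, -0.6, 0.8), dist = 0.6))
}

#' Generate a nested-sphere label phantom
#'
#' Builds the label volume described by a [phantom_spec()]: the digital-ball
#' total brain matches the reference TBV mean curve at the requested
#' gestational age to within the digitisation error (< 2 %); the cortical
#' plate shell carries lobe labels; white matter and non-overlapping interior
#' structure balls fill the inside.  Voxel-identical output for identical
#' specs.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_volume()] with hemisphere "both".
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$spacing_mm
  g <- spec$grid_size
  tbv_mm3 <- 1000 * predict_mean(spec$mean_model, spec$ga_weeks)  # cm^3 -> mm^3
  R <- (3 * tbv_mm3 / (4 * pi))^(1 / 3)
  abort_if(R + 2 * s > (g / 2) * s,
           sprintf("grid too small: brain radius %.1f mm needs > %d voxels/axis",
                   R, ceiling(2 * (R / s + 2))))
  ctr <- (g - 1) / 2
  ax <- ((seq_len(g) - 1) - ctr) * s
  dx2 <- array(rep(ax^2, times = g * g), c(g, g, g))
  dy2 <- aperm(dx2, c(2, 1, 3))
  dz2 <- aperm(dx2, c(3, 2, 1))
  r <- sqrt(dx2 + dy2 + dz2)

  lm <- fb_label_map()
  grid <- array(0L, c(g, g, g))
  t_cop <- spec$cop_thickness_mm
  inside <- r <= R
  shell <- inside & r > (R - t_cop)
  grid[inside & !shell] <- lm[["WM"]]

  # lobe sectors about the x (left-right) axis
  y <- array(rep(ax, each = g), c(g, g, g))
  z <- array(rep(ax, each = g * g), c(g, g, g))
  phi <- (atan2(z, y)) %% (2 * pi)
  for (lobe in lobe_names()) {
    sec <- spec$lobe_sector_angles[[lobe]]
    in_sec <- if (abs(diff(sec) - 2 * pi) < 1e-9) shell
      else shell & phi >= sec[1] & phi < sec[2]
    grid[in_sec] <- lm[[lobe]]
  }

  # interior structure balls, with non-overlap and containment checks
  place <- structure_placement()
  fr <- spec$structure_fractions
  x <- array(rep(ax, times = g * g), c(g, g, g))
  centres <- list(); radii <- numeric(0)
  for (st in names(fr)) {
    abort_if(!st %in% names(place), paste("no placement for structure", st))
    p <- place[[st]]
    d <- p$dir / max(sqrt(sum(p$dir^2)), 1e-12)
    c_mm <- d * p$dist * R
    r_st <- R * fr[[st]]^(1 / 3)
    abort_if(p$dist * R + r_st > R - t_cop - s,
             paste("structure", st, "does not fit inside the white matter"))
    for (j in seq_along(radii)) {
      sep <- sqrt(sum((c_mm - centres[[j]])^2))
      abort_if(sep <= r_st + radii[j],
               paste("structures overlap:", st, "and", names(radii)[j]))
    }
    centres[[st]] <- c_mm
    radii <- c(radii, stats::setNames(r_st, st))
    ball <- (x - c_mm[1])^2 + (y - c_mm[2])^2 + (z - c_mm[3])^2 <= r_st^2
    grid[ball] <- lm[[st]]
  }

  label_volume(grid, s, lm, hemisphere = "both")
}
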