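# Digital two-phase mouse-thorax phantom.
#
# The phantom is generated directly in voxel space (reconstruction is out of
# scope): a soft-tissue body cylinder containing two overlapping ellipsoidal
# lung lobes, a pure-air trachea entering the lungs from above (the tube tip
# defines the carina), a spine-like bone rod, and a water-equivalent insert
# outside the body for calibration. Lung parenchyma is a two-component
# air/soft-tissue mixture: a voxel with local air fraction f has noiseless
# CT number -1000*f HU (water = 0 HU), which makes the FRC/VT formulas exact
# on the phantom. Grey values are emitted on a raw scale through linear air /
# water anchors so that the calibration stage has real work to do.

default_geometry <- function() {
  list(
    fov_mm   = 9.6,
    body     = list(center = c(4.8, 4.8), radius = 4.0, hu = 40),
    lobes    = list(
      list(center = c(3.5, 4.8, 4.0), semi_axes = c(1.9, 2.1, 2.6)),
      list(center = c(6.1, 4.8, 4.0), semi_axes = c(1.9, 2.1, 2.6))
    ),
    trachea  = list(center = c(4.8, 4.8), radius = 0.35, carina_z = 5.4),
    water    = list(center = c(8.9, 0.9), radius = 0.4, z = c(3.0, 6.6)),
    bone     = list(center = c(4.8, 8.0), radius = 0.5, hu = 1500),
    seed_point = c(4.8, 4.8, 4.0)
  )
}

#' Specify a digital thorax phantom
#'
#' Parameters of the synthetic paired-phase thorax volume. Defaults emulate a
#' mouse thorax imaged at 0.075 mm isotropic voxels over a 9.6 mm field of
#' view; smaller grids keep the same physical geometry at coarser spacing.
#'
#' @param grid_n voxels per axis (scalar or length 3; default 128).
#' @param spacing_mm isotropic voxel spacing; defaults to `9.6 / max(grid_n)`
#'   so the field of view stays fixed (0.075 mm at 128).
#' @param air_fraction_expiration,air_fraction_inspiration parenchymal air
#'   fraction per respiratory phase, `0 < exp < insp < 1`.
#' @param lesions list of [lesion_spec()] objects.
#' @param noise_sigma_hu additive Gaussian noise scale (HU-equivalent), >= 0.
#' @param raw_air_value,raw_water_value raw grey values assigned to pure air
#'   and water; the generator emits `raw = raw_water + (raw_water - raw_air) *
#'   HU / 1000`, so calibration against these anchors recovers HU exactly.
#' @param seed integer RNG seed for the noise draw.
#' @param geometry advanced: geometry list as from `gatedlung:::default_geometry()`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_n = 128,
                         spacing_mm = NULL,
                         air_fraction_expiration = 0.45,
                         air_fraction_inspiration = 0.62,
                         lesions = list(),
                         noise_sigma_hu = 0,
                         raw_air_value = 10,
                         raw_water_value = 1510,
                         seed = 20240801L,
                         geometry = default_geometry()) {
  if (length(grid_n) == 1L) grid_n <- rep(grid_n, 3L)
  grid_n <- as.integer(grid_n)
  if (is.null(spacing_mm)) spacing_mm <- geometry$fov_mm / max(grid_n)
  stopifnot(all(grid_n >= 8L), spacing_mm > 0)
  if (!(air_fraction_expiration > 0 && air_fraction_expiration < 1 &&
        air_fraction_inspiration > 0 && air_fraction_inspiration < 1))
    stop("air fractions must lie in (0, 1)")
  if (air_fraction_inspiration <= air_fraction_expiration)
    stop("inspiration air fraction must exceed expiration air fraction")
  if (noise_sigma_hu < 0) stop("noise_sigma_hu must be >= 0")
  if (raw_air_value == raw_water_value)
    stop("raw air and water values must differ")
  fov <- grid_n * spacing_mm
  for (lobe in geometry$lobes) {
    if (any(lobe$center - lobe$semi_axes < 0) ||
        any(lobe$center + lobe$semi_axes > fov))
      stop("lung lobe extends outside the grid")
    if (any(lobe$semi_axes <= 0)) stop("lobe semi-axes must be positive")
  }
  structure(
    list(grid_n = grid_n, spacing_mm = spacing_mm,
         air_fraction_expiration = air_fraction_expiration,
         air_fraction_inspiration = air_fraction_inspiration,
         lesions = lesions, noise_sigma_hu = noise_sigma_hu,
         raw_air_value = raw_air_value, raw_water_value = raw_water_value,
         seed = as.integer(seed), geometry = geometry),
    class = "phantom_spec")
}

#' Specify a focal lung lesion
#'
#' Pneumonitis is modelled as a regional density increase (air fraction in the
#' sphere reduced by `severity` at both phases); fibrosis does the same but
#' may additionally dilate the airway tube inside the lesion, emulating the
#' enlarged airways that accompany dense scar ingrowth.
#'
#' @param kind `"pneumonitis"` or `"fibrosis"`.
#' @param center_mm lesion sphere centre (mm, length 3).
#' @param radius_mm lesion sphere radius (mm).
#' @param severity fraction in \[0, 1\] by which the air fraction of lesion
#'   voxels is reduced (`f -> f * (1 - severity)`).
#' @param airway_dilation_mm fibrosis only: increase of the airway tube radius
#'   inside the lesion sphere (default 0).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(kind = c("pneumonitis", "fibrosis"),
                        center_mm = c(3.5, 4.8, 4.0), radius_mm = 1.0,
                        severity = 0.5, airway_dilation_mm = 0) {
  kind <- match.arg(kind)
  stopifnot(length(center_mm) == 3L, radius_mm > 0)
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  if (airway_dilation_mm < 0) stop("airway_dilation_mm must be >= 0")
  if (kind == "pneumonitis" && airway_dilation_mm > 0)
    stop("airway dilation applies to fibrosis lesions only")
  structure(list(kind = kind, center_mm = center_mm, radius_mm = radius_mm,
                 severity = severity, airway_dilation_mm = airway_dilation_mm),
            class = "lesion_spec")
}

# --- voxelized geometry primitives (voxel centres at (k - 0.5) * spacing) ---

axis_coords <- function(n, spacing) (seq_len(n) - 0.5) * spacing

ellipsoid_mask <- function(grid_n, spacing, center, semi) {
  qx <- ((axis_coords(grid_n[1], spacing) - center[1]) / semi[1])^2
  qy <- ((axis_coords(grid_n[2], spacing) - center[2]) / semi[2])^2
  qz <- ((axis_coords(grid_n[3], spacing) - center[3]) / semi[3])^2
  q <- outer(as.vector(outer(qx, qy, "+")), qz, "+")
  array(q <= 1, dim = grid_n)
}

cylinder_mask <- function(grid_n, spacing, center_xy, radius, z_mm = NULL) {
  dx2 <- (axis_coords(grid_n[1], spacing) - center_xy[1])^2
  dy2 <- (axis_coords(grid_n[2], spacing) - center_xy[2])^2
  inplane <- outer(dx2, dy2, "+") <= radius^2
  zc <- axis_coords(grid_n[3], spacing)
  zok <- if (is.null(z_mm)) rep(TRUE, grid_n[3]) else (zc >= z_mm[1] & zc <= z_mm[2])
  array(outer(as.vector(inplane), zok, "&"), dim = grid_n)
}

sphere_mask <- function(grid_n, spacing, center, radius) {
  ellipsoid_mask(grid_n, spacing, center, rep(radius, 3L))
}

nearest_voxel <- function(point_mm, spacing) {
  pmax(1L, as.integer(round(point_mm / spacing + 0.5)))
}

#' Generate a paired-phase thorax phantom with exact ground truth
#'
#' Builds end-expiration and peak-inspiration volumes on the raw grey-value
#' scale, plus a `phantom_truth` record holding the true lung region, the true
#' per-phase air volumes, FRC and VT (all computed by exact summation over the
#' generated air-fraction fields before noise), and generator metadata
#' (carina voxel, calibration reference boxes, body extent, seed hint) that
#' downstream stages use in batch mode.
#'
#' The true lung region is the parenchyma plus the airway voxels lying below
#' the standard analysis boundary (2 mm above the carina), i.e. exactly the
#' voxels a correct threshold segmentation inside the standard bounding region
#' should select.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `expiration`, `inspiration` (raw-scale
#'   [volume_image()]s), `truth` and `meta`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  n <- spec$grid_n
  sp <- spec$spacing_mm

  lung <- ellipsoid_mask(n, sp, g$lobes[[1]]$center, g$lobes[[1]]$semi_axes)
  for (lobe in g$lobes[-1])
    lung <- lung | ellipsoid_mask(n, sp, lobe$center, lobe$semi_axes)
  body <- cylinder_mask(n, sp, g$body$center, g$body$radius)
  bone <- cylinder_mask(n, sp, g$bone$center, g$bone$radius)
  water <- cylinder_mask(n, sp, g$water$center, g$water$radius, g$water$z)

  zmax_mm <- n[3] * sp
  trachea <- cylinder_mask(n, sp, g$trachea$center, g$trachea$radius,
                           c(g$trachea$carina_z, zmax_mm))

  # per-phase parenchymal air-fraction fields (lesion-adjusted)
  f_exp <- array(0, dim = n)
  f_insp <- array(0, dim = n)
  f_exp[lung] <- spec$air_fraction_expiration
  f_insp[lung] <- spec$air_fraction_inspiration
  lesion_mask <- array(FALSE, dim = n)
  for (les in spec$lesions) {
    stopifnot(inherits(les, "lesion_spec"))
    sphere <- sphere_mask(n, sp, les$center_mm, les$radius_mm)
    hit <- sphere & lung
    if (!any(hit)) stop("lesion sphere does not intersect the lung")
    lesion_mask <- lesion_mask | hit
    f_exp[hit] <- f_exp[hit] * (1 - les$severity)
    f_insp[hit] <- f_insp[hit] * (1 - les$severity)
    if (les$kind == "fibrosis" && les$airway_dilation_mm > 0) {
      dil <- cylinder_mask(n, sp, g$trachea$center,
                           g$trachea$radius + les$airway_dilation_mm,
                           c(g$trachea$carina_z, zmax_mm))
      trachea <- trachea | (dil & sphere)
    }
  }

  parenchyma <- lung & !trachea

  # compose noiseless HU fields; painting order fixes overlaps
  compose_hu <- function(f) {
    hu <- array(-1000, dim = n)            # background air
    hu[body] <- g$body$hu                  # soft tissue
    hu[parenchyma] <- -1000 * f[parenchyma]
    hu[water] <- 0
    hu[bone] <- g$bone$hu
    hu[trachea] <- -1000                   # pure air tube
    hu
  }
  hu_exp <- compose_hu(f_exp)
  hu_insp <- compose_hu(f_insp)

  # ground truth before noise
  carina_voxel <- nearest_voxel(
    c(g$trachea$center, g$trachea$carina_z), sp)
  z_sup <- min(n[3], carina_voxel[3] + as.integer(round(2 / sp)))
  zidx <- slice.index(trachea, 3L)
  trachea_in_roi <- trachea & (zidx <= z_sup)
  lung_true <- parenchyma | trachea_in_roi

  # air-fraction fields of the whole scene: f in parenchyma, 1 in airway
  as_air_field <- function(f) {
    f[!parenchyma] <- 0
    f[trachea] <- 1
    f
  }
  f_exp <- as_air_field(f_exp)
  f_insp <- as_air_field(f_insp)

  vv <- sp^3
  air_ml <- function(f) sum(f[lung_true]) * vv / 1000
  air_exp <- air_ml(f_exp)
  air_insp <- air_ml(f_insp)
  truth <- structure(
    list(lung_mask_true = lung_true,
         air_volume_expiration_ml = air_exp,
         air_volume_inspiration_ml = air_insp,
         frc_true_ml = air_exp,
         vt_true_ml = air_insp - air_exp,
         lesion_mask = lesion_mask,
         air_fraction_expiration_field = f_exp,
         air_fraction_inspiration_field = f_insp,
         parenchyma_mask = parenchyma,
         airway_in_roi_mask = trachea_in_roi),
    class = "phantom_truth")

  # calibration reference boxes; halfwidth keeps even box corners inside the
  # cylinder after the (<= spacing/2) snap of the centre to a voxel centre
  safe_halfwidth <- function(radius) {
    max(0L, as.integer(floor(radius / (sqrt(2) * sp) - 0.5)))
  }
  tube_halfwidth <- safe_halfwidth(g$trachea$radius)
  tc <- nearest_voxel(c(g$trachea$center, 0), sp)[1:2]
  z_top <- n[3] - 1L
  trachea_roi <- list(lo = c(tc - tube_halfwidth, min(z_sup + 3L, z_top - 8L)),
                      hi = c(tc + tube_halfwidth, z_top))
  wc <- nearest_voxel(c(g$water$center, mean(g$water$z)), sp)
  w_halfwidth <- safe_halfwidth(g$water$radius)
  w_halfz <- max(4L, as.integer(floor(0.3 * diff(range(g$water$z)) / sp)))
  water_roi <- list(lo = c(wc[1:2] - w_halfwidth, wc[3] - w_halfz),
                    hi = c(wc[1:2] + w_halfwidth, wc[3] + w_halfz))

  body_lo <- pmax(1L, nearest_voxel(c(g$body$center - g$body$radius, 0), sp))
  body_hi <- pmin(n, c(nearest_voxel(
    c(g$body$center + g$body$radius, 0), sp)[1:2], n[3]))
  meta <- list(carina_voxel = carina_voxel,
               trachea_roi = trachea_roi,
               water_roi = water_roi,
               body_bbox = list(lo = c(body_lo[1:2], 1L), hi = body_hi),
               seed_hint = nearest_voxel(g$seed_point, sp),
               spacing_mm = rep(sp, 3L))

  # emit raw-scale volumes, optionally noisy (noise added on the HU scale)
  slope <- (spec$raw_water_value - spec$raw_air_value) / 1000
  to_raw <- function(hu) spec$raw_water_value + slope * hu
  seeds <- derive_seeds(spec$seed, 2L)
  make_vol <- function(hu, phase, seed_i) {
    img <- volume_image(hu, sp, phase = phase, scale = "HU")
    if (spec$noise_sigma_hu > 0)
      img <- add_noise(img, spec$noise_sigma_hu, seed = seed_i)
    img$values <- to_raw(img$values)
    img$scale <- "raw"
    img
  }
  list(expiration = make_vol(hu_exp, "expiration", seeds[1]),
       inspiration = make_vol(hu_insp, "inspiration", seeds[2]),
       truth = truth, meta = meta)
}

#' Add Gaussian noise to a volume
#'
#' Additive zero-mean Gaussian perturbation with standard deviation
#' `sigma_hu`, expressed in the image's intensity units (HU for calibrated
#' volumes; [generate_phantom()] applies it on the HU scale before mapping to
#' raw grey values). Deterministic given `seed`.
#'
#' @param image a [volume_image()].
#' @param sigma_hu noise standard deviation, >= 0.
#' @param seed integer RNG seed.
#' @return The perturbed [volume_image()].
#' @export
add_noise <- function(image, sigma_hu, seed = 1L) {
  stopifnot(inherits(image, "volume_image"))
  if (sigma_hu < 0) stop("sigma_hu must be >= 0")
  if (sigma_hu == 0) return(image)
  noise <- withr::with_seed(seed,
    stats::rnorm(length(image$values), sd = sigma_hu))
  image$values <- image$values + array(noise, dim = dim(image$values))
  image
}
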