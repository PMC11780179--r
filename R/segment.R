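# Lung delineation: bounding ROI anchored 2 mm above the carina, seeded
# region growing at a fixed HU threshold, leak detection, and automatic
# ROI-shrink retries standing in for the manual ROI adjustment an operator
# would perform when the grown region escapes the lung.

#' Bounding ROI for lung segmentation
#'
#' Axis-aligned box whose superior face sits `round(2 mm / spacing_z)` voxel
#' planes above the carina (the standard analysis convention); lateral and
#' inferior faces default to the body extent. Boxes are 1-based inclusive
#' voxel index ranges.
#'
#' @param image a calibrated [volume_image()].
#' @param carina_voxel voxel index (length 3, 1-based) of the carina.
#' @param body_bbox optional list with `lo`/`hi` voxel corners bounding the
#'   body; defaults to the full grid.
#' @param superior_margin_mm distance above the carina included in the ROI
#'   (default 2 mm).
#' @return A list `lo`, `hi`, `carina_z` of class `bounding_roi`.
#' @export
define_lung_roi <- function(image, carina_voxel, body_bbox = NULL,
                            superior_margin_mm = 2) {
  stopifnot(inherits(image, "volume_image"), length(carina_voxel) == 3L)
  d <- dim(image$values)
  carina_voxel <- as.integer(carina_voxel)
  if (any(carina_voxel < 1L) || any(carina_voxel > d))
    stop("carina voxel outside the grid")
  offset <- as.integer(round(superior_margin_mm / image$spacing_mm[3]))
  z_sup <- carina_voxel[3] + offset
  if (z_sup > d[3]) {
    warning("superior ROI face clamped to the grid boundary")
    z_sup <- d[3]
  }
  if (is.null(body_bbox)) body_bbox <- list(lo = c(1L, 1L, 1L), hi = d)
  lo <- pmax(1L, as.integer(body_bbox$lo))
  hi <- pmin(d, as.integer(body_bbox$hi))
  hi[3] <- z_sup
  if (any(hi < lo)) stop("bounding ROI is empty")
  structure(list(lo = lo, hi = hi, carina_z = carina_voxel[3]),
            class = "bounding_roi")
}

roi_n_voxels <- function(roi) prod(roi$hi - roi$lo + 1L)

#' Seeded region growing at a fixed HU threshold
#'
#' Grows the maximal connected set of voxels with `HU <= threshold_hu`
#' containing the seed, restricted to the bounding ROI. The default threshold
#' of -160 HU separates aerated lung from soft tissue; the inclusive
#' comparison and the 26-neighbour default connectivity are fixed conventions.
#'
#' @param image a calibrated (HU-scale) [volume_image()].
#' @param seed_voxel voxel index (length 3, 1-based) inside the ROI with
#'   `HU <= threshold_hu`.
#' @param roi a [define_lung_roi()] box (or any `lo`/`hi` list).
#' @param threshold_hu inclusion threshold in HU (default -160).
#' @param connectivity 6 or 26 (default 26).
#' @return An object of class `lung_mask`: logical array `mask` plus the
#'   seed, threshold, ROI, connectivity, `leak_flag` and `retries` used.
#' @export
grow_lung <- function(image, seed_voxel, roi, threshold_hu = -160,
                      connectivity = 26) {
  stopifnot(inherits(image, "volume_image"))
  if (image$scale != "HU") stop("grow_lung expects a calibrated (HU) image")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  d <- dim(image$values)
  seed_voxel <- as.integer(seed_voxel)
  if (any(seed_voxel < roi$lo) || any(seed_voxel > roi$hi))
    stop("seed outside ROI")
  if (image$values[seed_voxel[1], seed_voxel[2], seed_voxel[3]] > threshold_hu)
    stop("seed not in lung-density range")
  m <- flood_fill3d_cpp(as.vector(image$values), as.integer(d), seed_voxel,
                        threshold_hu, as.integer(roi$lo), as.integer(roi$hi),
                        as.integer(connectivity))
  mask <- structure(
    list(mask = array(m, dim = d), seed_voxel = seed_voxel,
         threshold_hu = threshold_hu, roi = roi,
         connectivity = as.integer(connectivity),
         leak_flag = FALSE, retries = 0L),
    class = "lung_mask")
  mask$leak_flag <- detect_leak(mask, roi)
  mask
}

#' Detect probable segmentation leaks
#'
#' Flags a grown mask that likely escaped the lung: it touches more than
#' `max_faces` of the ROI faces (air path to the ROI boundary) or fills more
#' than `max_fill_fraction` of the ROI volume. A mask reaching only the
#' superior face through the proximal airway is expected and not flagged.
#'
#' @param mask a [grow_lung()] result.
#' @param roi the bounding ROI it was grown in.
#' @param max_faces maximum number of ROI faces the mask may touch (default 2).
#' @param max_fill_fraction maximum mask/ROI volume ratio (default 0.9).
#' @return Logical leak flag.
#' @export
detect_leak <- function(mask, roi, max_faces = 2L, max_fill_fraction = 0.9) {
  m <- mask$mask
  lo <- roi$lo; hi <- roi$hi
  faces <- c(any(m[lo[1], lo[2]:hi[2], lo[3]:hi[3]]),
             any(m[hi[1], lo[2]:hi[2], lo[3]:hi[3]]),
             any(m[lo[1]:hi[1], lo[2], lo[3]:hi[3]]),
             any(m[lo[1]:hi[1], hi[2], lo[3]:hi[3]]),
             any(m[lo[1]:hi[1], lo[2]:hi[2], lo[3]]),
             any(m[lo[1]:hi[1], lo[2]:hi[2], hi[3]]))
  sum(faces) > max_faces || sum(m) > max_fill_fraction * roi_n_voxels(roi)
}

#' Region growing with automatic ROI-shrink retries on leak
#'
#' Automates the operator's ROI adjustment: when the grown mask is flagged as
#' leaking, every ROI face the mask touches (except the superior face, whose
#' position is the anatomical convention) is moved inward by `step_mm` and the
#' region is re-grown, up to `max_retries` times. A still-leaking final mask
#' is returned with `leak_flag = TRUE` for manual review, not an error.
#'
#' @inheritParams grow_lung
#' @param step_mm face shrink step per retry in mm (default 0.5).
#' @param max_retries maximum number of re-grows (default 5).
#' @param ... passed to [detect_leak()].
#' @return A `lung_mask` whose `retries` field counts the re-grows performed.
#' @export
segment_with_retry <- function(image, seed_voxel, roi, threshold_hu = -160,
                               connectivity = 26, step_mm = 0.5,
                               max_retries = 5L, ...) {
  mask <- grow_lung(image, seed_voxel, roi, threshold_hu, connectivity)
  mask$leak_flag <- detect_leak(mask, roi, ...)
  retries <- 0L
  while (mask$leak_flag && retries < max_retries) {
    roi <- shrink_touched_faces(mask, roi, step_mm, image$spacing_mm)
    if (any(seed_voxel < roi$lo) || any(seed_voxel > roi$hi)) break
    retries <- retries + 1L
    mask <- grow_lung(image, seed_voxel, roi, threshold_hu, connectivity)
    mask$leak_flag <- detect_leak(mask, roi, ...)
  }
  mask$retries <- retries
  mask
}

# move each touched face (other than the superior face) inward by step_mm
shrink_touched_faces <- function(mask, roi, step_mm, spacing_mm) {
  m <- mask$mask
  lo <- roi$lo; hi <- roi$hi
  step <- pmax(1L, as.integer(round(step_mm / spacing_mm)))
  if (any(m[lo[1], lo[2]:hi[2], lo[3]:hi[3]])) lo[1] <- lo[1] + step[1]
  if (any(m[hi[1], lo[2]:hi[2], lo[3]:hi[3]])) hi[1] <- hi[1] - step[1]
  if (any(m[lo[1]:hi[1], lo[2], lo[3]:hi[3]])) lo[2] <- lo[2] + step[2]
  if (any(m[lo[1]:hi[1], hi[2], lo[3]:hi[3]])) hi[2] <- hi[2] - step[2]
  if (any(m[lo[1]:hi[1], lo[2]:hi[2], lo[3]])) lo[3] <- lo[3] + step[3]
  # superior face (hi[3]) is anatomically anchored; leave it in place
  if (any(hi < lo)) stop("ROI collapsed while retrying segmentation")
  structure(list(lo = lo, hi = hi, carina_z = roi$carina_z),
            class = "bounding_roi")
}

#' Automatic seed selection inside the ROI
#'
#' Batch-mode stand-in for the operator's manual seed: the voxel nearest the
#' centroid of the clearly aerated voxels (`HU < air_cutoff_hu`, default
#' -400) within the ROI.
#'
#' @inheritParams grow_lung
#' @param air_cutoff_hu cutoff defining clearly aerated voxels (default -400).
#' @return Voxel index (length 3) usable as `seed_voxel`.
#' @export
auto_seed <- function(image, roi, air_cutoff_hu = -400) {
  stopifnot(inherits(image, "volume_image"))
  sub <- image$values[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2],
                      roi$lo[3]:roi$hi[3]]
  idx <- which(sub < air_cutoff_hu, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no aerated voxels inside ROI")
  centroid <- colMeans(idx)
  d2 <- (idx[, 1] - centroid[1])^2 + (idx[, 2] - centroid[2])^2 +
    (idx[, 3] - centroid[3])^2
  as.integer(idx[which.min(d2), ]) + roi$lo - 1L
}
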