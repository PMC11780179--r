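# Lung-function metrics. From a segmented lung at each respiratory phase we
# measure the volume and mean CT number; air content follows from the linear
# air/tissue mixture relation, giving
#   FRC = V_exp  * CTexp  / CTair            (air volume at end-expiration)
#   VT  = V_insp * CTinsp / CTair - FRC      (air volume exchanged per breath)
# with CTair fixed at -1000 HU.

#' Measure lung volume and mean CT number within a mask
#'
#' @param image a calibrated (HU) [volume_image()].
#' @param mask a [grow_lung()] result (or any logical array of the same
#'   dimension).
#' @return An object of class `lung_measurement`: `phase`, `volume_ml`,
#'   `mean_ct_hu`, `voxel_count`, `leak_flag`.
#' @export
measure_lung <- function(image, mask) {
  stopifnot(inherits(image, "volume_image"))
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  leak <- if (inherits(mask, "lung_mask")) mask$leak_flag else FALSE
  stopifnot(identical(dim(m), dim(image$values)))
  nvox <- sum(m)
  if (nvox == 0L) stop("empty lung mask")
  structure(
    list(phase = image$phase,
         volume_ml = nvox * voxel_volume_mm3(image) / 1000,
         mean_ct_hu = mean(image$values[m]),
         voxel_count = nvox,
         leak_flag = leak),
    class = "lung_measurement")
}

#' Functional residual capacity from the end-expiration measurement
#'
#' `FRC = volume_ml * mean_ct_hu / ct_air_hu`, the air volume contained in
#' the segmented lung at end-expiration under the linear air/tissue mixture
#' model. A positive mean CT number (denser than water, outside the model)
#' triggers a warning but the raw value is returned.
#'
#' @param expiration a [measure_lung()] result at end-expiration.
#' @param ct_air_hu CT number of pure air (default -1000 HU).
#' @return FRC in mL.
#' @export
compute_frc <- function(expiration, ct_air_hu = -1000) {
  stopifnot(inherits(expiration, "lung_measurement"))
  if (ct_air_hu == 0) stop("ct_air_hu must be non-zero")
  if (ct_air_hu >= 0) stop("ct_air_hu must be negative")
  if (expiration$phase != "expiration")
    warning("computing FRC from a non-expiration measurement")
  if (expiration$mean_ct_hu > 0)
    warning("mean CT number above water: FRC outside the mixture model")
  expiration$volume_ml * expiration$mean_ct_hu / ct_air_hu
}

#' Tidal volume from the peak-inspiration measurement and FRC
#'
#' `VT = volume_ml * mean_ct_hu / ct_air_hu - FRC`. Negative values are
#' permitted but warned about: they usually indicate swapped phase labels.
#'
#' @param inspiration a [measure_lung()] result at peak inspiration.
#' @param frc_ml FRC from [compute_frc()].
#' @inheritParams compute_frc
#' @return VT in mL.
#' @export
compute_vt <- function(inspiration, frc_ml, ct_air_hu = -1000) {
  stopifnot(inherits(inspiration, "lung_measurement"))
  if (ct_air_hu == 0) stop("ct_air_hu must be non-zero")
  if (ct_air_hu >= 0) stop("ct_air_hu must be negative")
  if (inspiration$phase != "inspiration")
    warning("computing VT from a non-inspiration measurement")
  vt <- inspiration$volume_ml * inspiration$mean_ct_hu / ct_air_hu - frc_ml
  if (is.finite(vt) && vt < 0)
    warning("negative tidal volume: possible phase misassignment")
  vt
}

#' CT-number histogram within the lung
#'
#' Counts over half-open bins `[e_i, e_{i+1})` spanning `range`; values
#' outside the range are clipped into the end bins, so counts always sum to
#' the masked voxel count (or to 1 when normalized).
#'
#' @inheritParams measure_lung
#' @param bin_width_hu bin width in HU (default 25).
#' @param range histogram range in HU (default `c(-1000, 200)`).
#' @param normalize normalize counts to unit sum (default `FALSE`).
#' @return An object of class `ct_histogram`: `bin_edges_hu`, `counts`,
#'   `mids_hu`, `phase`, `normalized`.
#' @export
ct_histogram <- function(image, mask, bin_width_hu = 25,
                         range = c(-1000, 200), normalize = FALSE) {
  stopifnot(inherits(image, "volume_image"))
  if (bin_width_hu <= 0) stop("bin width must be positive")
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  v <- image$values[m]
  if (length(v) == 0L) stop("empty lung mask")
  edges <- seq(range[1], range[2], by = bin_width_hu)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  # clip into end bins, then half-open binning [e_i, e_{i+1})
  v <- pmin(pmax(v, edges[1]), edges[length(edges)] - bin_width_hu / 1e6)
  bin <- findInterval(v, edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  if (normalize) counts <- counts / sum(counts)
  structure(
    list(bin_edges_hu = edges, counts = counts,
         mids_hu = (edges[-1] + edges[-length(edges)]) / 2,
         phase = image$phase, normalized = normalize),
    class = "ct_histogram")
}

#' Mean of a CT-number histogram
#'
#' Count-weighted mean of the bin midpoints; a density increase in the lung
#' shifts it toward 0 HU.
#'
#' @param h a [ct_histogram()].
#' @return Mean CT number in HU.
#' @export
histogram_mean <- function(h) {
  stopifnot(inherits(h, "ct_histogram"))
  sum(h$mids_hu * h$counts) / sum(h$counts)
}

metric_cols <- c("volume_ml", "mean_ct_hu", "frc_ml", "vt_ml")

#' Per-animal change between two study weeks
#'
#' For every animal with measurements at both weeks, the change
#' `value(week_b) - value(week_a)` in volume (each phase), mean CT number,
#' FRC and VT; negative values indicate a reduction at the later week.
#' Animals missing either week are dropped with a message.
#'
#' @param study a study table as produced by [run_study()]: long-format rows
#'   of `animal_id, group, week, phase, volume_ml, mean_ct_hu, frc_ml, vt_ml`.
#' @param week_a baseline week (default 12).
#' @param week_b follow-up week; `"endpoint"` (default) resolves per animal
#'   to its latest week.
#' @return A tibble with one row per animal and phase, columns
#'   `delta_<metric>` and `pct_<metric>` (per-animal percent change).
#' @export
longitudinal_change <- function(study, week_a = 12, week_b = "endpoint") {
  study <- tibble::as_tibble(study)
  a <- dplyr::filter(study, .data$week == week_a)
  if (identical(week_b, "endpoint")) {
    b <- study |>
      dplyr::group_by(.data$animal_id) |>
      dplyr::filter(.data$week == max(.data$week), .data$week > week_a) |>
      dplyr::ungroup()
  } else {
    b <- dplyr::filter(study, .data$week == week_b)
  }
  joined <- dplyr::inner_join(
    a, b, by = c("animal_id", "group", "phase"), suffix = c("_a", "_b"))
  dropped <- setdiff(unique(study$animal_id), unique(joined$animal_id))
  if (length(dropped) > 0)
    message(length(dropped), " animal(s) lacked both weeks and were dropped")
  if (nrow(joined) == 0L) stop("no animal has measurements at both weeks")
  out <- joined |>
    dplyr::transmute(
      .data$animal_id, .data$group, .data$phase,
      week_a = .data$week_a, week_b = .data$week_b)
  for (m in metric_cols) {
    va <- joined[[paste0(m, "_a")]]
    vb <- joined[[paste0(m, "_b")]]
    out[[paste0("delta_", m)]] <- vb - va
    out[[paste0("pct_", m)]] <- 100 * (vb - va) / va
  }
  out
}

#' Percent change of group means between two weeks
#'
#' The group-level summary statistic: percent change of the group mean of a
#' metric between `week_a` and `week_b` (complete-case per week, matching
#' survivor-only averaging), reported with the per-week group sizes.
#'
#' @inheritParams longitudinal_change
#' @param metric one of `"volume_ml"`, `"mean_ct_hu"`, `"frc_ml"`, `"vt_ml"`.
#' @param phase restrict to one respiratory phase (default `"expiration"`;
#'   irrelevant for `frc_ml`/`vt_ml`, which repeat across phases).
#' @return A tibble with one row per group: means at both weeks, group sizes
#'   and `pct_change`.
#' @export
group_percent_change <- function(study, metric = "frc_ml", week_a = 12,
                                 week_b = "endpoint", phase = "expiration") {
  metric <- match.arg(metric, metric_cols)
  study <- tibble::as_tibble(study)
  study <- dplyr::filter(study, .data$phase == !!phase)
  if (identical(week_b, "endpoint")) {
    ends <- study |>
      dplyr::group_by(.data$animal_id) |>
      dplyr::summarise(week_b = max(.data$week), .groups = "drop") |>
      dplyr::filter(.data$week_b > week_a)
    b <- dplyr::inner_join(study, ends,
                           by = dplyr::join_by(animal_id, week == week_b))
  } else {
    b <- dplyr::filter(study, .data$week == week_b)
  }
  a <- dplyr::filter(study, .data$week == week_a)
  summarise_grp <- function(d, nm) {
    d |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise("mean_{nm}" := mean(.data[[metric]]),
                       "n_{nm}" := dplyr::n(), .groups = "drop")
  }
  res <- dplyr::inner_join(summarise_grp(a, "a"), summarise_grp(b, "b"),
                           by = "group")
  if (nrow(res) == 0L) stop("no group has data at both weeks")
  res$pct_change <- 100 * (res$mean_b - res$mean_a) / res$mean_a
  res$metric <- metric
  res
}
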