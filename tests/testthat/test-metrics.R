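# Volume / CT-number measurement, FRC and VT, histograms, longitudinal change.

mask_of <- function(d, where = TRUE) {
  m <- array(FALSE, d); m[where] <- TRUE; m
}

test_that("measure_lung computes volume and mean CT exactly", {
  arr <- array(-700, c(10, 10, 10))
  img <- volume_image(arr, 0.075, phase = "expiration", scale = "HU")
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1] <- TRUE  # 100 voxels
  meas <- measure_lung(img, m)
  expect_equal(meas$volume_ml, 100 * 0.075^3 / 1000)
  expect_equal(meas$mean_ct_hu, -700)
  # 1000 voxels at 0.075 mm
  m2 <- array(FALSE, c(10, 10, 10)); m2[, , 1:10] <- TRUE
  expect_equal(measure_lung(img, m2)$volume_ml, 1000 * 0.075^3 / 1000)
  expect_equal(measure_lung(img, m2)$volume_ml, 4.21875e-4)
  # half -600 / half -800 averages to -700
  arr3 <- array(rep(c(-600, -800), 500), c(10, 10, 10))
  expect_equal(measure_lung(volume_image(arr3, 0.075, scale = "HU"),
                            m2)$mean_ct_hu, -700)
  expect_error(measure_lung(img, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("FRC follows volume * meanCT / CTair exactly", {
  mk <- function(vol_ml, ct, phase = "expiration") {
    structure(list(phase = phase, volume_ml = vol_ml, mean_ct_hu = ct,
                   voxel_count = 1L, leak_flag = FALSE),
              class = "lung_measurement")
  }
  expect_equal(compute_frc(mk(0.5, -1000)), 0.5)     # pure-air limit
  expect_equal(compute_frc(mk(0.5, 0)), 0)           # water limit
  expect_equal(compute_frc(mk(0.5, -600)), 0.30)     # mixed
  expect_error(compute_frc(mk(0.5, -600), ct_air_hu = 0), "non-zero")
  expect_error(compute_frc(mk(0.5, -600), ct_air_hu = 500), "negative")
  expect_warning(compute_frc(mk(0.5, 100)), "above water")
  expect_warning(compute_frc(mk(0.5, -600, phase = "inspiration")),
                 "non-expiration")
})

test_that("VT subtracts FRC from the inspiration air content", {
  mk <- function(vol_ml, ct) {
    structure(list(phase = "inspiration", volume_ml = vol_ml,
                   mean_ct_hu = ct, voxel_count = 1L, leak_flag = FALSE),
              class = "lung_measurement")
  }
  # identical phases: VT = 0
  expect_equal(compute_vt(mk(0.5, -600), frc_ml = 0.30), 0)
  expect_equal(compute_vt(mk(0.7, -650), frc_ml = 0.30), 0.7 * 0.65 - 0.30)
  expect_equal(compute_vt(mk(0.7, -650), frc_ml = 0.30), 0.155)
  expect_warning(v <- compute_vt(mk(0.4, -500), frc_ml = 0.30), "negative")
  expect_lt(v, 0)
})

test_that("FRC and VT are exact on the phantom through the full pipeline", {
  ph <- tiny_phantom(grid_n = 64)
  row <- run_subject(ph, run_config())
  expect_lt(abs(row$frc_ml[1] - ph$truth$frc_true_ml) / ph$truth$frc_true_ml,
            1e-9)
  expect_lt(abs(row$vt_ml[1] - ph$truth$vt_true_ml) / ph$truth$vt_true_ml,
            1e-9)
  # bounds implied by masked HU in [-1000, 0]
  expect_gte(row$frc_ml[1], 0)
  expect_lte(row$frc_ml[1], row$volume_ml[row$phase == "expiration"])
  expect_lte(row$frc_ml[1] + row$vt_ml[1],
             row$volume_ml[row$phase == "inspiration"])
})

test_that("CT histograms conserve counts, clip, and normalize", {
  arr <- array(-700, c(6, 6, 6))
  img <- volume_image(arr, 0.1, phase = "expiration", scale = "HU")
  m <- mask_of(c(6, 6, 6))
  h <- ct_histogram(img, m)
  expect_equal(sum(h$counts), 216)
  expect_equal(sum(h$counts > 0), 1)                       # single bin
  expect_equal(h$mids_hu[which(h$counts > 0)], -687.5)     # [-700, -675)
  hn <- ct_histogram(img, m, normalize = TRUE)
  expect_equal(sum(hn$counts), 1)
  # out-of-range values are clipped into the end bins
  arr2 <- array(c(-2000, 500, -300, -300, -300, -300), c(6, 6, 6))
  img2 <- volume_image(arr2, 0.1, scale = "HU")
  h2 <- ct_histogram(img2, m)
  expect_equal(sum(h2$counts), 216)
  expect_gt(h2$counts[1], 0)
  expect_gt(h2$counts[length(h2$counts)], 0)
  expect_true(all(diff(h2$bin_edges_hu) > 0))
  expect_error(ct_histogram(img, m, bin_width_hu = 0), "positive")
})

test_that("lesions shift the histogram mean toward 0 HU by the imposed amount", {
  clean <- tiny_phantom(grid_n = 48)
  les <- tiny_phantom(grid_n = 48, lesions = list(
    lesion_spec("fibrosis", severity = 0.5, radius_mm = 1.2)))
  cfg <- run_config()
  img_c <- rescale_to_hu(clean$expiration, calibration_refs(10, 1510))
  img_l <- rescale_to_hu(les$expiration, calibration_refs(10, 1510))
  mask <- clean$truth$lung_mask_true
  h_c <- ct_histogram(img_c, mask, bin_width_hu = 5)
  h_l <- ct_histogram(img_l, mask, bin_width_hu = 5)
  shift <- histogram_mean(h_l) - histogram_mean(h_c)
  # expected shift: lesion voxels go from -450 to -225 HU
  n_les <- sum(les$truth$lesion_mask & les$truth$parenchyma_mask)
  expected <- 225 * n_les / sum(mask)
  expect_gt(shift, 0)
  expect_equal(shift, expected, tolerance = 0.02)
})

make_study <- function() {
  tibble::tibble(
    animal_id = rep(c("a1", "a2"), each = 4),
    group = "g",
    week = rep(c(12, 12, 24, 24), 2),
    phase = rep(c("expiration", "inspiration"), 4),
    volume_ml = c(0.5, 0.7, 0.4, 0.6, 0.5, 0.7, 0.5, 0.7),
    mean_ct_hu = -500,
    frc_ml = c(0.30, 0.30, 0.15, 0.15, 0.30, 0.30, 0.30, 0.30),
    vt_ml = 0.1)
}

test_that("longitudinal change computes per-animal deltas with the sign convention", {
  st <- make_study()
  d <- longitudinal_change(st, week_a = 12, week_b = 24)
  a1e <- d[d$animal_id == "a1" & d$phase == "expiration", ]
  expect_equal(a1e$delta_frc_ml, -0.15)
  expect_equal(a1e$pct_frc_ml, -50)
  expect_equal(a1e$delta_volume_ml, -0.1)
  a2 <- d[d$animal_id == "a2" & d$phase == "expiration", ]
  expect_equal(a2$delta_frc_ml, 0)
  expect_equal(a2$delta_vt_ml, 0)
  # an animal missing the baseline week is dropped with a message
  st2 <- dplyr::bind_rows(st, tibble::tibble(
    animal_id = "a3", group = "g", week = 24, phase = "expiration",
    volume_ml = 1, mean_ct_hu = -500, frc_ml = 0.2, vt_ml = 0.1))
  expect_message(d2 <- longitudinal_change(st2, 12, 24), "dropped")
  expect_false("a3" %in% d2$animal_id)
  expect_error(longitudinal_change(st[st$week == 12, ], 12, 24), "no animal")
})

test_that("group percent change uses group means with endpoint resolution", {
  st <- make_study()
  pc <- group_percent_change(st, "frc_ml", week_a = 12, week_b = "endpoint")
  expect_equal(pc$pct_change, 100 * (mean(c(0.15, 0.30)) - 0.30) / 0.30)
  expect_equal(pc$n_a, 2L)
  pc2 <- group_percent_change(st, "vt_ml", week_a = 12, week_b = 24)
  expect_equal(pc2$pct_change, 0)
  expect_error(group_percent_change(st[st$week == 12, ], "frc_ml", 12, 24),
               "no group")
})
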