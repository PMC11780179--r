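# Phantom generator: ground-truth consistency, lesion behaviour, noise model.

test_that("phantom truth equals brute-force summation over the air-fraction fields", {
  ph <- tiny_phantom(grid_n = 48)
  tr <- ph$truth
  vv <- prod(ph$expiration$spacing_mm)
  expect_identical(tr$frc_true_ml, tr$air_volume_expiration_ml)
  expect_equal(tr$vt_true_ml,
               tr$air_volume_inspiration_ml - tr$air_volume_expiration_ml)
  # independent recomputation: sum the generated fraction fields over the
  # true lung region
  expect_equal(sum(tr$air_fraction_expiration_field[tr$lung_mask_true]) *
                 vv / 1000, tr$air_volume_expiration_ml, tolerance = 1e-12)
  expect_equal(sum(tr$air_fraction_inspiration_field[tr$lung_mask_true]) *
                 vv / 1000, tr$air_volume_inspiration_ml, tolerance = 1e-12)
  # closed form: parenchyma at constant fraction + pure-air airway voxels
  n_par <- sum(tr$parenchyma_mask)
  n_air <- sum(tr$airway_in_roi_mask)
  expect_equal(tr$frc_true_ml, (n_par * 0.45 + n_air) * vv / 1000,
               tolerance = 1e-12)
})

test_that("noiseless lung voxels follow HU = -1000 * air fraction through the raw anchors", {
  ph <- tiny_phantom(grid_n = 40)
  img <- rescale_to_hu(ph$expiration, calibration_refs(10, 1510))
  par <- ph$truth$parenchyma_mask
  expect_equal(unique(round(img$values[par], 9)), -450)
  expect_equal(unique(round(img$values[ph$truth$airway_in_roi_mask], 9)), -1000)
})

test_that("phase ordering and spec invariants are enforced", {
  ph <- tiny_phantom(grid_n = 40)
  expect_gte(ph$truth$air_volume_inspiration_ml,
             ph$truth$air_volume_expiration_ml)
  expect_gte(ph$truth$vt_true_ml, 0)
  expect_error(phantom_spec(air_fraction_expiration = 0.6,
                            air_fraction_inspiration = 0.6),
               "must exceed")
  expect_error(phantom_spec(air_fraction_expiration = 1.2,
                            air_fraction_inspiration = 1.3), "air fractions")
  expect_error(phantom_spec(noise_sigma_hu = -1), "noise")
  expect_error(phantom_spec(raw_air_value = 5, raw_water_value = 5), "differ")
})

test_that("a fibrosis lesion removes exactly its enclosed parenchymal air", {
  clean <- tiny_phantom(grid_n = 48)
  les <- lesion_spec("fibrosis", center_mm = c(3.5, 4.8, 4.0),
                     radius_mm = 1.2, severity = 1)
  lesioned <- tiny_phantom(grid_n = 48, lesions = list(les))
  vv <- prod(clean$expiration$spacing_mm)
  hit <- lesioned$truth$lesion_mask & lesioned$truth$parenchyma_mask
  removed <- sum(clean$truth$air_fraction_expiration_field[hit]) * vv / 1000
  expect_equal(clean$truth$frc_true_ml - lesioned$truth$frc_true_ml, removed,
               tolerance = 1e-12)
  # severity scales the removal linearly: severity 0.5 removes half as much
  half <- tiny_phantom(grid_n = 48, lesions = list(
    lesion_spec("fibrosis", center_mm = c(3.5, 4.8, 4.0), radius_mm = 1.2,
                severity = 0.5)))
  expect_equal(clean$truth$frc_true_ml - half$truth$frc_true_ml, removed / 2,
               tolerance = 1e-12)
})

test_that("increasing lesion severity never increases true FRC or VT", {
  sev <- c(0, 0.25, 0.5, 0.75, 1)
  truths <- lapply(sev, function(s) {
    lesions <- if (s > 0) list(lesion_spec("fibrosis", severity = s)) else list()
    tiny_phantom(grid_n = 40, lesions = lesions)$truth
  })
  frc <- vapply(truths, function(t) t$frc_true_ml, 1.0)
  vt <- vapply(truths, function(t) t$vt_true_ml, 1.0)
  expect_true(all(diff(frc) <= 1e-12))
  expect_true(all(diff(vt) <= 1e-12))
})

test_that("lesions outside the lung are rejected", {
  les <- lesion_spec("pneumonitis", center_mm = c(0.5, 0.5, 0.5),
                     radius_mm = 0.3)
  expect_error(tiny_phantom(grid_n = 40, lesions = list(les)),
               "does not intersect")
  expect_error(lesion_spec("pneumonitis", severity = 1.2), "severity")
  expect_error(lesion_spec("pneumonitis", airway_dilation_mm = 0.2),
               "fibrosis")
})

test_that("fibrosis airway dilation enlarges the airway within the lesion", {
  les_plain <- lesion_spec("fibrosis", center_mm = c(4.4, 4.8, 5.6),
                           radius_mm = 1.0, severity = 0.5)
  les_dil <- lesion_spec("fibrosis", center_mm = c(4.4, 4.8, 5.6),
                         radius_mm = 1.0, severity = 0.5,
                         airway_dilation_mm = 0.3)
  a <- tiny_phantom(grid_n = 64, lesions = list(les_plain))
  b <- tiny_phantom(grid_n = 64, lesions = list(les_dil))
  expect_gt(sum(b$truth$airway_in_roi_mask), sum(a$truth$airway_in_roi_mask))
})

test_that("add_noise is deterministic, zero-safe and calibrated", {
  img <- volume_image(array(0, c(50, 50, 50)), 0.1, scale = "HU")
  expect_identical(add_noise(img, 0, seed = 5), img)
  n1 <- add_noise(img, 25, seed = 42)
  n2 <- add_noise(img, 25, seed = 42)
  expect_identical(n1$values, n2$values)
  n3 <- add_noise(img, 25, seed = 43)
  expect_false(identical(n1$values, n3$values))
  # 1.25e5 voxels: sample SD within 5% of nominal
  expect_lt(abs(sd(n1$values) - 25) / 25, 0.05)
  expect_lt(abs(mean(n1$values)), 1)
  expect_error(add_noise(img, -1), "sigma")
})

test_that("generate_cohort is reproducible and respects the design", {
  groups <- list(cohort_group("control", n = 2),
                 cohort_group("treated", n = 2, f_scale_by_week = c("18" = 0.5)))
  c1 <- generate_cohort(groups, weeks = c(12, 18), seed = 7, grid_n = 32)
  c2 <- generate_cohort(groups, weeks = c(12, 18), seed = 7, grid_n = 32)
  expect_equal(nrow(c1$manifest), 2 * 2 * 2)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$subjects[[3]]$phantom$expiration$values,
                   c2$subjects[[3]]$phantom$expiration$values)
  # imposed halving of aeration halves true FRC up to the airway contribution
  frc12 <- sapply(c1$subjects, function(s)
    if (s$group == "treated" && s$week == 12) s$phantom$truth$frc_true_ml else NA)
  frc18 <- sapply(c1$subjects, function(s)
    if (s$group == "treated" && s$week == 18) s$phantom$truth$frc_true_ml else NA)
  ratio <- mean(frc18, na.rm = TRUE) / mean(frc12, na.rm = TRUE)
  expect_lt(abs(ratio - 0.5), 0.05)
  expect_error(generate_cohort(groups[1], weeks = 12), "2 groups")
  expect_error(cohort_group("x", n = 1), "n >= 2")
})
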