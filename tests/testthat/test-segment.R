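# ROI construction, seeded region growing, leak detection and retry.

hu_image <- function(arr, spacing = 0.1) {
  volume_image(arr, spacing, scale = "HU")
}

test_that("ROI superior face sits round(2 mm / spacing) planes above the carina", {
  img75 <- hu_image(array(-500, c(64, 64, 128)), spacing = 0.075)
  roi <- define_lung_roi(img75, c(32, 32, 60))
  expect_equal(roi$hi[3] - roi$carina_z, 27)   # round(2 / 0.075)
  img100 <- hu_image(array(-500, c(40, 40, 80)), spacing = 0.1)
  roi2 <- define_lung_roi(img100, c(20, 20, 40))
  expect_equal(roi2$hi[3] - roi2$carina_z, 20) # round(2 / 0.1)
  # carina near the grid top: clamped with a warning
  expect_warning(roi3 <- define_lung_roi(img100, c(20, 20, 78)), "clamped")
  expect_equal(roi3$hi[3], 80)
  expect_error(define_lung_roi(img100, c(20, 20, 90)), "outside the grid")
})

test_that("region growing reproduces the hand-computed 4x4 flood fill", {
  m <- rbind(c(-500, -500,    0, -500),
             c(-500,    0,    0, -500),
             c(   0,    0,    0,    0),
             c(-500, -500, -500, -500))
  img <- hu_image(array(m, c(4, 4, 1)))
  mask <- grow_lung(img, c(1, 1, 1), full_roi(c(4, 4, 1)),
                    threshold_hu = -160, connectivity = 6)
  expected <- array(FALSE, c(4, 4, 1))
  expected[1, 1, 1] <- expected[1, 2, 1] <- expected[2, 1, 1] <- TRUE
  expect_identical(mask$mask, expected)
})

test_that("uniform ROI saturates; bad seeds error", {
  img <- hu_image(array(-700, c(10, 10, 10)))
  roi <- structure(list(lo = c(2L, 2L, 2L), hi = c(9L, 9L, 9L),
                        carina_z = NA), class = "bounding_roi")
  mask <- grow_lung(img, c(5, 5, 5), roi)
  expect_equal(sum(mask$mask), 8^3)
  img2 <- hu_image(array(-100, c(10, 10, 10)))
  expect_error(grow_lung(img2, c(5, 5, 5), roi), "lung-density")
  expect_error(grow_lung(img, c(1, 1, 1), roi), "seed outside ROI")
  raw <- volume_image(array(-700, c(10, 10, 10)), 0.1, scale = "raw")
  expect_error(grow_lung(raw, c(5, 5, 5), roi), "calibrated")
})

test_that("region growing matches the igraph oracle on random grids", {
  withr::with_seed(101, {
    for (i in 1:12) {
      d <- sample(8:24, 3, replace = TRUE)
      arr <- array(runif(prod(d), -1000, 500), dim = d)
      conn <- if (i %% 2 == 0) 6L else 26L
      thr <- runif(1, -600, 0)
      cand <- which(arr <= thr, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      seedv <- cand[sample(nrow(cand), 1), ]
      mask <- grow_lung(hu_image(arr), seedv, full_roi(d),
                        threshold_hu = thr, connectivity = conn)
      ref <- oracle_flood_fill(arr, seedv, thr, c(1, 1, 1), d, conn)
      expect_identical(mask$mask, ref)
    }
  })
})

test_that("growing is idempotent from any voxel of the result", {
  withr::with_seed(11, arr <- array(runif(16^3, -1000, 400), rep(16, 3)))
  img <- hu_image(arr)
  cand <- which(arr <= -160, arr.ind = TRUE)
  seedv <- cand[1, ]
  mask <- grow_lung(img, seedv, full_roi(rep(16, 3)))
  inside <- which(mask$mask, arr.ind = TRUE)
  withr::with_seed(12, picks <- sample(nrow(inside), 5))
  for (i in picks) {
    again <- grow_lung(img, inside[i, ], full_roi(rep(16, 3)))
    expect_identical(again$mask, mask$mask)
  }
})

test_that("masks are monotone in the threshold", {
  withr::with_seed(13, arr <- array(runif(16^3, -1000, 400), rep(16, 3)))
  arr[8, 8, 8] <- -900
  img <- hu_image(arr)
  prev <- NULL
  for (thr in c(-700, -400, -160, -50)) {
    mask <- grow_lung(img, c(8, 8, 8), full_roi(rep(16, 3)),
                      threshold_hu = thr)$mask
    if (!is.null(prev)) expect_true(all(mask[prev]))
    prev <- mask
  }
})

test_that("leak detection counts ROI faces and fill fraction", {
  d <- c(12, 12, 12)
  roi <- full_roi(d)
  interior <- array(FALSE, d); interior[4:8, 4:8, 4:8] <- TRUE
  expect_false(detect_leak(structure(list(mask = interior),
                                     class = "lung_mask"), roi))
  full <- array(TRUE, d)
  expect_true(detect_leak(structure(list(mask = full),
                                    class = "lung_mask"), roi))
  three <- array(FALSE, d)
  three[1, 6, 6] <- three[6, 1, 6] <- three[6, 6, 1] <- TRUE   # 3 faces
  expect_true(detect_leak(structure(list(mask = three),
                                    class = "lung_mask"), roi))
  two <- array(FALSE, d)
  two[1, 6, 6] <- two[6, 1, 6] <- TRUE                          # 2 faces
  expect_false(detect_leak(structure(list(mask = two),
                                     class = "lung_mask"), roi))
})

test_that("retry shrinks the leaking faces and resolves a near-face channel", {
  d <- c(40, 40, 40)
  arr <- array(40, d)                      # body
  arr[1:3, , ] <- -800                     # outside-body air slab at x-lo
  arr[4:10, 20, 20] <- -800                # thin channel into the lung
  arr[11:30, 10:30, 5:30] <- -500          # lung blob
  img <- hu_image(arr, spacing = 0.1)
  roi <- structure(list(lo = c(1L, 1L, 1L), hi = c(40L, 40L, 35L),
                        carina_z = 15L), class = "bounding_roi")
  naive <- grow_lung(img, c(20, 20, 18), roi)
  expect_true(naive$leak_flag)
  fixed <- segment_with_retry(img, c(20, 20, 18), roi, step_mm = 0.5)
  expect_false(fixed$leak_flag)
  expect_equal(fixed$retries, 1L)
  expect_false(any(fixed$mask[1:3, , ]))   # slab excluded after shrink
  expect_true(all(fixed$mask[12:29, 11:29, 6:29]))

  # non-leaking case: retry output identical to plain growing, 0 retries
  arr2 <- array(40, d); arr2[11:30, 10:30, 5:30] <- -500
  img2 <- hu_image(arr2, spacing = 0.1)
  plain <- grow_lung(img2, c(20, 20, 18), roi)
  same <- segment_with_retry(img2, c(20, 20, 18), roi)
  expect_identical(same$mask, plain$mask)
  expect_equal(same$retries, 0L)

  # unresolvable: air everywhere fills the ROI however the faces shrink
  img3 <- hu_image(array(-700, d), spacing = 0.1)
  flagged <- segment_with_retry(img3, c(20, 20, 18), roi, max_retries = 3)
  expect_true(flagged$leak_flag)
  expect_equal(flagged$retries, 3L)
})

test_that("auto_seed lands in clearly aerated lung on the phantom", {
  ph <- tiny_phantom(grid_n = 48)
  img <- rescale_to_hu(ph$expiration, calibration_refs(10, 1510))
  roi <- define_lung_roi(img, ph$meta$carina_voxel, ph$meta$body_bbox)
  sv <- auto_seed(img, roi)
  expect_lt(img$values[sv[1], sv[2], sv[3]], -400)
  expect_true(ph$truth$lung_mask_true[sv[1], sv[2], sv[3]])
})

test_that("phantom segmentation recovers the true lung exactly (noise-free)", {
  ph <- tiny_phantom(grid_n = 64)
  img <- rescale_to_hu(ph$expiration, calibration_refs(10, 1510))
  roi <- define_lung_roi(img, ph$meta$carina_voxel, ph$meta$body_bbox)
  mask <- grow_lung(img, auto_seed(img, roi), roi)
  expect_equal(dice(mask$mask, ph$truth$lung_mask_true), 1)
  expect_false(mask$leak_flag)
})
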