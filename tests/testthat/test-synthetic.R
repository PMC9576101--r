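test_that("an undistorted noise-free scan reproduces predicted HU exactly", {
  scan <- generate_scan(tiny_scene(true_energy = 70), lib)
  for (m in c("air", "adipose", "blood", "cortical_bone")) {
    lab <- scan$truth$label[match(m, scan$truth$material)]
    expect_equal(mean(scan$image[scan$mask == lab]),
                 predicted_hu(m, 70, lib), tolerance = 1e-12, label = m)
  }
})

test_that("scans are bit-identical under the same seed, masks invariant under noise", {
  sc <- tiny_scene(noise_sd = 5, seed = 123)
  s1 <- generate_scan(sc, lib)
  s2 <- generate_scan(sc, lib)
  expect_identical(as.vector(s1$image), as.vector(s2$image))
  sc2 <- sc; sc2$seed <- 456L
  s3 <- generate_scan(sc2, lib)
  expect_identical(as.vector(s1$mask), as.vector(s3$mask))
  expect_false(identical(as.vector(s1$image), as.vector(s3$image)))
  # region means stay within 4 standard errors of the ideal value
  for (i in seq_len(nrow(s1$truth))) {
    n <- sum(s1$mask == s1$truth$label[i])
    se <- 5 / sqrt(n)
    expect_lt(abs(mean(s3$image[s3$mask == s1$truth$label[i]]) -
                    s1$truth$ideal_hu[i]), 4 * se)
  }
})

test_that("fat infiltration interpolates between pure muscle and pure adipose", {
  mk <- function(f) generate_scan(scan_scenario(list(
    ct_region(1, "skeletal_muscle", center = c(8, 8, 2), size = c(6, 6, 2),
              fat_fraction = f)), true_energy = 70, dim = c(16, 16, 3)), lib)
  hu0 <- mk(0)$truth$ideal_hu
  hu1 <- mk(1)$truth$ideal_hu
  expect_equal(hu0, predicted_hu("skeletal_muscle", 70, lib))
  expect_equal(hu1, predicted_hu("adipose", 70, lib))
  ff <- seq(0, 1, by = 0.2)
  hus <- vapply(ff, function(f) mk(f)$truth$ideal_hu, numeric(1))
  expect_true(all(diff(hus) < 0))   # monotone from muscle down to adipose
})

test_that("overlapping regions are rejected", {
  sc <- scan_scenario(list(
    ct_region(1, "air", center = c(8, 8, 2), size = c(8, 8, 2)),
    ct_region(2, "blood", center = c(10, 8, 2), size = c(8, 8, 2))),
    dim = c(24, 24, 3))
  expect_error(generate_scan(sc, lib), "overlap", class = "qct_input_error")
  expect_error(scan_scenario(list(
    ct_region(1, "air", center = c(4, 4, 2), size = c(2, 2, 2)),
    ct_region(1, "blood", center = c(9, 4, 2), size = c(2, 2, 2)))),
    "unique", class = "qct_input_error")
})

test_that("a condition battery varies raw HU but not geometry or ground truth", {
  battery <- generate_condition_battery(tiny_scene(), materials = lib)
  expect_equal(nrow(battery$conditions), 10)
  masks <- lapply(battery$scans, function(s) as.vector(s$mask))
  expect_true(all(vapply(masks, identical, logical(1), masks[[1]])))
  truths <- lapply(battery$scans, `[[`, "truth")
  expect_true(all(vapply(truths, identical, logical(1), truths[[1]])))
  muscle_lab <- battery$truth$label[battery$truth$name == "sample_05"]
  raw <- vapply(battery$scans, function(s)
    mean(s$image[s$mask == muscle_lab]), numeric(1))
  expect_gt(diff(range(raw)), 10)   # conditions really move the raw HU
})

test_that("sphere regions rasterise within their radius", {
  sc <- scan_scenario(list(
    ct_region(1, "blood", shape = "sphere", center = c(8, 8, 4), radius = 3)),
    dim = c(16, 16, 8), spacing = c(1, 1, 1))
  scan <- generate_scan(sc, lib)
  idx <- which(as.vector(scan$mask) == 1)
  expect_gt(length(idx), 50)
  coords <- arrayInd(idx, dim(scan$mask))
  d <- sqrt(rowSums((sweep(coords, 2, c(8, 8, 4)))^2))
  expect_true(all(d <= 3 + 1e-9))
})

test_that("scenario validation catches bad parameters", {
  r <- list(ct_region(1, "air", center = c(4, 4, 2), size = c(2, 2, 2)))
  expect_error(scan_scenario(r, hu_gain = 0), class = "qct_input_error")
  expect_error(scan_scenario(r, noise_sd = -1), class = "qct_input_error")
  expect_error(ct_region(1, "air", density = 1, center = c(1, 1, 1),
                         size = c(2, 2, 2)), class = "qct_input_error")
  expect_error(ct_region(1, "air", center = c(1, 1, 1), size = c(2, 2, 2),
                         fat_fraction = 2), class = "qct_input_error")
})
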