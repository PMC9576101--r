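subset_cases <- list(
  c("air", "adipose"),
  c("air", "blood"),
  c("air", "adipose", "blood"),
  c("air", "adipose", "blood", "skeletal_muscle", "cortical_bone"))

test_that("effective energy and densities round-trip from noise-free forward ROIs", {
  for (E0 in c(50, 70, 90, 120)) {
    for (mats in subset_cases) {
      cal <- internal_calibration(forward_rois(mats, E0), lib)
      expect_lt(abs(cal$effective_energy - E0), 0.02,
                label = sprintf("E* at E0=%g, {%s}", E0, paste(mats, collapse = ",")))
      for (m in c("adipose", "blood", "skeletal_muscle")) {
        got <- predict(cal, predicted_hu(m, E0, lib))
        expect_equal(got, weq_density(m, E0), tolerance = 1e-6,
                     label = sprintf("density of %s at E0=%g via {%s}", m, E0,
                                     paste(mats, collapse = ",")))
      }
    }
  }
})

test_that("round trip also holds at randomly drawn energies in 40-140 keV", {
  set.seed(7)
  for (E0 in runif(4, 40, 140)) {
    cal <- internal_calibration(forward_rois(c("air", "adipose", "blood"), E0), lib)
    expect_lt(abs(cal$effective_energy - E0), 0.02)
    expect_equal(predict(cal, predicted_hu("skeletal_muscle", E0, lib)),
                 weq_density("skeletal_muscle", E0), tolerance = 1e-6)
  }
})

test_that("two-ROI fit interpolates both materials to machine precision", {
  E0 <- 70
  rois <- forward_rois(c("air", "adipose"), E0)
  fit <- fit_hu_to_attenuation(rois, E0, lib)
  for (m in c("air", "adipose"))
    expect_equal(fit$slope * predicted_hu(m, E0, lib) + fit$intercept,
                 linear_attenuation(lib[[m]], E0), tolerance = 1e-12)
  expect_equal(unname(fit$residuals_hu), c(0, 0), tolerance = 1e-9)
})

test_that("the >=3-ROI OLS fit coincides with the 2-ROI fit on collinear data", {
  E0 <- 85
  fit5 <- fit_hu_to_attenuation(forward_rois(
    c("air", "adipose", "blood", "skeletal_muscle", "cortical_bone"), E0), E0, lib)
  fit2 <- fit_hu_to_attenuation(forward_rois(c("air", "adipose"), E0), E0, lib)
  expect_equal(fit5$slope, fit2$slope, tolerance = 1e-9)
  expect_equal(fit5$intercept, fit2$intercept, tolerance = 1e-9)
  expect_true(all(abs(fit5$residuals_hu) < 1e-6))
})

test_that("degenerate ROI sets are rejected", {
  expect_error(estimate_effective_energy(roi_sample("air", -1000), lib),
               class = "qct_degenerate_error")
  air2 <- roi_samples(roi_sample("air", -1000), roi_sample("water", 0))
  expect_error(estimate_effective_energy(air2, lib), "insensitive",
               class = "qct_degenerate_error")
  expect_error(estimate_effective_energy(NULL, lib), class = "qct_input_error")
  same_hu <- roi_samples(roi_sample("adipose", 50), roi_sample("blood", 50))
  expect_error(fit_hu_to_attenuation(same_hu, 70, lib),
               class = "qct_singular_error")
  expect_error(
    internal_calibration(roi_samples(roi_sample("skeletal_muscle", 55)), lib),
    class = "qct_degenerate_error")
})

test_that("affine HU miscalibration leaves densities unchanged for >=3-ROI sets", {
  set.seed(11)
  E0 <- 70
  mats <- list(c("air", "adipose", "blood"),
               c("air", "adipose", "blood", "skeletal_muscle", "cortical_bone"))
  hu_probe <- predicted_hu("skeletal_muscle", E0, lib)
  for (ms in mats) {
    ref <- predict(internal_calibration(forward_rois(ms, E0), lib), hu_probe)
    for (i in 1:5) {
      g <- runif(1, 0.9, 1.1); o <- runif(1, -40, 40)
      cal <- internal_calibration(forward_rois(ms, E0, gain = g, offset = o), lib)
      got <- predict(cal, g * hu_probe + o)
      expect_equal(got, ref, tolerance = 1e-6,
                   label = sprintf("gain %.3f offset %.1f {%s}", g, o,
                                   paste(ms, collapse = ",")))
    }
  }
})

test_that("a pure HU offset is absorbed exactly by the air anchor in 2-ROI sets", {
  E0 <- 70
  hu_probe <- predicted_hu("skeletal_muscle", E0, lib)
  ref <- predict(internal_calibration(forward_rois(c("air", "adipose"), E0), lib),
                 hu_probe)
  for (o in c(-25, -5, 10, 30)) {
    cal <- internal_calibration(
      forward_rois(c("air", "adipose"), E0, offset = o), lib)
    expect_equal(predict(cal, hu_probe + o), ref, tolerance = 1e-6)
    expect_lt(abs(cal$effective_energy - E0), 0.02)
  }
})

test_that("small ROI noise perturbs the estimate continuously across seeds", {
  E0 <- 70
  base <- forward_rois(c("air", "adipose", "blood", "skeletal_muscle",
                         "cortical_bone"), E0)
  hu_probe <- predicted_hu("skeletal_muscle", E0, lib)
  energies <- numeric(100); dens <- numeric(100)
  for (s in 1:100) {
    set.seed(s)
    rois <- base
    rois$mean_hu <- rois$mean_hu + rnorm(nrow(rois), 0, 0.5)
    cal <- internal_calibration(rois, lib)
    energies[s] <- cal$effective_energy
    dens[s] <- predict(cal, hu_probe)
  }
  expect_true(all(is.finite(energies)))
  expect_lt(diff(range(energies)), 5)          # no discontinuous jumps
  expect_lt(diff(range(dens)), 0.01)           # bounded density spread (g/cm^3)
  expect_lt(abs(mean(dens) - weq_density("skeletal_muscle", E0)), 0.005)
})

test_that("density conversion maps water-like HU to 1 g/cm^3 and air to ~0", {
  E0 <- 70
  cal <- internal_calibration(forward_rois(c("air", "adipose", "blood"), E0), lib)
  expect_equal(predict(cal, predicted_hu("water", E0, lib)), 1.0,
               tolerance = 1e-6)
  air_vol <- hu_volume(array(-1000, c(4, 4, 2)))
  d <- predict(cal, air_vol)
  expect_s3_class(d, "density_volume")
  expect_true(all(abs(d) < 0.01))
  expect_identical(dim(d), dim(air_vol))
})

test_that("full image calibration recovers generator ground truth", {
  scan <- generate_scan(tiny_scene(true_energy = 70), lib)
  res <- internal_calibrate(scan$image, scan$mask, scan$roi_map,
                            c("air", "adipose"), materials = lib)
  truth <- scan$truth
  for (i in seq_len(nrow(truth))) {
    got <- mean(res$density[scan$mask == truth$label[i]])
    if (truth$density_weq[i] > 0.1)   # air region is ~0; compare tissues
      expect_equal(got, truth$density_weq[i], tolerance = 1e-6,
                   label = truth$name[i])
  }
  expect_s3_class(res$calibration, "internal_calibration")
  expect_error(
    internal_calibrate(scan$image, scan$mask, scan$roi_map, c("air", "iron")),
    "iron", class = "qct_input_error")
})

test_that("roi_stats aggregates by mean or median and flags absent labels", {
  img <- hu_volume(array(c(rep(10, 8), rep(100, 8)), c(4, 2, 2)))
  mask <- label_volume(array(c(rep(1L, 8), rep(2L, 8)), c(4, 2, 2)))
  rs <- roi_stats(img, mask, list("1" = "adipose", "2" = "blood"))
  expect_equal(rs$mean_hu, c(10, 100))
  expect_equal(rs$n_voxels, c(8L, 8L))
  img2 <- img; img2[1] <- 1000
  rs_med <- roi_stats(img2, mask, list("1" = "adipose"), aggregate = "median")
  expect_equal(rs_med$mean_hu, 10)   # median ignores the outlier voxel
  expect_error(roi_stats(img, mask, list("7" = "air")), "7",
               class = "qct_input_error")
})

test_that("fitted + residuals reconstruct the ROI means and coef returns the map", {
  cal <- internal_calibration(forward_rois(c("air", "adipose", "blood"), 80), lib)
  expect_equal(unname(fitted(cal) + residuals(cal)), cal$rois$mean_hu)
  expect_named(coef(cal), c("slope", "intercept"))
  expect_gt(coef(cal)[["slope"]], 0)
  expect_output(print(summary(cal)), "residuals")
})
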