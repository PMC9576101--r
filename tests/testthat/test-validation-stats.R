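test_that("Bland-Altman handles identical and constant-shift pairs exactly", {
  x <- c(1.01, 1.03, 1.05, 1.08)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_halfwidth, 0)
  ba <- bland_altman(x + 0.01, x)
  expect_equal(ba$bias, 0.01)
  expect_equal(ba$loa_halfwidth, 0)
  expect_equal(ba$loa_low, ba$loa_high)
})

test_that("Bland-Altman bias is antisymmetric and LOA reflect on swapping", {
  set.seed(3)
  x <- rnorm(12, 1.06, 0.01); y <- x + rnorm(12, -0.004, 0.002)
  a <- bland_altman(x, y); b <- bland_altman(y, x)
  expect_equal(a$bias, -b$bias)
  expect_equal(a$loa_low, -b$loa_high)
  expect_equal(a$loa_high, -b$loa_low)
  expect_equal(a$loa_halfwidth, b$loa_halfwidth)
})

test_that("Bland-Altman bias estimates a known simulated bias at n = 10", {
  set.seed(99)
  biases <- replicate(300, {
    y <- rnorm(10, 1.06, 0.01)
    x <- y + rnorm(10, -0.004, 0.002)
    bland_altman(x, y)$bias
  })
  expect_lt(abs(mean(biases) - (-0.004)), 3 * 0.002 / sqrt(10 * 300) * 10)
  expect_error(bland_altman(1:3, 1:4), class = "qct_input_error")
  expect_error(bland_altman(1, 1), class = "qct_input_error")
})

test_that("CV is zero for constant series, scale-invariant, and rejects bad means", {
  m <- matrix(rep(c(55, 60), each = 5), nrow = 2, byrow = TRUE)
  cv <- cv_across_conditions(m)
  expect_equal(cv$cv_pct, c(0, 0))
  expect_equal(mean_cv(cv), 0)
  set.seed(5)
  m2 <- matrix(rnorm(40, 60, 3), nrow = 4)
  expect_equal(cv_across_conditions(3.7 * m2)$cv_pct,
               cv_across_conditions(m2)$cv_pct)
  # permutation of conditions leaves the CV unchanged
  expect_equal(cv_across_conditions(m2[, sample(10)])$cv_pct,
               cv_across_conditions(m2)$cv_pct)
  expect_error(cv_across_conditions(matrix(c(-5, 1, 2, 2), 2)),
               class = "qct_value_error")
  expect_error(cv_across_conditions(matrix(1, 1, 1)), class = "qct_input_error")
})

test_that("regression comparison returns exact coefficients on exact lines", {
  x <- c(1.01, 1.04, 1.06, 1.09)
  r1 <- regression_compare(x, x)
  expect_equal(r1$slope, 1); expect_equal(r1$intercept, 0)
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)
  r2 <- regression_compare(x, 2 * x + 1)
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 1)
  expect_equal(r2$r_squared, 1, tolerance = 1e-12)
  expect_error(regression_compare(rep(1, 5), rnorm(5)),
               class = "qct_singular_error")
  expect_error(regression_compare(1:2, 1:2), class = "qct_input_error")
})

test_that("internal and phantom densities correlate tightly on a noisy battery", {
  scene <- tiny_scene(true_energy = 70, seed = 21)
  battery <- generate_condition_battery(
    scene, default_condition_battery(noise_sd = 2), materials = lib)
  phantom <- attr(scene, "phantom")
  samples <- attr(scene, "sample_labels")
  pairs <- lapply(battery$scans, function(s) {
    int <- internal_calibrate(s$image, s$mask, s$roi_map,
                              c("air", "adipose", "blood"), materials = lib)
    ph <- phantom_calibrate(s$image, s$mask, phantom)
    cbind(vapply(samples, function(l) mean(int$density[s$mask == l]), numeric(1)),
          vapply(samples, function(l) mean(ph$density[s$mask == l]), numeric(1)))
  })
  all_pairs <- do.call(rbind, pairs)
  reg <- regression_compare(all_pairs[, 2], all_pairs[, 1])
  expect_gt(reg$r_squared, 0.99)
  expect_lt(abs(percent_method_difference(all_pairs[, 2], all_pairs[, 1])), 1)
})

test_that("supplementary density tables load from long and wide layouts", {
  long <- data.frame(sample = rep(sprintf("S%02d", 1:3), each = 4),
                     condition = rep(c("c1", "c2"), 6),
                     method = rep(c("Internal", "Sucrose phantom"), each = 2),
                     value = runif(12, 1.0, 1.1))
  p_long <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, p_long, row.names = FALSE)
  got <- load_supplementary_densities(p_long)
  expect_named(got, c("sample", "condition", "method", "value"))
  expect_setequal(unique(got$method), c("internal", "sucrose_phantom"))
  expect_equal(nrow(got), 12)

  wide <- data.frame(sample = sprintf("S%02d", 1:3), method = "HU",
                     c1 = rnorm(3, 57, 5), c2 = rnorm(3, 57, 5))
  p_wide <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, p_wide, row.names = FALSE)
  got_w <- load_supplementary_densities(p_wide)
  expect_equal(nrow(got_w), 6)
  expect_true(all(got_w$method == "HU"))
  expect_setequal(unique(got_w$condition), c("c1", "c2"))

  # round trip: exporting the long table and re-loading reproduces it
  p_rt <- withr::local_tempfile(fileext = ".csv")
  write.csv(got, p_rt, row.names = FALSE)
  expect_equal(load_supplementary_densities(p_rt), got)
})

test_that("schema violations are reported with what was found", {
  p_bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(foo = 1:3, bar = letters[1:3]), p_bad, row.names = FALSE)
  expect_error(load_supplementary_densities(p_bad), "foo, bar",
               class = "qct_schema_error")
  expect_error(load_supplementary_densities("does-not-exist.xlsx"),
               class = "qct_input_error")
})
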