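#' Region of a synthetic scan scenario
#'
#' A homogeneous material region placed on the voxel grid. Regions are
#' axis-aligned boxes or spheres. A region is either a named reference
#' material (optionally with a fat-infiltration volume fraction mixing
#' muscle-like tissue with adipose) or an explicit water-like density
#' (attenuation modelled as water's mu/rho scaled by that density, the model
#' used for dilute sucrose solutions).
#'
#' @param label positive integer mask label, unique within a scenario.
#' @param material reference material name, or `NULL` when `density` is
#'   given.
#' @param density explicit water-like density in g/cm^3 (sucrose vials), or
#'   `NULL` when `material` is given.
#' @param shape `"box"` or `"sphere"`.
#' @param center voxel-index centre (length 3, 1-based, may be fractional).
#' @param size box edge lengths in voxels (length 3; boxes only).
#' @param radius sphere radius in voxels (spheres only).
#' @param fat_fraction volume fraction in `[0, 1]` of adipose mixed into the
#'   region's linear attenuation (fat infiltration); material regions only.
#' @param name optional region name used in the ground-truth table.
#' @return object of class `ct_region`.
#' @export
ct_region <- function(label, material = NULL, density = NULL,
                      shape = c("box", "sphere"), center, size = NULL,
                      radius = NULL, fat_fraction = 0, name = NULL) {
  shape <- match.arg(shape)
  if (is.null(material) == is.null(density))
    qct_stop("give exactly one of 'material' or 'density'", "qct_input_error")
  if (!is.null(density) && density <= 0)
    qct_stop("explicit region density must be positive", "qct_input_error")
  if (fat_fraction < 0 || fat_fraction > 1)
    qct_stop("fat_fraction must be in [0, 1]", "qct_input_error")
  if (shape == "box" && (is.null(size) || length(size) != 3))
    qct_stop("box regions need a length-3 'size'", "qct_input_error")
  if (shape == "sphere" && is.null(radius))
    qct_stop("sphere regions need a 'radius'", "qct_input_error")
  if (label < 1 || label != round(label))
    qct_stop("region labels are positive integers", "qct_input_error")
  if (is.null(name))
    name <- if (!is.null(material)) material else sprintf("density_%g", density)
  structure(list(label = as.integer(label), material = material,
                 density = density, shape = shape, center = center,
                 size = size, radius = radius, fat_fraction = fat_fraction,
                 name = name),
            class = "ct_region")
}

#' Synthetic scan scenario
#'
#' Describes a digital scan with known ground truth: material regions imaged
#' at a true effective energy `true_energy`, then distorted by a
#' scanner-condition affine HU miscalibration (`hu_gain`, `hu_offset`) plus
#' additive Gaussian noise. The (gain, offset, noise) triple is the
#' emulation of scan-protocol and bore-position effects on HU.
#'
#' @param regions list of [ct_region()]s (non-overlapping).
#' @param true_energy true effective energy E0 in keV.
#' @param hu_gain multiplicative HU distortion (> 0).
#' @param hu_offset additive HU distortion.
#' @param noise_sd additive Gaussian noise SD in HU (>= 0).
#' @param seed integer RNG seed for the voxel noise.
#' @param dim grid dimensions in voxels (length 3).
#' @param spacing voxel spacing in mm.
#' @return object of class `scan_scenario`.
#' @export
scan_scenario <- function(regions, true_energy = 70, hu_gain = 1,
                          hu_offset = 0, noise_sd = 0, seed = 1L,
                          dim = c(48, 48, 4), spacing = c(1, 1, 2)) {
  if (!length(regions) || !all(vapply(regions, inherits, logical(1), "ct_region")))
    qct_stop("'regions' must be a non-empty list of ct_region objects",
             "qct_input_error")
  labels <- vapply(regions, `[[`, integer(1), "label")
  if (anyDuplicated(labels))
    qct_stop("region labels must be unique", "qct_input_error")
  if (hu_gain <= 0) qct_stop("hu_gain must be positive", "qct_input_error")
  if (noise_sd < 0) qct_stop("noise_sd must be >= 0", "qct_input_error")
  structure(list(regions = regions, true_energy = true_energy,
                 hu_gain = hu_gain, hu_offset = hu_offset,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 dim = as.integer(dim), spacing = spacing),
            class = "scan_scenario")
}

# voxel linear indices covered by a region
.region_voxels <- function(region, dm) {
  if (region$shape == "box") {
    half <- region$size / 2
    rng <- lapply(1:3, function(a) {
      i <- seq(ceiling(region$center[a] - half[a]),
               floor(region$center[a] + half[a] - 1e-9))
      i[i >= 1 & i <= dm[a]]
    })
    if (any(lengths(rng) == 0)) return(integer(0))
    idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  } else {
    lim <- lapply(1:3, function(a) {
      i <- seq(floor(region$center[a] - region$radius),
               ceiling(region$center[a] + region$radius))
      i[i >= 1 & i <= dm[a]]
    })
    idx <- as.matrix(expand.grid(lim[[1]], lim[[2]], lim[[3]]))
    d2 <- (idx[, 1] - region$center[1])^2 + (idx[, 2] - region$center[2])^2 +
      (idx[, 3] - region$center[3])^2
    idx <- idx[d2 <= region$radius^2, , drop = FALSE]
  }
  if (!nrow(idx)) return(integer(0))
  idx[, 1] + (idx[, 2] - 1) * dm[1] + (idx[, 3] - 1) * dm[1] * dm[2]
}

# ideal HU and water-equivalent density of a region at energy E0
.region_truth <- function(region, E0, materials) {
  mu_w <- linear_attenuation(materials$water, E0)
  mu_a <- linear_attenuation(materials$air, E0)
  if (!is.null(region$density)) {
    mu <- region$density * mass_attenuation(materials$water, E0)
    mass_density <- region$density
  } else {
    if (!region$material %in% names(materials))
      qct_stop(sprintf("unknown region material '%s'", region$material),
               "qct_input_error")
    f <- region$fat_fraction
    mu <- (1 - f) * linear_attenuation(materials[[region$material]], E0) +
      f * linear_attenuation(materials$adipose, E0)
    mass_density <- (1 - f) * materials[[region$material]]$rho_ref +
      f * materials$adipose$rho_ref
  }
  list(ideal_hu = 1000 * (mu - mu_w) / (mu_w - mu_a),
       density_weq = mu / mass_attenuation(materials$water, E0),
       mass_density = mass_density)
}

#' Generate a synthetic CT scan with ground truth
#'
#' Rasterises the scenario's regions, computes each region's ideal HU at the
#' true effective energy (water/air-anchored definition; fat-infiltrated
#' regions use voxel-wise linear-attenuation mixing), applies the affine HU
#' miscalibration and per-voxel Gaussian noise (reproducible under the
#' scenario seed), and tabulates the ground truth.
#'
#' @param scenario a [scan_scenario()].
#' @param materials a [material_library()].
#' @return list with `image` ([hu_volume()]), `mask` ([label_volume()]),
#'   `truth` (data frame: label, name, material, fat_fraction, ideal_hu,
#'   density_weq, mass_density) and `roi_map` (label -> material, for the
#'   pure material regions).
#' @export
generate_scan <- function(scenario, materials = material_library()) {
  stopifnot(inherits(scenario, "scan_scenario"))
  dm <- scenario$dim
  mask <- integer(prod(dm))
  ideal <- numeric(prod(dm))
  rows <- list()
  for (region in scenario$regions) {
    vox <- .region_voxels(region, dm)
    if (!length(vox))
      qct_stop(sprintf("region '%s' (label %d) covers no voxels",
                       region$name, region$label), "qct_input_error")
    if (any(mask[vox] != 0))
      qct_stop(sprintf("region '%s' (label %d) overlaps another region",
                       region$name, region$label), "qct_input_error")
    tr <- .region_truth(region, scenario$true_energy, materials)
    mask[vox] <- region$label
    ideal[vox] <- tr$ideal_hu
    rows[[length(rows) + 1]] <- data.frame(
      label = region$label, name = region$name,
      material = if (is.null(region$material)) NA_character_ else region$material,
      fat_fraction = region$fat_fraction, ideal_hu = tr$ideal_hu,
      density_weq = tr$density_weq, mass_density = tr$mass_density,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  stored <- scenario$hu_gain * ideal + scenario$hu_offset
  if (scenario$noise_sd > 0) {
    runif(1)  # ensure .Random.seed exists before we save/restore it
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(scenario$seed)
    stored <- stored + rnorm(length(stored), 0, scenario$noise_sd)
  }
  pure <- truth[!is.na(truth$material) & truth$fat_fraction == 0, ]
  roi_map <- setNames(as.list(pure$material), pure$label)
  list(image = hu_volume(array(stored, dm), scenario$spacing),
       mask = label_volume(array(mask, dm), scenario$spacing),
       truth = truth, roi_map = roi_map)
}

#' Generate a battery of scans under varying scan conditions
#'
#' Re-images the same scenario geometry (identical mask and ground truth)
#' under a list of HU distortion conditions, emulating the repeat-scan
#' design of two protocols at five bore positions.
#'
#' @param scenario a [scan_scenario()]; its own gain/offset/noise are
#'   replaced per condition.
#' @param conditions data frame with columns `gain`, `offset`, `noise_sd`
#'   (>= 2 rows); defaults to [default_condition_battery()].
#' @param materials a [material_library()].
#' @return list with `scans` (one [generate_scan()] result per condition),
#'   `conditions`, `truth` (shared ground truth).
#' @export
generate_condition_battery <- function(scenario,
                                       conditions = default_condition_battery(),
                                       materials = material_library()) {
  if (nrow(conditions) < 2)
    qct_stop("a condition battery needs >= 2 conditions", "qct_input_error")
  scans <- lapply(seq_len(nrow(conditions)), function(i) {
    sc <- scenario
    sc$hu_gain <- conditions$gain[i]
    sc$hu_offset <- conditions$offset[i]
    sc$noise_sd <- conditions$noise_sd[i]
    sc$seed <- scenario$seed + i
    generate_scan(sc, materials)
  })
  list(scans = scans, conditions = conditions, truth = scans[[1]]$truth)
}

#' Default 10-condition scan battery
#'
#' Two protocol-like gain levels crossed with five position-like HU offsets
#' (2 x 5 = 10 conditions), with gains inside \[0.93, 1.07\] and offsets
#' inside \[-30, 30\] HU. Noise-free by default.
#'
#' @param gains two gain levels.
#' @param offsets five offset levels in HU.
#' @param noise_sd Gaussian HU noise SD applied to every condition.
#' @return data frame with columns `condition`, `gain`, `offset`,
#'   `noise_sd`.
#' @export
default_condition_battery <- function(gains = c(0.95, 1.05),
                                      offsets = seq(-30, 30, length.out = 5),
                                      noise_sd = 0) {
  g <- expand.grid(offset = offsets, gain = gains)
  data.frame(condition = seq_len(nrow(g)), gain = g$gain, offset = g$offset,
             noise_sd = noise_sd)
}

#' Default synthetic scan scenario
#'
#' A desk-scale digital stand-in for the validation scan setup: one region
#' each of air, adipose, blood and cortical bone (the internal-calibration
#' ROIs), `n_samples` muscle sample regions spanning a range of fat
#' infiltration, and five water-like sucrose vials at the phantom densities
#' 1.00, 1.01, 1.04, 1.06 and 1.11 g/cm^3. All regions are axis-aligned
#' boxes on a 64 x 52 x 4 grid.
#'
#' @param n_samples number of muscle sample regions.
#' @param fat_range range of fat volume fractions spanned by the samples.
#' @param true_energy true effective energy E0 in keV.
#' @param seed scenario seed.
#' @param ... further arguments to [scan_scenario()]
#'   (`hu_gain`, `hu_offset`, `noise_sd`).
#' @return a [scan_scenario()]. The vial labels/densities are in attribute
#'   `phantom` and the muscle sample labels in attribute `sample_labels`.
#' @export
default_scan_scenario <- function(n_samples = 10, fat_range = c(0, 0.27),
                                  true_energy = 70, seed = 1L, ...) {
  sucrose <- c(1.00, 1.01, 1.04, 1.06, 1.11)
  cell <- function(r, c) c(6 + 12 * (c - 1) + 4, 6 + 12 * (r - 1) + 4, 2.5)
  regions <- list(
    ct_region(1, "air", center = cell(1, 1), size = c(8, 8, 4)),
    ct_region(2, "adipose", center = cell(1, 2), size = c(8, 8, 4)),
    ct_region(3, "blood", center = cell(1, 3), size = c(8, 8, 4)),
    ct_region(4, "cortical_bone", center = cell(1, 4), size = c(8, 8, 4)))
  fat <- seq(fat_range[1], fat_range[2], length.out = n_samples)
  for (i in seq_len(n_samples)) {
    r <- 2 + (i - 1) %/% 5
    c <- 1 + (i - 1) %% 5
    regions[[length(regions) + 1]] <- ct_region(
      4 + i, "skeletal_muscle", center = cell(r, c), size = c(8, 8, 4),
      fat_fraction = fat[i], name = sprintf("sample_%02d", i))
  }
  for (j in seq_along(sucrose))
    regions[[length(regions) + 1]] <- ct_region(
      4 + n_samples + j, density = sucrose[j], center = cell(4, j),
      size = c(8, 8, 4), name = sprintf("vial_%d", j))
  sc <- scan_scenario(regions, true_energy = true_energy, seed = seed,
                      dim = c(64, 52, 4), ...)
  attr(sc, "phantom") <- list(vial_labels = 4 + n_samples + seq_along(sucrose),
                              known_values = sucrose, units = "g/cm^3")
  attr(sc, "sample_labels") <- 4 + seq_len(n_samples)
  sc
}
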