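#' ROI measurement summary
#'
#' One region of interest summarised by its material identity and HU
#' statistics. A set of ROIs is a data frame with one row per region.
#'
#' @param material material name (must exist in the material library used
#'   downstream).
#' @param mean_hu mean HU over the ROI voxels.
#' @param sd_hu HU standard deviation (>= 0).
#' @param n_voxels voxel count (>= 1).
#' @return one-row data frame of class `roi_samples`.
#' @export
roi_sample <- function(material, mean_hu, sd_hu = 0, n_voxels = 1L) {
  if (!is.finite(mean_hu)) qct_stop("mean_hu must be finite", "qct_input_error")
  if (sd_hu < 0) qct_stop("sd_hu must be >= 0", "qct_input_error")
  if (n_voxels < 1) qct_stop("n_voxels must be >= 1", "qct_input_error")
  structure(data.frame(material = as.character(material), mean_hu = mean_hu,
                       sd_hu = sd_hu, n_voxels = as.integer(n_voxels),
                       stringsAsFactors = FALSE),
            class = c("roi_samples", "data.frame"))
}

#' Combine ROI samples
#' @param ... `roi_samples` rows (or data frames with the same columns).
#' @return a `roi_samples` data frame.
#' @export
roi_samples <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  structure(out, class = c("roi_samples", "data.frame"))
}

.check_rois <- function(rois, materials) {
  if (is.null(rois) || NROW(rois) == 0)
    qct_stop("empty ROI list", "qct_input_error")
  req <- c("material", "mean_hu")
  if (!all(req %in% names(rois)))
    qct_stop("ROI samples need 'material' and 'mean_hu' columns", "qct_input_error")
  missing <- setdiff(rois$material, names(materials))
  if (length(missing))
    qct_stop(sprintf("ROI material(s) not in the material library: %s",
                     paste(missing, collapse = ", ")), "qct_input_error")
  rois
}

#' Summarise ROI statistics from an image and a label mask
#'
#' @param image an [hu_volume()].
#' @param mask a [label_volume()] aligned to the same grid.
#' @param roi_map named character vector or list mapping mask label (name,
#'   as character) to material name, e.g. `c("1" = "air", "2" = "adipose")`.
#' @param aggregate `"mean"` (conventional QCT practice, the default) or
#'   `"median"` for the per-ROI HU location statistic.
#' @return a `roi_samples` data frame with one row per mapped label.
#' @export
roi_stats <- function(image, mask, roi_map, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!identical(dim(image), dim(mask)))
    qct_stop("image and mask grids differ", "qct_input_error")
  labels <- as.integer(names(roi_map))
  if (anyNA(labels))
    qct_stop("roi_map names must be integer mask labels", "qct_input_error")
  present <- unique(as.vector(mask))
  absent <- setdiff(labels, present)
  if (length(absent))
    qct_stop(sprintf("mask is missing label(s) %s (materials: %s)",
                     paste(absent, collapse = ", "),
                     paste(unlist(roi_map)[as.character(absent)], collapse = ", ")),
             "qct_input_error")
  loc <- if (aggregate == "mean") mean else median
  rows <- lapply(seq_along(labels), function(i) {
    v <- image[mask == labels[i]]
    roi_sample(unlist(roi_map)[[i]], loc(v),
               if (length(v) > 1) sd(v) else 0, length(v))
  })
  do.call(roi_samples, rows)
}

# predicted HU for each ROI material at each energy (rows = rois)
.predicted_hu_matrix <- function(rois, materials, energies) {
  vapply(energies, function(e)
    vapply(rois$material, function(m)
      predicted_hu(materials[[m]], e, materials), numeric(1)),
    numeric(nrow(rois)))
}

#' Estimate the effective scan energy from ROI measurements
#'
#' The effective energy E* is the single photon energy at which the reference
#' materials' predicted HU best match the measured ROI HU. Two selection
#' criteria are available:
#'
#' * `"r2"` — maximise the coefficient of determination of the affine fit of
#'   linear attenuation mu(E) on measured HU across the ROIs. This criterion
#'   is exactly invariant under affine HU miscalibration (gain and offset),
#'   which is what makes the method robust across scan protocols and bore
#'   positions; it needs at least 3 ROIs (with 2 the fit is always perfect).
#' * `"sse"` — minimise the sum of squared differences between measured and
#'   predicted HU. When an air ROI is present, all measured HUs are first
#'   shifted so that measured air sits at its defining value of -1000 HU,
#'   anchoring the scanner offset; this is the criterion used for 2-ROI sets
#'   (air plus one tissue), where it is exact under offset miscalibration.
#'
#' The default `"auto"` uses `"r2"` when 3 or more ROIs are supplied and
#' `"sse"` otherwise. The search is a 1-keV grid scan over `energy_range`
#' (ties broken toward the lower energy) followed by golden-section
#' refinement well below 0.01 keV.
#'
#' @param rois a `roi_samples` data frame (>= 2 distinct materials; at least
#'   one must be energy-sensitive, i.e. not air or water).
#' @param materials a [material_library()].
#' @param energy_range numeric length-2 search window in keV (within the
#'   tabulated range).
#' @param objective `"auto"`, `"r2"` or `"sse"`.
#' @return list of class `energy_estimate` with elements `energy` (keV),
#'   `objective`, `value` (objective value at the optimum).
#' @export
estimate_effective_energy <- function(rois, materials = material_library(),
                                      energy_range = c(30, 200),
                                      objective = c("auto", "r2", "sse")) {
  objective <- match.arg(objective)
  rois <- .check_rois(rois, materials)
  if (length(unique(rois$material)) < 2)
    qct_stop("effective-energy estimation needs >= 2 ROIs of distinct materials",
             "qct_degenerate_error")
  lo <- max(energy_range[1], min(materials$water$curve$energies))
  hi <- min(energy_range[2], max(materials$water$curve$energies))
  if (!(hi > lo)) qct_stop("empty energy search range", "qct_input_error")

  grid <- unique(c(lo, seq(ceiling(lo), floor(hi), by = 1), hi))
  P <- .predicted_hu_matrix(rois, materials, grid)   # rois x energies
  sensitive <- apply(P, 1, function(p) diff(range(p)) > 1e-9)
  if (!any(sensitive))
    qct_stop("all supplied ROIs are energy-insensitive (air/water only); the effective energy is unidentifiable",
             "qct_degenerate_error")

  if (objective == "auto") objective <- if (nrow(rois) >= 3) "r2" else "sse"
  if (objective == "r2" && nrow(rois) < 3)
    qct_stop("the r2 objective is degenerate with fewer than 3 ROIs; use objective = 'sse'",
             "qct_degenerate_error")

  h <- rois$mean_hu
  if (objective == "sse" && "air" %in% rois$material)
    h <- h + (-1000 - h[match("air", rois$material)])

  obj <- if (objective == "sse") {
    function(e) {
      p <- vapply(seq_len(nrow(rois)), function(i)
        predicted_hu(materials[[rois$material[i]]], e, materials), numeric(1))
      sum((h - p)^2)
    }
  } else {
    function(e) {
      mu <- vapply(rois$material, function(m)
        linear_attenuation(materials[[m]], e), numeric(1))
      r <- suppressWarnings(cor(h, mu))
      if (!is.finite(r)) return(1)
      1 - r^2
    }
  }

  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)                       # first minimum = lowest energy
  bracket <- c(max(lo, grid[i] - 1), min(hi, grid[i] + 1))
  opt <- optimize(obj, interval = bracket, tol = 1e-6)
  # keep the grid point if refinement did not improve (flat objective)
  if (vals[i] < opt$objective) opt <- list(minimum = grid[i], objective = vals[i])
  structure(list(energy = opt$minimum, objective = objective,
                 value = opt$objective),
            class = "energy_estimate")
}

#' @export
print.energy_estimate <- function(x, ...) {
  cat(sprintf("Effective energy %.3f keV (%s objective, value %.4g)\n",
              x$energy, x$objective, x$value))
  invisible(x)
}

#' Fit the affine HU-to-attenuation map at a given energy
#'
#' Ordinary least squares of the reference linear attenuation mu_m(E) on the
#' measured mean HU across ROIs; with exactly two ROIs the fit interpolates
#' both points. The measured air ROI participates: it anchors the line
#' against a scanner HU offset.
#'
#' @param rois a `roi_samples` data frame (>= 2 ROIs with distinct mean HU).
#' @param energy effective energy E* (keV).
#' @param materials a [material_library()].
#' @return list with `slope` ((1/cm)/HU), `intercept` (1/cm),
#'   `residuals_hu` (per-ROI residual expressed in HU), `mu` (reference
#'   attenuation at E*).
#' @export
fit_hu_to_attenuation <- function(rois, energy, materials = material_library()) {
  rois <- .check_rois(rois, materials)
  if (nrow(rois) < 2)
    qct_stop("the HU-to-attenuation fit needs >= 2 ROIs", "qct_degenerate_error")
  h <- rois$mean_hu
  if (diff(range(h)) < 1e-9)
    qct_stop("all ROI mean HUs are identical; the affine fit is singular",
             "qct_singular_error")
  mu <- vapply(rois$material, function(m)
    linear_attenuation(materials[[m]], energy), numeric(1))
  fit <- stats::lsfit(h, mu)
  slope <- unname(fit$coefficients[2]); intercept <- unname(fit$coefficients[1])
  if (!is.finite(slope) || slope <= 0)
    qct_stop("fitted HU-to-attenuation slope is not positive; ROI set is inconsistent with the reference materials",
             "qct_singular_error")
  list(slope = slope, intercept = intercept,
       residuals_hu = setNames((mu - (slope * h + intercept)) / slope,
                               rois$material),
       mu = setNames(mu, rois$material))
}

#' Internal (phantomless) CT density calibration
#'
#' The core fitting function. From the HU summaries of tissue regions of
#' interest it (1) estimates the effective scan energy E*
#' ([estimate_effective_energy()]), (2) fits the affine map from HU to
#' linear attenuation at E* ([fit_hu_to_attenuation()]), and (3) records
#' water's mass attenuation at E*, so that any HU value can be expressed as
#' water-equivalent density rho_weq = (a HU + b) / (mu/rho)_water(E*) in
#' g/cm^3. Use [predict()] to convert HU values or volumes to density.
#'
#' @param rois a `roi_samples` data frame, e.g. from [roi_stats()].
#' @param materials a [material_library()].
#' @param energy_range search window for E* in keV.
#' @param objective E* selection criterion, see
#'   [estimate_effective_energy()].
#' @return object of class `internal_calibration` with components
#'   `effective_energy`, `slope`, `intercept`, `water_mass_attenuation`,
#'   `residuals_hu`, `roi_set`, `rois`, `objective`, `objective_value`.
#' @examples
#' lib <- material_library()
#' rois <- roi_samples(
#'   roi_sample("air", -1000, 2, 500),
#'   roi_sample("adipose", predicted_hu("adipose", 70, lib), 4, 400))
#' cal <- internal_calibration(rois, lib)
#' predict(cal, c(-1000, 0, 60))   # densities of air, water-like, muscle-like HU
#' @export
internal_calibration <- function(rois, materials = material_library(),
                                 energy_range = c(30, 200),
                                 objective = c("auto", "r2", "sse")) {
  est <- estimate_effective_energy(rois, materials, energy_range, objective)
  fit <- fit_hu_to_attenuation(rois, est$energy, materials)
  structure(list(
    effective_energy = est$energy,
    slope = fit$slope,
    intercept = fit$intercept,
    water_mass_attenuation = mass_attenuation(materials$water, est$energy),
    residuals_hu = fit$residuals_hu,
    roi_set = rois$material,
    rois = rois,
    objective = est$objective,
    objective_value = est$value,
    energy_range = energy_range,
    call = match.call()),
    class = "internal_calibration")
}

#' @export
print.internal_calibration <- function(x, ...) {
  cat("Internal (phantomless) CT density calibration\n")
  cat(sprintf("  ROIs: %s\n", paste(x$roi_set, collapse = ", ")))
  cat(sprintf("  Effective energy E* = %.2f keV (%s objective)\n",
              x$effective_energy, x$objective))
  cat(sprintf("  HU -> mu map: mu = %.4e * HU + %.4e  [1/cm]\n",
              x$slope, x$intercept))
  cat(sprintf("  Water mu/rho at E*: %.4f cm^2/g\n", x$water_mass_attenuation))
  invisible(x)
}

#' @export
summary.internal_calibration <- function(object, ...) {
  structure(list(cal = object,
                 residual_table = data.frame(
                   material = object$roi_set,
                   mean_hu = object$rois$mean_hu,
                   residual_hu = unname(object$residuals_hu))),
            class = "summary.internal_calibration")
}

#' @export
print.summary.internal_calibration <- function(x, ...) {
  print(x$cal)
  cat(sprintf("  Objective value at E*: %.4g\n", x$cal$objective_value))
  cat("  Per-ROI residuals (HU):\n")
  print(x$residual_table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.internal_calibration <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
residuals.internal_calibration <- function(object, ...) object$residuals_hu

#' @export
fitted.internal_calibration <- function(object, ...) {
  setNames(object$rois$mean_hu - unname(object$residuals_hu), object$roi_set)
}

#' Convert HU to water-equivalent density with a fitted calibration
#'
#' Per voxel (or value), `rho_weq = (slope * HU + intercept) /
#' (mu/rho)_water(E*)`. Negative outputs (air) are preserved, not clamped:
#' clamping would bias downstream agreement statistics, and muscle masks
#' exclude air regions anyway.
#'
#' @param object an `internal_calibration`.
#' @param newdata numeric HU values or an [hu_volume()]; defaults to the
#'   fitted ROI mean HUs.
#' @param ... unused.
#' @return densities in g/cm^3; a [density_volume()] if `newdata` is a
#'   volume, otherwise a numeric vector.
#' @export
predict.internal_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$rois$mean_hu
  rho <- (object$slope * as.vector(newdata) + object$intercept) /
    object$water_mass_attenuation
  if (inherits(newdata, "hu_volume")) {
    density_volume(array(rho, dim(newdata)), voxel_spacing(newdata),
                   units = "g/cm^3",
                   provenance = list(method = "internal",
                                     effective_energy = object$effective_energy,
                                     slope = object$slope,
                                     intercept = object$intercept,
                                     roi_set = object$roi_set))
  } else rho
}

#' @export
plot.internal_calibration <- function(x, ...) {
  h <- x$rois$mean_hu
  mu <- x$slope * (h - unname(x$residuals_hu)) + x$intercept
  plot(h, mu, xlab = "measured HU", ylab = expression(mu ~ (cm^-1)),
       main = sprintf("Internal calibration, E* = %.1f keV", x$effective_energy),
       pch = 19, ...)
  abline(x$intercept, x$slope, col = "grey40")
  invisible(x)
}

#' Water-equivalent density image from a calibration
#'
#' Thin wrapper over [predict.internal_calibration()] (kept as the
#' pipeline-facing verb).
#'
#' @param image an [hu_volume()].
#' @param cal an `internal_calibration`.
#' @return a [density_volume()] in g/cm^3.
#' @export
calibrate_to_water_density <- function(image, cal) {
  stopifnot(inherits(cal, "internal_calibration"))
  predict(cal, image)
}

#' Run the full internal calibration on an image + mask
#'
#' Composes [roi_stats()], [internal_calibration()] and
#' [calibrate_to_water_density()].
#'
#' @param image an [hu_volume()].
#' @param mask a [label_volume()].
#' @param roi_map named map from mask label to material name.
#' @param roi_set material names to use (must all appear in `roi_map`).
#' @param materials a [material_library()].
#' @param aggregate per-ROI HU statistic, `"mean"` or `"median"`.
#' @param ... passed to [internal_calibration()] (`energy_range`,
#'   `objective`).
#' @return list with `calibration` (the fit) and `density` (the
#'   [density_volume()]).
#' @export
internal_calibrate <- function(image, mask, roi_map, roi_set,
                               materials = material_library(),
                               aggregate = "mean", ...) {
  available <- unlist(roi_map)
  missing <- setdiff(roi_set, available)
  if (length(missing))
    qct_stop(sprintf("roi_map provides no label for material(s): %s",
                     paste(missing, collapse = ", ")), "qct_input_error")
  keep <- roi_map[available %in% roi_set]
  rois <- roi_stats(image, mask, keep, aggregate = aggregate)
  cal <- internal_calibration(rois, materials, ...)
  list(calibration = cal, density = calibrate_to_water_density(image, cal))
}

#' The standard ROI subsets for the combination sweep
#'
#' The five nested combinations used to study which internal ROIs are needed
#' for accurate muscle density: all five materials; dropping bone; dropping
#' bone and muscle; then the two-ROI sets air+blood and air+adipose.
#'
#' @return named list of character vectors of material names.
#' @export
roi_subsets <- function() {
  list(
    "air,adipose,blood,muscle,bone" =
      c("air", "adipose", "blood", "skeletal_muscle", "cortical_bone"),
    "air,adipose,blood,muscle" = c("air", "adipose", "blood", "skeletal_muscle"),
    "air,adipose,blood" = c("air", "adipose", "blood"),
    "air,blood" = c("air", "blood"),
    "air,adipose" = c("air", "adipose"))
}

#' ROI-combination sweep with Bland-Altman agreement against a reference
#'
#' Runs [internal_calibrate()] for each ROI subset and compares the
#' resulting per-sample mean densities against a reference density vector
#' (typically phantom-calibrated densities or simulation ground truth) by
#' Bland-Altman analysis.
#'
#' @param image an [hu_volume()].
#' @param mask a [label_volume()].
#' @param roi_map named map from mask label to material name (must cover all
#'   materials used by `subsets`).
#' @param reference_densities numeric vector of reference densities, one per
#'   sample label, in the order of `sample_labels`.
#' @param sample_labels integer mask labels of the sample regions whose mean
#'   density is compared.
#' @param subsets list of ROI material subsets; defaults to [roi_subsets()].
#' @param materials a [material_library()].
#' @param ... passed to [internal_calibrate()].
#' @return data frame with one row per subset: `roi_set`, `effective_energy`,
#'   `bias`, `loa_halfwidth`, `loa_low`, `loa_high`.
#' @export
roi_combination_sweep <- function(image, mask, roi_map, reference_densities,
                                  sample_labels, subsets = roi_subsets(),
                                  materials = material_library(), ...) {
  if (length(reference_densities) != length(sample_labels))
    qct_stop("reference_densities and sample_labels lengths differ",
             "qct_input_error")
  rows <- lapply(names(subsets), function(nm) {
    res <- internal_calibrate(image, mask, roi_map, subsets[[nm]],
                              materials = materials, ...)
    dens <- vapply(sample_labels, function(l) mean(res$density[mask == l]),
                   numeric(1))
    ba <- bland_altman(dens, reference_densities)
    data.frame(roi_set = nm,
               effective_energy = res$calibration$effective_energy,
               bias = ba$bias, loa_halfwidth = ba$loa_halfwidth,
               loa_low = ba$loa_low, loa_high = ba$loa_high)
  })
  do.call(rbind, rows)
}
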