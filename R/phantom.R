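#' Reference-phantom calibration
#'
#' Fits the linear (OLS) relationship between the measured mean HU of
#' phantom vials/rods and their known densities, the comparator calibration
#' throughout: density = slope * HU + intercept. With a sucrose-water
#' phantom the output units are g/cm^3; with a hydroxyapatite (HA) bone
#' phantom they are mgHA/cm^3 (same fit, different scale).
#'
#' @param mean_hu measured mean HU per vial (>= 2 distinct values).
#' @param known_density known vial densities, same length, strictly
#'   increasing.
#' @param units unit string recorded on the fit and propagated to density
#'   outputs (`"g/cm^3"` or `"mgHA/cm^3"`).
#' @return object of class `phantom_calibration` with `slope`, `intercept`,
#'   `r_squared`, `units`, `data`.
#' @examples
#' # the five sucrose vials forward-imaged at some effective energy
#' hu <- c(0, 10, 40, 60, 110)
#' cal <- phantom_calibration(hu, c(1.00, 1.01, 1.04, 1.06, 1.11))
#' predict(cal, 55)
#' @export
phantom_calibration <- function(mean_hu, known_density, units = "g/cm^3") {
  if (length(mean_hu) != length(known_density))
    qct_stop("mean_hu and known_density lengths differ", "qct_input_error")
  if (length(mean_hu) < 2)
    qct_stop("phantom calibration needs >= 2 vials", "qct_input_error")
  if (any(diff(sort(known_density)) <= 0))
    qct_stop("known vial densities must be distinct", "qct_input_error")
  if (diff(range(mean_hu)) < 1e-9)
    qct_stop("all vial mean HUs are identical; the phantom fit is singular",
             "qct_singular_error")
  fit <- lm(known_density ~ mean_hu)
  r2 <- if (length(mean_hu) == 2) 1
        else suppressWarnings(summary(fit)$r.squared)  # exact lines are expected
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, units = units,
                 data = data.frame(mean_hu = mean_hu,
                                   known_density = known_density),
                 call = match.call()),
            class = "phantom_calibration")
}

#' @export
print.phantom_calibration <- function(x, ...) {
  cat("Reference-phantom CT density calibration\n")
  cat(sprintf("  density [%s] = %.6g * HU + %.6g   (R^2 = %.6f, %d vials)\n",
              x$units, x$slope, x$intercept, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
coef.phantom_calibration <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
predict.phantom_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$mean_hu
  rho <- object$slope * as.vector(newdata) + object$intercept
  if (inherits(newdata, "hu_volume")) {
    density_volume(array(rho, dim(newdata)), voxel_spacing(newdata),
                   units = object$units,
                   provenance = list(method = "phantom", slope = object$slope,
                                     intercept = object$intercept))
  } else rho
}

#' @export
residuals.phantom_calibration <- function(object, ...) {
  object$data$known_density - predict(object)
}

#' @export
plot.phantom_calibration <- function(x, ...) {
  plot(x$data$mean_hu, x$data$known_density, pch = 19,
       xlab = "measured HU", ylab = sprintf("known density [%s]", x$units),
       main = "Reference-phantom calibration", ...)
  abline(x$intercept, x$slope, col = "grey40")
  invisible(x)
}

#' Apply a phantom calibration to an image
#'
#' Per-voxel affine rescaling of HU to density; units come from the fit.
#'
#' @param image an [hu_volume()].
#' @param cal a [phantom_calibration()].
#' @return a [density_volume()].
#' @export
apply_phantom_calibration <- function(image, cal) {
  stopifnot(inherits(cal, "phantom_calibration"))
  predict(cal, image)
}

#' Read a phantom specification from JSON
#'
#' Expected keys: `vial_labels` (integer mask labels), `known_values`
#' (densities, strictly increasing, same length) and `units`.
#'
#' @param path JSON file.
#' @return list with `vial_labels`, `known_values`, `units`.
#' @export
read_phantom_spec <- function(path) {
  spec <- jsonlite::fromJSON(path)
  req <- c("vial_labels", "known_values", "units")
  missing <- setdiff(req, names(spec))
  if (length(missing))
    qct_stop(sprintf("phantom spec missing field(s): %s; found: %s",
                     paste(missing, collapse = ", "),
                     paste(names(spec), collapse = ", ")), "qct_schema_error")
  if (length(spec$vial_labels) < 2 ||
      length(spec$vial_labels) != length(spec$known_values))
    qct_stop("phantom spec needs >= 2 vials with one known value each",
             "qct_input_error")
  if (any(diff(spec$known_values) <= 0))
    qct_stop("phantom known_values must be strictly increasing", "qct_input_error")
  spec[req]
}

#' Calibrate an image against an in-scan phantom
#'
#' Measures the vials' mean HU in the mask and fits
#' [phantom_calibration()].
#'
#' @param image an [hu_volume()].
#' @param mask a [label_volume()] containing the vial labels.
#' @param spec a phantom spec list, see [read_phantom_spec()].
#' @param aggregate `"mean"` or `"median"` vial HU statistic.
#' @return list with `calibration` and `density` (the rescaled volume).
#' @export
phantom_calibrate <- function(image, mask, spec, aggregate = "mean") {
  loc <- if (identical(aggregate, "median")) median else mean
  hu <- vapply(spec$vial_labels, function(l) {
    v <- image[mask == l]
    if (!length(v))
      qct_stop(sprintf("mask has no voxels for vial label %d", l),
               "qct_input_error")
    loc(v)
  }, numeric(1))
  cal <- phantom_calibration(hu, spec$known_values, units = spec$units)
  list(calibration = cal, density = predict(cal, image))
}
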