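#' Mass-attenuation curve
#'
#' A tabulated mass attenuation coefficient (mu/rho, cm^2/g) over a strictly
#' increasing photon-energy grid (keV). Interpolation between grid points is
#' log-log linear, the standard choice for photon attenuation data, which are
#' close to power laws in the photoelectric-dominated decade. No extrapolation
#' is performed outside the tabulated range.
#'
#' @param energies numeric vector of photon energies in keV, strictly
#'   increasing, all positive. The grid must cover at least 10--200 keV.
#' @param mass_attenuation numeric vector of mu/rho values in cm^2/g, all
#'   positive, same length as `energies`.
#' @param material optional material name used in error messages.
#' @return an object of class `attenuation_curve`.
#' @export
attenuation_curve <- function(energies, mass_attenuation, material = "custom") {
  energies <- as.numeric(energies)
  mass_attenuation <- as.numeric(mass_attenuation)
  if (length(energies) != length(mass_attenuation) || length(energies) < 2)
    qct_stop("an attenuation curve needs >= 2 (energy, mu/rho) pairs of equal length",
             "qct_input_error")
  if (anyNA(energies) || anyNA(mass_attenuation))
    qct_stop("attenuation curve contains missing values", "qct_input_error")
  if (any(energies <= 0) || any(mass_attenuation <= 0))
    qct_stop("energies and mass attenuation coefficients must be positive",
             "qct_input_error")
  if (any(diff(energies) <= 0))
    qct_stop("energy grid must be strictly increasing (duplicate or unsorted energies; absorption edges are not supported)",
             "qct_input_error")
  if (energies[1] > 10 || energies[length(energies)] < 200)
    qct_stop("energy grid must cover at least 10-200 keV", "qct_input_error")
  structure(list(energies = energies, mass_attenuation = mass_attenuation,
                 material = material),
            class = "attenuation_curve")
}

#' @export
print.attenuation_curve <- function(x, ...) {
  cat(sprintf("<attenuation_curve: %s, %d points, %.6g-%.6g keV>\n",
              x$material, length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Reference material
#'
#' Couples an attenuation curve with a nominal reference mass density, from
#' which the linear attenuation coefficient mu = (mu/rho) * rho_ref follows.
#'
#' @param name material name; one of the packaged names
#'   (`air`, `water`, `adipose`, `blood`, `skeletal_muscle`, `cortical_bone`)
#'   or any custom label.
#' @param rho_ref reference mass density in g/cm^3 (positive; for air it must
#'   be below 0.01, and water is pinned at exactly 1.000).
#' @param curve an [attenuation_curve()].
#' @return an object of class `material_spec`.
#' @export
material_spec <- function(name, rho_ref, curve) {
  stopifnot(inherits(curve, "attenuation_curve"))
  rho_ref <- as.numeric(rho_ref)
  if (length(rho_ref) != 1 || is.na(rho_ref) || rho_ref <= 0)
    qct_stop(sprintf("rho_ref for '%s' must be a single positive number", name),
             "qct_input_error")
  if (identical(name, "air") && rho_ref >= 0.01)
    qct_stop("air rho_ref must be below 0.01 g/cm^3", "qct_input_error")
  if (identical(name, "water") && abs(rho_ref - 1) > 1e-12)
    qct_stop("water rho_ref is 1.000 g/cm^3 by definition", "qct_input_error")
  curve$material <- name
  structure(list(name = name, rho_ref = rho_ref, curve = curve),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec: %s, rho_ref = %g g/cm^3>\n", x$name, x$rho_ref))
  invisible(x)
}

#' Load the packaged material library
#'
#' Reads the mass-attenuation tables and reference densities shipped with the
#' package (or a user-supplied directory with the same layout: one delimited
#' table per material plus a `manifest.json` mapping material name to table
#' file and `rho_ref`). Reference densities can be overridden per material.
#'
#' @param path directory holding `manifest.json` and the referenced tables;
#'   defaults to the tables shipped with the package (ICRU-44 tissue
#'   compositions, water and dry air).
#' @param rho_ref optional named numeric vector of density overrides in
#'   g/cm^3, e.g. `c(cortical_bone = 2.0)`.
#' @return an object of class `material_library`: a named list of
#'   [material_spec()] objects, always including `water` and `air`.
#' @export
material_library <- function(path = NULL, rho_ref = NULL) {
  default <- is.null(path) && is.null(rho_ref)
  if (default && !is.null(.qct$default_library)) return(.qct$default_library)
  if (is.null(path))
    path <- system.file("extdata", "attenuation", package = "qctcal")
  manifest_file <- file.path(path, "manifest.json")
  if (!file.exists(manifest_file))
    qct_stop(sprintf("no manifest.json found under '%s'", path), "qct_input_error")
  manifest <- jsonlite::fromJSON(manifest_file, simplifyVector = FALSE)
  lib <- list()
  for (entry in manifest) {
    tab <- read.delim(file.path(path, entry$table), header = FALSE,
                      comment.char = "#", col.names = c("energy", "mu_rho"))
    rho <- entry$rho_ref
    if (!is.null(rho_ref) && entry$material %in% names(rho_ref))
      rho <- unname(rho_ref[[entry$material]])
    lib[[entry$material]] <- material_spec(
      entry$material, rho, attenuation_curve(tab$energy, tab$mu_rho, entry$material))
  }
  if (!all(c("water", "air") %in% names(lib)))
    qct_stop("material library must define both 'water' and 'air'", "qct_input_error")
  lib <- structure(lib, class = "material_library")
  if (default) .qct$default_library <- lib
  lib
}

#' @export
print.material_library <- function(x, ...) {
  cat(sprintf("<material_library: %s>\n", paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Interpolate a mass attenuation coefficient
#'
#' Log-log linear interpolation of mu/rho at the requested energies.
#' Tabulated grid points are reproduced exactly; energies outside the grid
#' raise a range error naming the material and the valid bounds.
#'
#' @param curve an [attenuation_curve()] or [material_spec()].
#' @param energy photon energy (keV), vectorised.
#' @return mu/rho in cm^2/g, same length as `energy`.
#' @export
mass_attenuation <- function(curve, energy) {
  if (inherits(curve, "material_spec")) curve <- curve$curve
  stopifnot(inherits(curve, "attenuation_curve"))
  energy <- as.numeric(energy)
  lo <- curve$energies[1]; hi <- curve$energies[length(curve$energies)]
  if (anyNA(energy) || any(energy < lo) || any(energy > hi))
    qct_stop(sprintf("energy out of range for material '%s': tabulated %g-%g keV",
                     curve$material, lo, hi), "qct_range_error")
  exp(stats::approx(log(curve$energies), log(curve$mass_attenuation),
                    xout = log(energy))$y)
}

#' Linear attenuation coefficient
#'
#' mu = (mu/rho) * rho_ref, in 1/cm.
#'
#' @param material a [material_spec()].
#' @param energy photon energy (keV), vectorised.
#' @return mu in 1/cm.
#' @export
linear_attenuation <- function(material, energy) {
  stopifnot(inherits(material, "material_spec"))
  mass_attenuation(material$curve, energy) * material$rho_ref
}

#' Predicted Hounsfield value of a material at a given effective energy
#'
#' Uses the defining HU anchoring, `HU = 1000 (mu - mu_water) /
#' (mu_water - mu_air)`, so water maps to exactly 0 and air to exactly -1000
#' at every energy.
#'
#' @param material a [material_spec()], or a material name resolved against
#'   `materials`.
#' @param energy photon energy (keV), vectorised.
#' @param materials a [material_library()] supplying the water and air
#'   anchors (and the named material, if `material` is a name).
#' @return predicted HU, same length as `energy`.
#' @export
predicted_hu <- function(material, energy, materials = material_library()) {
  if (is.character(material)) {
    if (!material %in% names(materials))
      qct_stop(sprintf("unknown material '%s'; library has: %s", material,
                       paste(names(materials), collapse = ", ")),
               "qct_input_error")
    material <- materials[[material]]
  }
  mu   <- linear_attenuation(material, energy)
  mu_w <- linear_attenuation(materials$water, energy)
  mu_a <- linear_attenuation(materials$air, energy)
  1000 * (mu - mu_w) / (mu_w - mu_a)
}
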