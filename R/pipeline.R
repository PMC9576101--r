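#' Write a report as pretty-printed JSON with sorted keys
#'
#' Atomic write (temp file + rename) so partially written reports are never
#' observed; key ordering is deterministic for diffability.
#'
#' @param x named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  x <- .sort_keys(x)
  tmp <- paste0(path, ".tmp")
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), tmp)
  file.rename(tmp, path)
  invisible(path)
}

.sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && !is.data.frame(x)) {
    x <- x[order(names(x))]
    lapply(x, .sort_keys)
  } else x
}

#' Read a scan scenario from YAML or JSON
#'
#' The file mirrors the [scan_scenario()] arguments; each entry of
#' `regions` mirrors [ct_region()].
#'
#' @param path `.yaml`/`.yml` or `.json` scenario file.
#' @return a [scan_scenario()].
#' @export
read_scan_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  if (is.null(spec$regions))
    qct_stop("scenario file has no 'regions'", "qct_schema_error")
  regions <- lapply(spec$regions, function(r) do.call(ct_region, r))
  args <- spec[setdiff(names(spec), "regions")]
  do.call(scan_scenario, c(list(regions = regions), args))
}

#' Run one calibration-pipeline step
#'
#' The programmatic equivalent of the command-line tool: executes one of
#' the subcommands and writes its artifacts. `config` is a named list with
#' a `command` entry plus the parameters for that command:
#'
#' * `simulate`: `scenario` (a [scan_scenario()] or a scenario file path),
#'   `out_dir`. Writes `image.nii.gz`, `mask.nii.gz`, `truth.csv`,
#'   `roi_map.json`.
#' * `internal`: `image`, `mask` (NIfTI paths or volumes), `roi_map` (JSON
#'   path or named map), `roi_set` (character vector), optional
#'   `energy_range`, `objective`, `aggregate`, `out_density`, `out_report`.
#' * `phantom`: `image`, `mask`, `phantom` (JSON path or spec list),
#'   optional `aggregate`, `out_density`, `out_report`.
#' * `sweep`: `image`, `mask`, `roi_map`, `reference_densities`,
#'   `sample_labels`, optional `out_report`.
#' * `stats`: `mode` (`"agreement"` or `"cv"`), `input` (csv with samples in
#'   rows for cv, or two-column pairs for agreement), optional `out_report`.
#'
#' @param config named list as above.
#' @return list of computed results (also written to disk when `out_*`
#'   entries are present), invisibly.
#' @export
run_pipeline <- function(config) {
  cmd <- config$command
  if (is.null(cmd) || !cmd %in% c("simulate", "internal", "phantom", "sweep", "stats"))
    qct_stop("config$command must be one of simulate, internal, phantom, sweep, stats",
             "qct_config_error")
  switch(cmd,
         simulate = .pipe_simulate(config),
         internal = .pipe_internal(config),
         phantom = .pipe_phantom(config),
         sweep = .pipe_sweep(config),
         stats = .pipe_stats(config))
}

.load_image <- function(x) if (is.character(x)) read_hu_volume(x) else x
.load_mask <- function(x) if (is.character(x)) read_label_volume(x) else x
.load_roi_map <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    jsonlite::fromJSON(x, simplifyVector = FALSE)
  else as.list(x)
}

.pipe_simulate <- function(config) {
  scenario <- config$scenario
  if (is.character(scenario)) scenario <- read_scan_scenario(scenario)
  scan <- generate_scan(scenario)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(scan$image, file.path(config$out_dir, "image.nii.gz"))
    write_volume(scan$mask, file.path(config$out_dir, "mask.nii.gz"))
    write.csv(scan$truth, file.path(config$out_dir, "truth.csv"),
              row.names = FALSE)
    write_report_json(scan$roi_map, file.path(config$out_dir, "roi_map.json"))
  }
  invisible(scan)
}

.pipe_internal <- function(config) {
  image <- .load_image(config$image)
  mask <- .load_mask(config$mask)
  roi_map <- .load_roi_map(config$roi_map)
  roi_set <- config$roi_set
  if (is.null(roi_set)) roi_set <- unique(unlist(roi_map))
  args <- list(image = image, mask = mask, roi_map = roi_map, roi_set = roi_set)
  if (!is.null(config$aggregate)) args$aggregate <- config$aggregate
  if (!is.null(config$energy_range)) args$energy_range <- config$energy_range
  if (!is.null(config$objective)) args$objective <- config$objective
  res <- do.call(internal_calibrate, args)
  cal <- res$calibration
  if (!is.null(config$out_density)) write_volume(res$density, config$out_density)
  if (!is.null(config$out_report))
    write_report_json(list(
      method = "internal", effective_energy = cal$effective_energy,
      slope = cal$slope, intercept = cal$intercept,
      water_mass_attenuation = cal$water_mass_attenuation,
      residuals_hu = as.list(cal$residuals_hu),
      roi_set = cal$roi_set, objective = cal$objective,
      objective_value = cal$objective_value), config$out_report)
  invisible(res)
}

.pipe_phantom <- function(config) {
  image <- .load_image(config$image)
  mask <- .load_mask(config$mask)
  spec <- config$phantom
  if (is.character(spec)) spec <- read_phantom_spec(spec)
  res <- phantom_calibrate(image, mask, spec,
                           aggregate = if (is.null(config$aggregate)) "mean"
                                       else config$aggregate)
  if (!is.null(config$out_density)) write_volume(res$density, config$out_density)
  if (!is.null(config$out_report))
    write_report_json(list(
      method = "phantom", slope = res$calibration$slope,
      intercept = res$calibration$intercept,
      r_squared = res$calibration$r_squared,
      units = res$calibration$units), config$out_report)
  invisible(res)
}

.pipe_sweep <- function(config) {
  tab <- roi_combination_sweep(.load_image(config$image), .load_mask(config$mask),
                               .load_roi_map(config$roi_map),
                               config$reference_densities, config$sample_labels)
  if (!is.null(config$out_report)) {
    rows <- lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
    write_report_json(list(sweep = rows), config$out_report)
  }
  invisible(tab)
}

.pipe_stats <- function(config) {
  mode <- config$mode
  if (is.null(mode) || !mode %in% c("agreement", "cv"))
    qct_stop("stats mode must be 'agreement' or 'cv'", "qct_config_error")
  tab <- if (is.character(config$input)) read.csv(config$input) else config$input
  if (mode == "agreement") {
    if (ncol(tab) < 2) qct_stop("agreement input needs two columns", "qct_config_error")
    ba <- bland_altman(tab[[1]], tab[[2]])
    reg <- regression_compare(tab[[1]], tab[[2]])
    out <- list(bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                loa_halfwidth = ba$loa_halfwidth, slope = reg$slope,
                intercept = reg$intercept, r_squared = reg$r_squared, n = ba$n)
  } else {
    m <- as.matrix(tab[vapply(tab, is.numeric, logical(1))])
    cv <- cv_across_conditions(m)
    out <- list(per_sample_cv_pct = as.list(setNames(cv$cv_pct, cv$sample)),
                mean_cv_pct = mean_cv(cv))
  }
  if (!is.null(config$out_report)) write_report_json(out, config$out_report)
  invisible(out)
}
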