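#' Bland-Altman agreement analysis
#'
#' Mean difference (bias) and 95% limits of agreement between two paired
#' measurement series, plus the trend of the differences against the pair
#' means. Differences are `d = x - y`; the limits are
#' `bias +/- 1.96 * SD(d)` with the sample (n - 1) standard deviation.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return object of class `agreement_report` with `bias`, `loa_low`,
#'   `loa_high`, `loa_halfwidth`, `bias_trend` (slope/intercept of d on the
#'   pair means, `NA` when the means are constant) and `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    qct_stop("Bland-Altman needs paired vectors of equal length", "qct_input_error")
  if (length(x) < 2)
    qct_stop("Bland-Altman needs n >= 2 pairs", "qct_input_error")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  half <- 1.96 * sd(d)
  trend <- if (var(m) > 0) {
    cf <- coef(lm(d ~ m))
    c(intercept = unname(cf[1]), slope = unname(cf[2]))
  } else c(intercept = NA_real_, slope = NA_real_)
  structure(list(bias = bias, loa_low = bias - half, loa_high = bias + half,
                 loa_halfwidth = half, bias_trend = trend, n = length(x)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias = %.6g, 95%% LOA [%.6g, %.6g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  if (is.finite(x$bias_trend["slope"]))
    cat(sprintf("  difference-vs-mean trend: slope %.4g, intercept %.4g\n",
                x$bias_trend["slope"], x$bias_trend["intercept"]))
  invisible(x)
}

#' Coefficient of variation across scan conditions
#'
#' Per-sample CV = 100 * SD / mean over repeated measurements of the same
#' sample under different scan conditions, plus the arithmetic mean CV over
#' samples. The CV is undefined for non-positive means (as can happen for
#' raw HU series near 0): those raise an error.
#'
#' @param values numeric matrix or data frame, one row per sample, one
#'   column per condition (>= 2 conditions).
#' @return object of class `cv_table`: data frame with `sample`, `mean`,
#'   `sd`, `cv_pct`, and attribute `mean_cv`.
#' @export
cv_across_conditions <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2)
    qct_stop("CV needs >= 2 conditions per sample", "qct_input_error")
  mu <- rowMeans(values)
  if (any(mu <= 0))
    qct_stop(sprintf("CV undefined for non-positive sample means (rows: %s); raw HU series can violate this",
                     paste(which(mu <= 0), collapse = ", ")), "qct_value_error")
  s <- apply(values, 1, sd)
  out <- data.frame(sample = if (!is.null(rownames(values))) rownames(values)
                    else as.character(seq_len(nrow(values))),
                    mean = mu, sd = s, cv_pct = 100 * s / mu,
                    row.names = NULL)
  structure(out, class = c("cv_table", "data.frame"),
            mean_cv = mean(100 * s / mu))
}

#' Mean CV of a `cv_table`
#' @param x a [cv_across_conditions()] result.
#' @return mean CV in percent.
#' @export
mean_cv <- function(x) attr(x, "mean_cv")

#' @export
print.cv_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("mean CV = %.4g%%\n", attr(x, "mean_cv")))
  invisible(x)
}

#' Linear regression comparison of two methods
#'
#' OLS of `y` on `x` with the coefficient of determination, used to compare
#' density values produced by two calibration methods.
#'
#' @param x,y paired numeric vectors (n >= 3, `x` non-degenerate).
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
regression_compare <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    qct_stop("regression comparison needs paired vectors with n >= 3",
             "qct_input_error")
  if (var(x) == 0)
    qct_stop("regression comparison needs non-constant x", "qct_singular_error")
  fit <- lm(y ~ x)
  # exactly collinear input is a designed case (line-of-identity checks);
  # summary.lm warns about the perfect fit, which is expected here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = length(x))
}

#' Percent difference between two calibration methods
#'
#' `100 * mean((reference - comparison) / reference)` over samples; the
#' summary used to quote how far one method's density values sit from a
#' reference method's.
#'
#' @param reference,comparison paired density vectors.
#' @return percent difference (positive when the comparison method reads
#'   lower than the reference).
#' @export
percent_method_difference <- function(reference, comparison) {
  if (length(reference) != length(comparison))
    qct_stop("paired vectors of equal length required", "qct_input_error")
  100 * mean((reference - comparison) / reference)
}

#' Load per-sample density tables from a supplementary workbook
#'
#' Reads the per-sample muscle values measured under each scan condition for
#' each method, either from an xlsx workbook (one sheet per method, needs
#' the readxl package) or from a delimited text export, and normalises them
#' to a long table. Two layouts are accepted:
#'
#' * long: columns `sample`, `condition`, `method`, `value` (any case);
#' * wide: a `sample` column plus one column per condition; for xlsx the
#'   method is the sheet name, for csv a `method` column must be present.
#'
#' Method names are normalised to `HU`, `internal`, `sucrose_phantom`,
#' `HA_phantom` where recognisable; unrecognised names are kept as-is.
#'
#' @param path `.xlsx`, `.csv` or `.tsv` file.
#' @return long data frame with columns `sample`, `condition`, `method`,
#'   `value`.
#' @export
load_supplementary_densities <- function(path) {
  if (!file.exists(path))
    qct_stop(sprintf("workbook not found: %s", path), "qct_input_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      qct_stop("reading xlsx requires the 'readxl' package", "qct_input_error")
    sheets <- readxl::excel_sheets(path)
    if (!length(sheets)) qct_stop("workbook has no sheets", "qct_schema_error")
    tabs <- lapply(sheets, function(s)
      .normalise_density_table(as.data.frame(readxl::read_excel(path, sheet = s)),
                               default_method = s))
    out <- do.call(rbind, tabs)
  } else {
    sep <- if (ext == "tsv") "\t" else ","
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    out <- .normalise_density_table(tab, default_method = NULL)
  }
  if (!nrow(out)) qct_stop("no density rows found in workbook", "qct_schema_error")
  out
}

.canon_method <- function(m) {
  key <- gsub("[^a-z]", "", tolower(m))
  map <- c(hu = "HU", hounsfield = "HU", hounsfieldunits = "HU",
           internal = "internal", internalcalibration = "internal",
           sucrose = "sucrose_phantom", sucrosephantom = "sucrose_phantom",
           sucrosewaterphantom = "sucrose_phantom", phantom = "sucrose_phantom",
           ha = "HA_phantom", haphantom = "HA_phantom",
           habonephantom = "HA_phantom", hydroxyapatite = "HA_phantom")
  out <- unname(map[key])
  ifelse(is.na(out), m, out)
}

.normalise_density_table <- function(tab, default_method = NULL) {
  names(tab) <- trimws(names(tab))
  lower <- tolower(names(tab))
  long_cols <- c("sample", "condition", "method", "value")
  if (all(long_cols %in% lower)) {
    out <- tab[, match(long_cols, lower)]
    names(out) <- long_cols
  } else if ("sample" %in% lower) {
    sample_col <- which(lower == "sample")
    method_col <- which(lower == "method")
    value_cols <- setdiff(seq_along(tab), c(sample_col, method_col))
    value_cols <- value_cols[vapply(tab[value_cols], is.numeric, logical(1))]
    if (!length(value_cols))
      qct_stop(sprintf("no numeric condition columns found; columns present: %s",
                       paste(names(tab), collapse = ", ")), "qct_schema_error")
    method <- if (length(method_col)) tab[[method_col]]
      else if (!is.null(default_method)) default_method
      else qct_stop(sprintf("wide layout needs a 'method' column or a method-named sheet; columns present: %s",
                            paste(names(tab), collapse = ", ")), "qct_schema_error")
    out <- do.call(rbind, lapply(value_cols, function(j)
      data.frame(sample = as.character(tab[[sample_col]]),
                 condition = names(tab)[j], method = method,
                 value = tab[[j]], stringsAsFactors = FALSE)))
  } else {
    qct_stop(sprintf("unrecognised table layout; expected long (sample, condition, method, value) or wide (sample + condition columns); columns present: %s",
                     paste(names(tab), collapse = ", ")), "qct_schema_error")
  }
  out$sample <- as.character(out$sample)
  out$condition <- as.character(out$condition)
  out$method <- .canon_method(as.character(out$method))
  out$value <- as.numeric(out$value)
  rownames(out) <- NULL
  out
}
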