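#' Read and write annual series and covariate panels
#'
#' Plain CSV (comma separated, header required, decimal point). A series
#' file has columns `year` and one value column (default `deaths`); a
#' panel file has `year` plus the six covariate columns documented in
#' [covariate_panel()].
#'
#' @param path file path.
#' @param value_col value column name for series files; `NULL` = the single
#'   non-year column.
#' @return `read_annual_series()` an [annual_series()];
#'   `read_covariate_panel()` a [covariate_panel()].
#' @export
read_annual_series <- function(path, value_col = NULL) {
  df <- .read_csv_checked(path)
  if (!"year" %in% names(df))
    stop("schema error in '", path, "': no 'year' column", call. = FALSE)
  as_annual_series(df, value_col = value_col)
}

#' @rdname read_annual_series
#' @export
read_covariate_panel <- function(path) {
  covariate_panel(.read_csv_checked(path))
}

.read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("schema error in '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("schema error in '", path, "': need a header row and data",
         call. = FALSE)
  for (cn in names(df)) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1L]
      stop("schema error in '", path, "': non-numeric cell at row ",
           if (is.na(bad)) "?" else bad, ", column '", cn, "'",
           call. = FALSE)
    }
  }
  df
}

#' @rdname read_annual_series
#' @param x object to write.
#' @param value_name column name for the series values on output.
#' @export
write_annual_series <- function(x, path, value_name = "deaths") {
  df <- as.data.frame(as_annual_series(x), value_name = value_name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_annual_series
#' @export
write_covariate_panel <- function(x, path) {
  utils::write.csv(covariate_panel(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "greyshap")
  if (p == "") stop("bundled data file missing: ", file, call. = FALSE)
  p
}

#' Bundled Chinese road-traffic data
#'
#' National road-traffic accident fatality counts and the six macro
#' covariates (vehicle population, population, GDP, road freight volume,
#' road passenger volume, road mileage) for China, 2002-2011, with a
#' 2012-2013 hold-out set, as published in the study this package
#' reproduces.
#'
#' @param holdout return the 2012-2013 hold-out years instead of the
#'   2002-2011 training years?
#' @return `china_fatalities()` an [annual_series()] of deaths;
#'   `china_covariates()` a [covariate_panel()].
#' @examples
#' china_fatalities()
#' china_covariates(holdout = TRUE)
#' @export
china_fatalities <- function(holdout = FALSE) {
  read_annual_series(.extdata(
    if (holdout) "fatalities_2012_2013.csv" else "fatalities_2002_2011.csv"))
}

#' @rdname china_fatalities
#' @export
china_covariates <- function(holdout = FALSE) {
  read_covariate_panel(.extdata(
    if (holdout) "covariates_2012_2013.csv" else "covariates_2002_2011.csv"))
}

#' Published hold-out member predictions (reference values)
#'
#' The 2012-2013 member-model predictions printed in the reproduced study:
#' its Verhulst values follow a shifted forecast index that this package's
#' `predict()` deliberately does not use (see the methods vignette), and
#' its regression values were computed from display-rounded coefficients.
#' They are bundled verbatim because the published combined hold-out
#' forecast is defined as their weighted sum.
#'
#' @return data frame with columns `year`, `verhulst`, `regression`.
#' @export
reference_holdout_predictions <- function() {
  .read_csv_checked(.extdata("holdout_member_predictions.csv"))
}

#' Published in-sample results (reference values)
#'
#' The published per-year fitted values and relative errors of the
#' Verhulst, regression and combined models on the 2002-2011 data, used by
#' [check_reproduction()] to compare regenerated tables against print.
#'
#' @return data frame, one row per year 2002-2011.
#' @export
reference_insample_results <- function() {
  .read_csv_checked(.extdata("reference_results.csv"))
}
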