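#' Read and write the package's tidy CSV dialects
#'
#' Concentration-time series are stored with columns `time_h`, `analyte`,
#' `conc_mg_L`, `replicate`, `matrix`, `temperature`; steady-state cohorts
#' with `id`, `time_h`, `analyte`, `dv_mg_L`, `rate_mg_h`, `gfr_ml_min`.
#'
#' @param x the object to write.
#' @param path file path.
#' @return The read functions return the corresponding classed data.frame;
#'   the write functions return `path` invisibly.
#' @name meropk_io
NULL

#' @rdname meropk_io
#' @export
write_decay_series <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname meropk_io
#' @export
read_decay_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "analyte", "conc_mg_L")
  if (!all(need %in% names(d))) {
    stop("decay-series CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(d) <- c("concentration_series", "data.frame")
  d
}

#' @rdname meropk_io
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname meropk_io
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time_h", "analyte", "dv_mg_L", "rate_mg_h", "gfr_ml_min")
  if (!all(need %in% names(d))) {
    stop("cohort CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(d) <- c("poppk_dataset", "data.frame")
  d
}

#' Write a stability report as JSON
#'
#' @param report a [stability_report()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  if (!inherits(report, "stability_report")) {
    stop("`report` must be a stability_report", call. = FALSE)
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write population PK estimates as JSON
#'
#' @param fit a `poppk_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_poppk_fit <- function(fit, path) {
  if (!inherits(fit, "poppk_fit")) stop("`fit` must be a poppk_fit", call. = FALSE)
  out <- unclass(fit)
  out$fixed <- unclass(out$fixed)
  out$se <- as.list(out$se)
  out$rse_percent <- as.list(out$rse_percent)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
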