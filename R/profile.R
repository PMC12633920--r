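.prosoceq_env <- new.env(parent = emptyenv())

#' Load the calibrated reference profile shipped with the package
#'
#' The package ships, under `extdata/calibrated_profile.json`, the winning
#' demographic parameter set found by [calibrate_reference_model()]: the
#' combination of wellbeing, mortality, marriage and reproduction parameters
#' that keeps the threat-free baseline population approximately constant.
#' These values are the defaults of [demography_params()].
#'
#' @param path optional path to an alternative profile JSON file.
#' @return a named list with the calibrated parameter values plus a
#'   `metadata` entry (calibration seed, budget, achieved score).
#' @export
calibrated_profile <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .prosoceq_env$profile
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "calibrated_profile.json",
                        package = "prosoceq")
    if (!nzchar(path)) stop("shipped calibrated profile not found")
    prof <- jsonlite::read_json(path, simplifyVector = TRUE)
    .prosoceq_env$profile <- prof
    return(prof)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Persist a calibrated profile as JSON
#'
#' @param profile named list of calibrated parameter values, e.g. the
#'   `$params` element returned by [calibrate_reference_model()].
#' @param path output file path.
#' @param metadata optional named list stored alongside the values
#'   (seed, budget, achieved score).
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path, metadata = NULL) {
  out <- c(profile, list(metadata = metadata))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
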