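# Plain-text interchange for the tabular inputs and run reports.

#' Read a bioassay CSV
#'
#' Expected columns: `specimen_id, species, dilution, time_h, dead, n`
#' (`species` optional).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_bioassay_csv <- function(path) {
  df <- read.csv(path)
  need <- c("specimen_id", "dilution", "time_h", "dead", "n")
  if (!all(need %in% names(df))) {
    stop("bioassay CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$dead < 0 | df$dead > df$n)) stop("dead counts outside [0, n]")
  if (any(df$dilution < 0 | df$dilution > 1)) stop("dilutions outside [0, 1]")
  df
}

#' Read a predation-records CSV
#'
#' Expected columns: `model_id, colour, transect, time_h, status, reason`
#' (optional `jnd`).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_predation_csv <- function(path) {
  df <- read.csv(path)
  need <- c("model_id", "colour", "transect", "time_h", "status")
  if (!all(need %in% names(df))) {
    stop("predation CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$status %in% c("attacked", "censored"))) {
    stop("status must be 'attacked' or 'censored'")
  }
  if (any(df$time_h <= 0)) stop("times must be positive")
  if ("reason" %in% names(df)) {
    bad <- df$status == "censored" & df$reason == "none"
    if (any(bad)) stop("censored records must carry a censor reason")
  }
  df
}

#' Write a structured honesty-run report
#'
#' JSON report of a [run_honesty_pipeline()] result: seed and key
#' generator parameters (for replay), mapping quality, the headline
#' contrast and saturation effects, and the retained model terms.
#'
#' @param run An `honesty_run`.
#' @param path Output path.
#' @export
write_honesty_report <- function(run, path) {
  stopifnot(inherits(run, "honesty_run"))
  fit <- run$fit
  jsonlite::write_json(list(
    config = run$config_digest,
    n_specimens = nrow(run$table),
    mapping_r_squared = as.list(run$measurement$mapping$r_squared),
    contrast_effect = fit$contrast_effect,
    saturation_effect = fit$saturation_effect,
    retained_terms = fit$retained_terms,
    dropped_constant_predictors = fit$dropped_constant,
    specimens_with_missing_values = fit$na_report
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
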