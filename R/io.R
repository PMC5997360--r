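# Readers/writers for the tabular formats the pipeline touches, plus
# run-configuration echoing.  CSV is the tabular interchange format (tidy
# long form); FASTA and JASPAR PFM are handled in their own modules.

TIMECOURSE_COLS <- c("tissue", "gene", "time_h", "replicate", "value")

validate_timecourse <- function(df) {
  df <- as.data.frame(df)
  missing <- setdiff(TIMECOURSE_COLS, names(df))
  if (length(missing))
    stop("time-course data missing column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(df)) stop("time-course data has no rows")
  for (col in c("time_h", "value")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("non-numeric '", col, "' at data row ", bad[1])
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(df$value <= 0))
    warning("non-positive expression values present")
  canonical_order(df)
}

#' Read a time-course dataset from CSV
#'
#' Expects columns tissue, gene, time_h, replicate, value (extra columns
#' are kept).  Rows are returned in canonical order (tissue, gene, time,
#' replicate), so files with shuffled rows read identically.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  out <- validate_timecourse(df)  # schema first, then empty-input check
  rownames(out) <- NULL
  out
}

#' Write a time-course dataset to CSV
#'
#' @param df time-course data.frame.
#' @param path output path.
#' @export
write_timecourse <- function(df, path) {
  df <- validate_timecourse(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write core-clock parameters as flat key/value JSON
#'
#' Keys are named exactly as the published parameter symbols (tau_Bmal1,
#' d_RevErba, ar1, ...).
#'
#' @param params `core_clock_params`.
#' @param path output path.
#' @export
write_clock_params <- function(params, path) {
  v <- as.list(unlist(params[PARAM_ORDER]))
  jsonlite::write_json(v, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read core-clock parameters from flat key/value JSON
#'
#' @param path JSON path.
#' @return `core_clock_params`.
#' @export
read_clock_params <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  core_clock_parameters(base = unlist(v))
}

#' Write a truth manifest (JSON)
#' @param manifest manifest list.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Write the effective run configuration next to an artifact
#'
#' Every artifact the CLI produces is accompanied by the configuration
#' that produced it, echoed verbatim.
#'
#' @param config named list of effective settings.
#' @param path output path (JSON).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a fit as a tidy report table
#'
#' Mirrors the parameter-table layout: parameter, estimate, 95% CI and the
#' bounds used.
#'
#' @param fit `clock_fit`.
#' @param ... passed to [wald_ci()].
#' @return data.frame: parameter, estimate, ci_lo, ci_hi, bound_lo,
#'   bound_hi.
#' @export
fit_report <- function(fit, ...) {
  ci <- wald_ci(fit, ...)
  keep <- match(ci$parameter, names(fit$par))
  data.frame(parameter = ci$parameter, estimate = ci$estimate,
             ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
             bound_lo = fit$lower[keep], bound_hi = fit$upper[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}
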