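# Delimited-table I/O for cohorts, phase-2 views and fit results, plus a
# small JSON/YAML config reader used by the command-line wrapper.

#' Write / read a cohort as CSV
#'
#' Columns: `id`, `time`, `event`, `w`, `x`, `stratum` (phase-2 views add
#' `selected` and `weight`, with `x` missing for unselected subjects).
#'
#' @param cohort A cohort or phase-2 view `data.frame`.
#' @param path File path.
#' @return `read_cohort_csv` returns the validated `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "event")
  if (!all(need %in% names(df)))
    stop("cohort table must contain columns time and event")
  if (any(df$time <= 0)) stop("invalid cohort: nonpositive times")
  if (!all(df$event %in% c(0, 1))) stop("invalid cohort: event must be 0/1")
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  if (!is.null(df$selected)) df$selected <- as.logical(df$selected)
  df
}

#' Read a simulation setting from a JSON or YAML config file
#'
#' Keys mirror the arguments of [sim_setting()].
#'
#' @param path Path to a `.json`/`.yaml`/`.yml` file.
#' @return A `sim_setting`.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the jsonlite package is required to read JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(sim_setting, cfg)
}
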