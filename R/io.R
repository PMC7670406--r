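# Cohort file readers/writers and run reports.

#' Read a cohort file
#'
#' Parses the delimited cohort format (header required): columns `age`,
#' `d1..dN`, `surv_age`, `censored`, one row per individual. Deficits are
#' 0/1 or the NA token. Every row is validated and all violations are
#' reported with their row numbers.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param na Token representing a missing deficit (default `"NA"`).
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path, sep = "\t", na = "NA") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na, stringsAsFactors = FALSE)
  dn <- grep("^d[0-9]+$", names(raw), value = TRUE)
  need <- c("age", "surv_age", "censored")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0 || length(dn) == 0) {
    stop("cohort file must have columns age, d1..dN, surv_age, censored; missing: ",
         paste(c(missing_cols, if (length(dn) == 0) "d1..dN"), collapse = ", "))
  }
  dn <- paste0("d", seq_along(dn))  # enforce contiguous ordering
  if (!all(dn %in% names(raw))) stop("deficit columns must be d1..dN with no gaps")
  bad <- character(0)
  for (r in seq_len(nrow(raw))) {
    dv <- as.numeric(raw[r, dn])
    if (!all(is.na(dv) | dv %in% c(0, 1))) {
      bad <- c(bad, sprintf("row %d: non-binary deficit value", r))
    }
    if (all(is.na(dv))) bad <- c(bad, sprintf("row %d: all deficits missing", r))
    if (is.na(raw$age[r]) || is.na(raw$surv_age[r]) ||
        raw$surv_age[r] < raw$age[r]) {
      bad <- c(bad, sprintf("row %d: surv_age < age (or missing)", r))
    }
    if (!raw$censored[r] %in% c(0, 1)) {
      bad <- c(bad, sprintf("row %d: censored flag must be 0/1", r))
    }
  }
  if (length(bad) > 0) {
    stop("invalid cohort file:\n", paste(bad, collapse = "\n"))
  }
  raw[, c("age", dn, "surv_age", "censored")]
}

#' Write a cohort file
#'
#' @param data Cohort data.frame.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, sep = "\t") {
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducible run report
#'
#' Serializes metric tables together with the configuration echo, the seed
#' and the package version as pretty JSON; byte output is deterministic for
#' fixed inputs, so a report doubles as a run manifest.
#'
#' @param results Named list of metric data.frames (or scalars).
#' @param path Output path.
#' @param config Optional configuration list echoed into the report.
#' @param seed Seed used for the run.
#' @return The manifest list, invisibly.
#' @export
write_report <- function(results, path, config = NULL, seed = NULL) {
  manifest <- list(
    package = "agenet",
    version = as.character(utils::packageVersion("agenet")),
    seed = seed,
    config = config,
    results = results
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns", null = "null")
  invisible(manifest)
}
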