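# Snapshot-table interchange: plain CSV, one row per snapshot. Numeric I/O
# is full precision; 2-decimal display columns exist only in reports.

snapshot_required_cols <- c("protein", "donor", "subunit", "time_ps",
                            "rc_nm", "neg_sfeg_ev")
snapshot_optional_cols <- c("wavelength_nm", "lambda_ev", "ln_rate")

#' Read a snapshot CSV
#'
#' The format has header columns `protein`, `donor`, `subunit`,
#' `wavelength_nm` (optional), `time_ps`, `rc_nm`, `neg_sfeg_ev`,
#' `lambda_ev` (optional), `ln_rate` (optional), one row per snapshot.
#' Rows are ordered by `time_ps` within each donor series. Distances
#' outside the plausible 0.1--5 nm window raise a warning (likely a unit
#' slip), not an error.
#'
#' @param path CSV file path.
#' @return A tibble of snapshots ordered by series and time, with a
#'   `series_id` column identifying each protein/donor/subunit/wavelength
#'   combination.
#' @seealso [write_snapshot_csv()], [trajectory_rates()],
#'   [donor_equivalence_report()]
#' @export
read_snapshot_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) abort("Empty snapshot file.")
  miss <- setdiff(snapshot_required_cols, names(df))
  if (length(miss) > 0) {
    abort(paste0("Snapshot CSV is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"wavelength_nm" %in% names(df)) df$wavelength_nm <- NA_real_
  bad <- which(!is.finite(df$rc_nm) | df$rc_nm <= 0 |
                 !is.finite(df$neg_sfeg_ev))
  if (length(bad) > 0) {
    abort(paste0("Malformed snapshot row at line ", bad[1] + 1L,
                 ": rc_nm must be > 0 and neg_sfeg_ev finite."))
  }
  if (any(df$rc_nm < 0.1 | df$rc_nm > 5)) {
    warn("Some rc_nm fall outside the plausible 0.1-5 nm window; check units.")
  }
  df <- dplyr::arrange(df, .data$protein, .data$donor, .data$subunit,
                       .data$wavelength_nm, .data$time_ps)
  df$series_id <- paste(df$protein, df$donor, df$subunit,
                        ifelse(is.na(df$wavelength_nm), "",
                               df$wavelength_nm),
                        sep = "/")
  df
}

#' @rdname read_snapshot_csv
#' @param snapshots A snapshot tibble (e.g. from [simulate_trajectory()]).
#' @return `write_snapshot_csv()` returns `path` invisibly.
#' @export
write_snapshot_csv <- function(snapshots, path) {
  keep <- intersect(c(snapshot_required_cols, snapshot_optional_cols),
                    names(snapshots))
  readr::write_csv(snapshots[, keep], path, progress = FALSE)
  invisible(path)
}

#' Write an analysis report as CSV or JSON
#'
#' Serializes a record table (e.g. an [donor_equivalence_report()] result or
#' a fixture report) with every numeric field at full precision; columns
#' whose name starts with `xm_` or equals `abs_diff` additionally get a
#' 2-decimal `*_display` companion mirroring the published tables. The CSV
#' and JSON emitters carry identical content.
#'
#' @param records A data frame of records; zero rows give a header-only CSV
#'   (or empty JSON array).
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path,
                         format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  records <- as_tibble(records)
  disp_cols <- names(records)[grepl("^xm_", names(records)) |
                                names(records) == "abs_diff"]
  for (col in disp_cols) {
    records[[paste0(col, "_display")]] <- round(records[[col]], 2)
  }
  if (format == "csv") {
    readr::write_csv(records, path, progress = FALSE)
  } else {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report file (`.csv` or `.json`).
#' @return A tibble.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}
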