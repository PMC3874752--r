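# CSV interchange: schema definitions, validation and round-trip-stable
# writing. All tables are UTF-8, header row, '.' decimal, unquoted.

table_schemas <- function() {
  list(
    cohort = list(
      required = c("patient_id", "group", "bsa_m2", "lvedp_mmhg", "heart_rate",
                   "n_frames", "true_lav_min", "true_lav_ac", "true_lav_max",
                   "mv_open_frame", "ac_onset_frame", "mv_close_frame"),
      checks = list(
        bsa_m2 = function(x) x > 0,
        lvedp_mmhg = function(x) x > 0 & x <= 60,
        heart_rate = function(x) x > 0,
        true_lav_min = function(x) x > 0,
        true_lav_ac = function(x) x > 0,
        true_lav_max = function(x) x > 0
      )
    ),
    curves = list(
      required = c("patient_id", "frame", "time_ms", "volume_ml_m2"),
      checks = list(
        frame = function(x) x >= 0,
        time_ms = function(x) x >= 0,
        volume_ml_m2 = function(x) x > 0
      )
    ),
    biplane = list(
      required = c("patient_id", "observer_id", "frame", "a1_cm2", "a2_cm2", "l_cm"),
      checks = list(
        a1_cm2 = function(x) x > 0,
        a2_cm2 = function(x) x > 0,
        l_cm = function(x) x > 0
      )
    ),
    phasic = list(
      required = c("patient_id", "observer_id", "method",
                   "lav_min", "lav_ac", "lav_max"),
      checks = list(
        lav_min = function(x) x > 0,
        lav_ac = function(x) x > 0,
        lav_max = function(x) x > 0
      )
    )
  )
}

#' Read and schema-validate the pipeline CSV tables
#'
#' Checks each named file against its schema: required columns present,
#' numeric columns numeric, and units sanity (volumes and planimetry
#' measurements positive, LVEDP in (0, 60] mmHg). Row-level failures are
#' collected with their file line numbers (header = line 1). If more than
#' `max_invalid_frac` of a table's rows are invalid the whole validation
#' aborts; otherwise invalid rows are dropped from the returned tables and
#' reported.
#'
#' @param paths Named character vector or list; names among `cohort`,
#'   `curves`, `biplane`, `phasic`; values are CSV paths.
#' @param max_invalid_frac Abort threshold for the invalid-row fraction
#'   (default 0.1).
#' @return List with `tables` (named list of cleaned data frames) and
#'   `issues` (data.frame: `table`, `line`, `column`, `problem`).
#' @export
validate_tables <- function(paths, max_invalid_frac = 0.1) {
  schemas <- table_schemas()
  unknown <- setdiff(names(paths), names(schemas))
  if (length(unknown)) {
    abort_validation(sprintf("unknown table name(s): %s", paste(unknown, collapse = ", ")))
  }
  tables <- list()
  issues <- list()
  for (nm in names(paths)) {
    path <- paths[[nm]]
    if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    sch <- schemas[[nm]]
    missing <- setdiff(sch$required, names(df))
    if (length(missing)) {
      abort_validation(sprintf("table '%s' missing column(s): %s",
                               nm, paste(missing, collapse = ", ")))
    }
    bad <- rep(FALSE, nrow(df))
    for (col in names(sch$checks)) {
      v <- df[[col]]
      if (!is.numeric(v)) {
        suppressWarnings(v <- as.numeric(v))
      }
      ok <- !is.na(v) & sch$checks[[col]](v)
      if (any(!ok)) {
        rows <- which(!ok)
        issues[[length(issues) + 1L]] <- data.frame(
          table = nm, line = rows + 1L, column = col,
          problem = "failed range/type check", stringsAsFactors = FALSE
        )
        bad <- bad | !ok
      }
      df[[col]] <- v
    }
    if (nrow(df) > 0 && mean(bad) > max_invalid_frac) {
      abort_validation(sprintf(
        "table '%s': %.0f%% of rows invalid (limit %.0f%%)",
        nm, 100 * mean(bad), 100 * max_invalid_frac
      ))
    }
    tables[[nm]] <- df[!bad, , drop = FALSE]
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(table = character(), line = integer(), column = character(),
               problem = character(), stringsAsFactors = FALSE)
  list(tables = tables, issues = issues)
}

# write.csv wrapper whose output is stable under write -> read -> write:
# numbers are serialized with as.character (15 significant digits), which
# round-trips through read.csv to the identical string.
write_table_csv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Long-format curves table for a list of curves
#'
#' @param curves List of `la_curve` objects.
#' @return `data.frame` with `patient_id`, `frame`, `time_ms`,
#'   `volume_ml_m2`.
#' @export
curves_to_table <- function(curves) {
  out <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(patient_id = cv$patient_id, frame = seq_len(cv$n_frames) - 1L,
               time_ms = cv$times, volume_ml_m2 = cv$volumes,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
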