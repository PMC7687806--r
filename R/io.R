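# Table contracts: every interchange file is headered, comma-delimited,
# UTF-8 text with ISO-8601 UTC timestamps ("%Y-%m-%dT%H:%M:%SZ").

TABLE_SPECS <- list(
  vitals = list(cols = c("encounter_id", "timestamp", "channel", "value"),
                time_cols = "timestamp",
                key = c("encounter_id", "channel", "timestamp")),
  labs = list(cols = c("encounter_id", "timestamp", "analyte", "value"),
              time_cols = "timestamp", key = NULL),
  consciousness = list(cols = c("encounter_id", "timestamp", "scale",
                                "value"),
                       time_cols = "timestamp", key = NULL),
  medications = list(cols = c("encounter_id", "drug_name", "start_time"),
                     time_cols = "start_time", key = NULL),
  encounters = list(cols = c("encounter_id", "unit", "admission",
                             "discharge"),
                    time_cols = c("admission", "discharge"),
                    key = "encounter_id"),
  sofa_daily = list(cols = c("encounter_id", "date"), time_cols = NULL,
                    key = c("encounter_id", "date")),
  episodes = list(cols = c("encounter_id", "episode_id", "start_time",
                           "end_time"),
                  time_cols = c("start_time", "end_time"), key = NULL),
  determinations = list(cols = c("encounter_id", "episode_id", "score",
                                 "positive"),
                        time_cols = "first_positive_time", key = NULL),
  truth = list(cols = c("encounter_id", "infected", "dies"),
               time_cols = "infection_onset", key = "encounter_id"),
  results = list(cols = c("stratum", "score", "outcome"), time_cols = NULL,
                 key = NULL)
)

TIME_FMT <- "%Y-%m-%dT%H:%M:%SZ"

fmt_time <- function(t) {
  out <- format(t, TIME_FMT, tz = "UTC")
  out[is.na(t)] <- ""
  out
}

parse_time_col <- function(x, col, file) {
  if (inherits(x, "POSIXct")) {      # fread already recognized ISO-8601 UTC
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(x, format = TIME_FMT, tz = "UTC")
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: unparseable %s timestamps at data line(s) %s (e.g. \"%s\")",
                 basename(file), col,
                 paste(utils::head(bad, 5), collapse = ", "), x[bad[1]]))
  }
  out
}

#' Write a pipeline table to CSV
#'
#' @param table data.frame/data.table to write.
#' @param path output file.
#' @param type one of the known table types (`"vitals"`, `"labs"`,
#'   `"consciousness"`, `"medications"`, `"encounters"`, `"sofa_daily"`,
#'   `"episodes"`, `"determinations"`, `"truth"`, `"results"`).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, type) {
  spec <- TABLE_SPECS[[match.arg(type, names(TABLE_SPECS))]]
  d <- as.data.table(table)  # copy; we mutate time columns into text
  for (tc in intersect(spec$time_cols, names(d))) {
    set(d, j = tc, value = fmt_time(d[[tc]]))
  }
  fwrite(d, path)
  invisible(path)
}

#' Read and validate a pipeline table from CSV
#'
#' Checks the column contract, parses ISO-8601 timestamps (errors name the
#' offending line), and rejects duplicated grid keys.
#'
#' @param path input file.
#' @param type table type, see [write_table()].
#' @return a data.table.
#' @export
read_table <- function(path, type) {
  type <- match.arg(type, names(TABLE_SPECS))
  spec <- TABLE_SPECS[[type]]
  if (!file.exists(path)) stop("read_table(): no such file: ", path)
  d <- fread(path, colClasses = if (type == "vitals")
    list(character = "encounter_id") else NULL)
  miss <- setdiff(spec$cols, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  }
  for (tc in intersect(spec$time_cols, names(d))) {
    set(d, j = tc, value = parse_time_col(d[[tc]], tc, path))
  }
  if ("date" %in% names(d)) set(d, j = "date", value = as.Date(d$date))
  if (!is.null(spec$key) && all(spec$key %in% names(d))) {
    dup <- duplicated(d, by = spec$key)
    if (any(dup)) {
      keys <- d[dup, spec$key, with = FALSE]
      stop(sprintf("%s: duplicated key(s) (%s): %s", basename(path),
                   paste(spec$key, collapse = ", "),
                   paste(utils::head(do.call(paste, keys), 3),
                         collapse = "; ")))
    }
  }
  d
}

COHORT_TABLES <- c("encounters", "vitals", "labs", "consciousness",
                   "sofa_daily", "medications", "truth")

#' Write a synthetic cohort to a directory of CSV files
#'
#' One file per table (`encounters.csv`, `vitals.csv`, ...). The `truth.csv`
#' ground-truth table is written alongside for validation; the pipeline never
#' reads it.
#'
#' @param cohort a `sepsis_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in COHORT_TABLES) {
    write_table(cohort[[tb]], file.path(dir, paste0(tb, ".csv")), tb)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort CSV files.
#' @return named list of data.tables (tables that exist in `dir`).
#' @export
read_cohort <- function(dir) {
  out <- list()
  for (tb in COHORT_TABLES) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (file.exists(f)) out[[tb]] <- read_table(f, tb)
  }
  if (!length(out)) stop("read_cohort(): no cohort tables found in ", dir)
  out
}
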