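# CSV table I/O with typed schemas, ISO-8601 UTC timestamps and a
# provenance comment header (tool version, seed, config hash). CSV is the
# interchange format because transmitter vendor exports are CSV-like.

TABLE_SCHEMAS <- list(
  acc = list(cols = c("bird_id", "burst_id", "timestamp_utc", "sample_idx",
                      "x_g", "y_g", "z_g"), time = "timestamp_utc"),
  gps = list(cols = c("bird_id", "timestamp_utc", "lat", "lon"),
             time = "timestamp_utc"),
  weather = list(cols = c("timestamp_utc", "temp_c", "wind_ms"),
                 time = "timestamp_utc"),
  truth = list(cols = c("bird_id", "burst_id", "timestamp_utc", "behavior",
                        "sub_behavior", "period"), time = "timestamp_utc"),
  scans = list(cols = c("scan_id", "timestamp_utc", "bird_idx", "behavior",
                        "distance_m"), time = "timestamp_utc"),
  behaviors = list(cols = c("bird_id", "burst_id", "timestamp_utc",
                            "behavior"), time = "timestamp_utc"),
  features = list(cols = "burst_id", time = NULL),
  censor = list(cols = c("bird_id", "release_date", "last_day",
                         "changepoints", "effect_sizes", "censored_through",
                         "included"), time = NULL)
)

fmt_iso8601 <- function(x) format(as_utc(x), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a pipeline table to CSV
#'
#' Writes with a `#`-prefixed provenance header (package version, seed,
#' config hash) and ISO-8601 UTC timestamps; [read_table()] reverses it
#' exactly.
#'
#' @param df the table.
#' @param path output path.
#' @param schema schema name (one of `names(TABLE_SCHEMAS)`) used to
#'   validate required columns; `NULL` skips validation.
#' @param seed,config_hash provenance fields recorded in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema = NULL, seed = NA,
                        config_hash = NA) {
  if (!is.null(schema)) {
    sch <- TABLE_SCHEMAS[[schema]]
    miss <- setdiff(sch$cols, names(df))
    if (length(miss)) stop_db("table lacks required column(s): ",
                              paste(miss, collapse = ", "))
    if (!is.null(sch$time)) df[[sch$time]] <- fmt_iso8601(df[[sch$time]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# divebudget %s; seed=%s; config=%s",
    as.character(utils::packageVersion("divebudget")), seed, config_hash),
    con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline table from CSV
#'
#' Validates the schema's required columns (an error names any missing
#' column) and parses timestamp columns as UTC ISO-8601; a malformed
#' timestamp is an error reporting its row number. A header-only file
#' yields zero records without error.
#'
#' @param path CSV path.
#' @param schema schema name; `NULL` skips validation/parsing.
#' @return the table as a data frame.
#' @export
read_table <- function(path, schema = NULL) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    sch <- TABLE_SCHEMAS[[schema]]
    miss <- setdiff(sch$cols, names(df))
    if (length(miss)) stop_db(path, " lacks required column(s): ",
                              paste(miss, collapse = ", "))
    if (!is.null(sch$time) && nrow(df)) {
      parsed <- as.POSIXct(df[[sch$time]], tz = "UTC",
                           format = "%Y-%m-%dT%H:%M:%SZ")
      if (anyNA(parsed)) {
        stop_db(path, ": malformed timestamp at row(s) ",
                paste(head(which(is.na(parsed)), 5), collapse = ", "))
      }
      df[[sch$time]] <- parsed
    }
  }
  df
}
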