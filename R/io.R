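# Plain-CSV serialization of systems tables and result bundles. The systems
# file starts with a versioned comment header so schema drift is caught at
# read time; numeric columns are written with round-trippable precision.

SYSTEMS_FILE_VERSION <- "welfareLCA_systems_v1"

#' Write a systems table to CSV
#'
#' UTF-8 CSV with a `#`-prefixed version line ahead of the column header.
#' Numeric values are written with 17 significant digits so that
#' `read_systems(write_systems(x))` reproduces `x` exactly.
#'
#' @param systems A [pig_systems()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_systems <- function(systems, path) {
  df <- as.data.frame(systems)[, systems_columns()]
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", SYSTEMS_FILE_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a systems table from CSV
#'
#' Checks the schema version line and the column header, normalizes label
#' names, validates every row via [validate_systems()] and returns a
#' [pig_systems()] table. Malformed rows are reported with their
#' `system_id` and offending column.
#'
#' @param path Path to a file written by [write_systems()].
#' @return A [pig_systems()] table (possibly with zero rows).
#' @export
read_systems <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!identical(first, paste0("# ", SYSTEMS_FILE_VERSION))) {
    stop("unrecognized systems file version (expected '",
         SYSTEMS_FILE_VERSION, "')", call. = FALSE)
  }
  df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                        na.strings = "", colClasses = "character",
                        check.names = FALSE)
  if (!identical(names(df), systems_columns())) {
    stop("systems file header does not match the v1 schema", call. = FALSE)
  }
  if (nrow(df) == 0L) {
    df <- empty_systems_frame()
    class(df) <- c("pig_systems", "data.frame")
    return(df)
  }
  df$labels_held[is.na(df$labels_held)] <- ""
  numeric_cols <- c(sp_score_cols, fp_score_cols, production_cols)
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop("malformed value in row ", bad[1], " (system_id=",
           df$system_id[bad[1]], "), column ", col, ": '",
           df[[col]][bad[1]], "'", call. = FALSE)
    }
    df[[col]] <- parsed
  }
  pig_systems(df)
}

empty_systems_frame <- function() {
  df <- as.data.frame(setNames(
    lapply(systems_columns(), function(col) {
      if (col %in% c(sp_score_cols, fp_score_cols, production_cols)) {
        numeric(0)
      } else character(0)
    }), systems_columns()))
  df
}
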