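# Table schemas: required/optional column types plus row-level checks that
# report offending line numbers.

table_schemas <- function() {
  list(
    events = list(
      required = c(cell_line = "character", metaphase_id = "character",
                   pulse_index = "integer", arm_id = "character",
                   homolog = "character", status = "character"),
      optional = c(true_time = "numeric", true_status = "character",
                   red_s1 = "numeric", green_s1 = "numeric",
                   red_s2 = "numeric", green_s2 = "numeric"),
      checks = function(df) {
        bad <- which(!(df$status %in%
                         c("detargeted", "mixed", "unscorable")))
        msg <- if (length(bad))
          paste0("invalid status at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", "))
        c(msg,
          check_nonneg(df, c("red_s1", "green_s1", "red_s2", "green_s2")),
          check_positive_int(df, "pulse_index"))
      }
    ),
    counts = list(
      required = c(arm_id = "character", pulse_index = "integer",
                   n_scored = "integer", n_detargeted = "integer"),
      optional = character(0),
      checks = function(df) {
        c(check_nonneg(df, c("n_scored", "n_detargeted")),
          check_positive_int(df, "pulse_index"),
          {
            bad <- which(df$n_detargeted > df$n_scored)
            if (length(bad))
              paste0("n_detargeted > n_scored at row(s) ",
                     paste(utils::head(bad, 5), collapse = ", "))
          })
      }
    ),
    spots3d = list(
      required = c(nucleus_id = "character", arm_id = "character",
                   x_um = "numeric", y_um = "numeric", z_um = "numeric"),
      optional = character(0),
      checks = function(df) NULL
    ),
    qfish = list(
      required = c(metaphase_id = "character", arm_id = "character",
                   homolog = "character", intensity = "numeric"),
      optional = character(0),
      checks = function(df) check_nonneg(df, "intensity")
    )
  )
}

check_nonneg <- function(df, cols) {
  msgs <- NULL
  for (col in intersect(cols, names(df))) {
    bad <- which(df[[col]] < 0)
    if (length(bad))
      msgs <- c(msgs, paste0("negative ", col, " at row(s) ",
                             paste(utils::head(bad, 5), collapse = ", ")))
  }
  msgs
}

check_positive_int <- function(df, col) {
  bad <- which(df[[col]] < 1 | df[[col]] != round(df[[col]]))
  if (length(bad))
    paste0(col, " must be a positive integer; bad row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
}

#' Read and validate a pipeline TSV table
#'
#' Reads a tab-separated table and validates it against one of the package
#' schemas (`"events"`, `"counts"`, `"spots3d"`, `"qfish"`): required
#' columns must be present with the right type, and row-level constraints
#' (non-negative counts, valid status labels, ...) are reported with row
#' numbers.
#'
#' @param path Path to a TSV file with a header line.
#' @param schema Schema name.
#' @return The validated data.frame.
#' @export
read_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!is.character(schema) || length(schema) != 1L ||
      !schema %in% names(schemas))
    stop_input("`schema` must be one of: ",
               paste(names(schemas), collapse = ", "))
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  if (!nrow(df)) stop_input("empty table: ", path)
  sc <- schemas[[schema]]
  missing <- setdiff(names(sc$required), names(df))
  if (length(missing))
    stop_input("schema '", schema, "': missing required column(s): ",
               paste(missing, collapse = ", "))
  types <- c(sc$required, sc$optional)
  for (col in intersect(names(types), names(df))) {
    want <- types[[col]]
    if (want == "character") df[[col]] <- as.character(df[[col]])
    else {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad))
        stop_input("schema '", schema, "': non-numeric ", col,
                   " at row(s) ",
                   paste(utils::head(bad, 5), collapse = ", "))
      df[[col]] <- if (want == "integer") as.integer(round(v)) else v
    }
  }
  msgs <- sc$checks(df)
  msgs <- msgs[!vapply(msgs, is.null, logical(1))]
  if (length(msgs))
    stop_input("schema '", schema, "' validation failed: ",
               paste(unlist(msgs), collapse = "; "))
  df
}

#' Write a pipeline table as TSV
#'
#' UTF-8, tab-separated, `.` decimal separator, header line, no quoting or
#' row names — the package's interchange format.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
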