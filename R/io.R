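#' @keywords internal
table_schemas <- function() {
  lesion_cols <- lesion_weights()$category
  list(
    survival = list(
      columns = c("individual_id", "group", "aquarium", "day", "event"),
      check = function(df) {
        bad <- which(!df$event %in% c(0L, 1L))
        if (length(bad)) return(sprintf("row %d: event must be 0 or 1", bad[1]))
        bad <- which(df$day < 1)
        if (length(bad)) return(sprintf("row %d: day must be >= 1", bad[1]))
        NULL
      }
    ),
    biomarkers = list(
      columns = c("individual_id", "group", "analyte", "value", "units"),
      check = function(df) {
        bad <- which(!is.finite(df$value) | df$value < 0)
        if (length(bad)) return(sprintf("row %d: value must be a non-negative number", bad[1]))
        NULL
      }
    ),
    lesions = list(
      columns = c("individual_id", "group", lesion_cols),
      check = function(df) {
        for (col in lesion_cols) {
          bad <- which(!df[[col]] %in% score_levels())
          if (length(bad)) {
            return(sprintf("row %d: %s score %s not on the 0/2/4/6 scale",
                           bad[1], col, df[[col]][bad[1]]))
          }
        }
        NULL
      }
    ),
    morphometry = list(
      columns = c("individual_id", "group", "tubule_id", "tubule_area_um2",
                  "lumen_area_um2", "wall_area_um2"),
      check = function(df) {
        bad <- which(df$tubule_area_um2 <= 0 | df$lumen_area_um2 < 0 |
                       df$wall_area_um2 < 0)
        if (length(bad)) return(sprintf("row %d: non-positive tubule area", bad[1]))
        NULL
      }
    ),
    comet_cells = list(
      columns = c("individual_id", "group", "cell_id", "tailed",
                  "head_boundary_um", "bin_um", "profile"),
      check = function(df) {
        bad <- which(df$head_boundary_um <= 0 | df$bin_um <= 0)
        if (length(bad)) return(sprintf("row %d: non-positive geometry", bad[1]))
        NULL
      }
    )
  )
}

#' Read a validated pipeline table
#'
#' Reads one of the pipeline's CSV schemas (`survival`, `biomarkers`,
#' `lesions`, `morphometry`, `comet_cells`), checks mandatory columns and
#' per-row value constraints, and fails fast with a diagnostic naming the
#' offending file and row. Unknown extra columns are kept with a warning;
#' an empty file with a valid header is an empty record set, not an error.
#'
#' @param path CSV file path.
#' @param schema schema name.
#' @return Validated data frame.
#' @export
read_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    stop("unknown schema: ", schema, call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("group" %in% names(df)) df$group <- as.character(df$group)
  if ("individual_id" %in% names(df)) df$individual_id <- as.character(df$individual_id)
  sc <- schemas[[schema]]
  missing <- setdiff(sc$columns, names(df))
  if (length(missing)) {
    stop(path, ": missing mandatory columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), sc$columns)
  if (length(extra)) {
    warning(path, ": unknown columns kept as-is: ", paste(extra, collapse = ", "))
  }
  if (nrow(df)) {
    msg <- sc$check(df)
    if (!is.null(msg)) stop(path, ": ", msg, call. = FALSE)
  }
  df
}

#' Write a pipeline table
#'
#' Plain CSV with the schema's fixed header, no row names; the write/read
#' round trip is lossless for the pipeline schemas.
#'
#' @param records data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
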