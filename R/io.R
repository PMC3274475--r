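# Schema-validated CSV I/O. All tables travel as comma-separated UTF-8 text
# with a mandatory header; GEOIDs are zero-padded strings and dates ISO-8601
# strings throughout, so round-trips are lossless and byte-reproducible.

.SCHEMAS <- list(
  grid = list(
    cols = c(cell_id = "character", lat = "numeric", lon = "numeric",
             date = "character", value = "numeric", se = "numeric")),
  bg = list(
    cols = c(geoid = "character", lat = "numeric", lon = "numeric",
             population = "integer")),
  bg_est = list(
    cols = c(geoid = "character", date = "character", mu = "numeric",
             delta = "numeric")),
  exposures = list(
    cols = c(geoid = "character", level = "character", date = "character",
             pe = "numeric", psi = "numeric", population = "numeric")),
  stations = list(
    cols = c(station_id = "character", bg_geoid = "character",
             date = "character", observed = "numeric"),
    optional = c(urban_rural = "character"))
)

.ISO_DATE_RE <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"

.check_rows <- function(dt, schema_name) {
  viol <- character()
  date_cols <- intersect(c("date"), names(dt))
  for (dc in date_cols) {
    bad <- which(!grepl(.ISO_DATE_RE, dt[[dc]]))
    if (length(bad)) {
      viol <- c(viol, sprintf("row %d: %s '%s' is not an ISO-8601 date",
                              utils::head(bad, 3), dc,
                              dt[[dc]][utils::head(bad, 3)]))
    }
  }
  geoid_col <- intersect(c("geoid", "bg_geoid"), names(dt))
  for (gc in geoid_col) {
    # 12-digit BG GEOIDs except in the exposures table, whose geoid column
    # holds unit prefixes of level-dependent width (or "US")
    if (schema_name == "exposures") next
    bad <- which(!grepl("^[0-9]{12}$", dt[[gc]]))
    if (length(bad)) {
      viol <- c(viol, sprintf("row %d: %s '%s' is not a 12-digit GEOID",
                              utils::head(bad, 3), gc,
                              dt[[gc]][utils::head(bad, 3)]))
    }
  }
  viol
}

#' Read a schema-validated CSV table
#'
#' Known schemas: `"grid"` (cell_id, lat, lon, date, value, se), `"bg"`
#' (geoid, lat, lon, population), `"bg_est"` (geoid, date, mu, delta),
#' `"exposures"` (geoid, level, date, pe, psi, population) and `"stations"`
#' (station_id, bg_geoid, date, observed \[, urban_rural\]). Columns are
#' checked for presence and type, GEOIDs for 12-digit format, dates for
#' ISO-8601 format; violations are reported with row numbers. An empty file
#' with a valid header yields an empty table with a warning.
#'
#' @param path CSV file path.
#' @param schema one of the schema names above.
#' @return data.table conforming to the schema.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(.SCHEMAS))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sc <- .SCHEMAS[[schema]]
  classes <- c(sc$cols, sc$optional)
  hdr <- names(data.table::fread(path, nrows = 0L, header = TRUE))
  classes <- classes[names(classes) %in% hdr]  # avoid colClasses warnings
  dt <- data.table::fread(path, colClasses = list(
    character = names(classes)[classes == "character"],
    numeric = names(classes)[classes == "numeric"],
    integer = names(classes)[classes == "integer"]),
    header = TRUE, data.table = TRUE, encoding = "UTF-8")
  missing_cols <- setdiff(names(sc$cols), names(dt))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(dt) == 0L) {
    warning(sprintf("%s: empty table (header only)", path))
    return(dt[])
  }
  viol <- .check_rows(dt, schema)
  if (length(viol)) {
    stop(sprintf("%s: %d row-level violation(s), first offenders:\n  %s",
                 path, length(viol),
                 paste(utils::head(viol, 5), collapse = "\n  ")))
  }
  dt[]
}

#' Write a pipeline CSV table
#'
#' Full double precision (up to 15 significant digits), comma-separated,
#' UTF-8, with header — so identical inputs produce byte-identical outputs.
#'
#' @param dt data.frame/data.table.
#' @param path output path (parent directory must exist).
#' @return invisibly `path`.
#' @export
write_table <- function(dt, path) {
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}
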