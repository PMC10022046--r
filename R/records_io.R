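# Reading, validating and filtering hospitalization records (SIH/SUS RD-style
# CSV stand-ins) and the municipality registry.

#' Normalize a municipality code to its 6-digit form
#'
#' SIH RD files carry 6-digit IBGE municipality codes; registries often carry
#' 7 digits (with a trailing check digit). Both are normalized to the 6-digit
#' form by truncating the 7th digit so joins are robust across sources.
#'
#' @param x Character or numeric vector of codes.
#' @return Character vector of 6-digit codes; `NA` where the input is not a
#'   6- or 7-digit code.
#' @export
normalize_muni_code <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^[0-9]{6,7}$", x)
  x[ok] <- substr(x[ok], 1L, 6L)
  x[!ok] <- NA_character_
  x
}

.default_schema <- c(year = "year", month = "month", origin_code = "origin_code",
                     dest_code = "dest_code", procedure_code = "procedure_code")

.fread_sniffed <- function(path) {
  # comma- or semicolon-delimited, UTF-8 with Latin-1 fallback (names of
  # Brazilian municipalities in real DATASUS exports vary in both)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (length(header) && lengths(regmatches(header, gregexpr(";", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
  dt <- tryCatch(
    data.table::fread(path, sep = sep, colClasses = "character", encoding = "UTF-8"),
    error = function(e)
      data.table::fread(path, sep = sep, colClasses = "character", encoding = "Latin-1")
  )
  if (!all(validUTF8(unlist(lapply(dt, as.character), use.names = FALSE)))) {
    dt <- dt[, lapply(.SD, function(col) iconv(col, from = "latin1", to = "UTF-8"))]
  }
  dt
}

#' Read hospitalization records
#'
#' One row is one hospitalization authorization (AIH), not one unique patient;
#' duplicates are kept. Rows violating a field invariant are not silently
#' dropped: they are collected into a rejection report retrievable with
#' [rejected_records()], and `nrow(records) + nrow(rejections)` always equals
#' the input row count.
#'
#' @param path CSV file (comma- or semicolon-delimited, auto-detected) with
#'   columns `year,month,origin_code,dest_code,procedure_code`, remappable via
#'   `schema`.
#' @param schema Named character vector mapping the canonical field names to
#'   the file's column names.
#' @param year_range Two integers; records outside this competence-year window
#'   are rejected.
#' @return A `data.table` of valid records (canonical columns, codes
#'   normalized to 6 digits) with attribute `"rejections"`.
#' @export
read_records <- function(path, schema = NULL,
                         year_range = c(1980L, 2100L)) {
  if (!file.exists(path)) stop(sprintf("records file not found: %s", path))
  sch <- .default_schema
  if (!is.null(schema)) sch[names(schema)] <- schema
  raw <- .fread_sniffed(path)
  if (nrow(raw) == 0L) {
    warning(sprintf("records file is empty: %s", path))
    out <- data.table::data.table(year = integer(), month = integer(),
                                  origin_code = character(), dest_code = character(),
                                  procedure_code = character())
    data.table::setattr(out, "rejections", .empty_rejections())
    return(out)
  }
  missing <- setdiff(unname(sch), names(raw))
  if (length(missing))
    stop(sprintf("schema error: mapped column(s) not in header: %s",
                 paste(missing, collapse = ", ")))
  dt <- data.table::data.table(
    year = suppressWarnings(as.integer(raw[[sch[["year"]]]])),
    month = suppressWarnings(as.integer(raw[[sch[["month"]]]])),
    origin_code = normalize_muni_code(raw[[sch[["origin_code"]]]]),
    dest_code = normalize_muni_code(raw[[sch[["dest_code"]]]]),
    procedure_code = trimws(raw[[sch[["procedure_code"]]]])
  )
  reasons <- rep(NA_character_, nrow(dt))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- why
  }
  flag(is.na(dt$year) | dt$year < year_range[1] | dt$year > year_range[2],
       sprintf("year outside [%d, %d]", year_range[1], year_range[2]))
  flag(is.na(dt$month) | dt$month < 1L | dt$month > 12L, "month not in 1..12")
  flag(is.na(dt$origin_code), "origin_code is not a 6- or 7-digit code")
  flag(is.na(dt$dest_code), "dest_code is not a 6- or 7-digit code")
  flag(is.na(dt$procedure_code) | dt$procedure_code == "", "empty procedure_code")

  bad <- !is.na(reasons)
  rej <- data.table::data.table(row = which(bad), reason = reasons[bad])
  out <- dt[!bad]
  data.table::setattr(out, "rejections", rej)
  if (nrow(rej))
    message(sprintf("read_records: %d of %d row(s) rejected (see rejected_records())",
                    nrow(rej), nrow(dt)))
  out
}

.empty_rejections <- function() data.table::data.table(row = integer(), reason = character())

#' Rejection report of a [read_records()] result
#' @param records The value returned by [read_records()].
#' @return A `data.table` with columns `row` (1-based input row) and `reason`.
#' @export
rejected_records <- function(records) {
  rej <- attr(records, "rejections", exact = TRUE)
  if (is.null(rej)) .empty_rejections() else rej
}

#' Write hospitalization records in the canonical CSV schema
#' @param records A records `data.table`.
#' @param path Output file.
#' @export
write_records <- function(records, path) {
  cols <- names(.default_schema)
  data.table::fwrite(records[, cols, with = FALSE], path)
  invisible(path)
}

#' Read a municipality registry
#'
#' @param path CSV with required columns `code,name,lat,lon` and optional
#'   `easting,northing,utm_zone,macroregion`. Codes are normalized to
#'   6 digits; duplicate codes and out-of-range coordinates are errors, as is
#'   a row carrying only part of the UTM triple.
#' @return A `data.table` keyed by `code` (class `municipality_registry`).
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop(sprintf("registry file not found: %s", path))
  raw <- .fread_sniffed(path)
  need <- c("code", "name", "lat", "lon")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop(sprintf("registry is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  reg <- data.table::data.table(
    code = normalize_muni_code(raw$code),
    name = raw$name,
    lat = as.numeric(raw$lat),
    lon = as.numeric(raw$lon)
  )
  if (anyNA(reg$code))
    stop(sprintf("registry has invalid municipality code(s): %s",
                 paste(unique(raw$code[is.na(reg$code)]), collapse = ", ")))
  dup <- unique(reg$code[duplicated(reg$code)])
  if (length(dup))
    stop(sprintf("registry has duplicated code(s): %s", paste(dup, collapse = ", ")))
  bad <- reg$lat < -90 | reg$lat > 90 | reg$lon < -180 | reg$lon > 180 |
    is.na(reg$lat) | is.na(reg$lon)
  if (any(bad))
    stop(sprintf("registry has out-of-range lat/lon for code(s): %s",
                 paste(reg$code[bad], collapse = ", ")))
  utm_cols <- c("easting", "northing", "utm_zone")
  if (any(utm_cols %in% names(raw))) {
    has <- vapply(utm_cols, function(cl)
      if (cl %in% names(raw)) !is.na(raw[[cl]]) & raw[[cl]] != "" else rep(FALSE, nrow(raw)),
      logical(nrow(raw)))
    if (!is.matrix(has)) has <- matrix(has, nrow = 1L)
    partial <- rowSums(has) %in% c(1L, 2L)
    if (any(partial))
      stop(sprintf("registry has a partial UTM triple for code(s): %s",
                   paste(reg$code[partial], collapse = ", ")))
    reg[, easting := if ("easting" %in% names(raw)) as.numeric(raw$easting) else NA_real_]
    reg[, northing := if ("northing" %in% names(raw)) as.numeric(raw$northing) else NA_real_]
    reg[, utm_zone := if ("utm_zone" %in% names(raw)) as.character(raw$utm_zone) else NA_character_]
  }
  reg[, macroregion := if ("macroregion" %in% names(raw)) as.character(raw$macroregion)
      else NA_character_]
  data.table::setkeyv(reg, "code")
  data.table::setattr(reg, "class", c("municipality_registry", class(reg)))
  reg
}

#' Construct a procedure filter
#'
#' The procedure codes defining a network (e.g. the PPI cardiovascular-surgery
#' group) are user-supplied configuration; no code list ships as a default.
#'
#' @param codes Non-empty character vector of procedure codes.
#' @param label Human-readable group label.
#' @return An object of class `procedure_filter`.
#' @export
procedure_filter <- function(codes, label = "procedure group") {
  codes <- unique(trimws(as.character(codes)))
  codes <- codes[codes != ""]
  if (!length(codes)) stop("procedure_filter: 'codes' must be a non-empty set")
  structure(list(codes = codes, label = label), class = "procedure_filter")
}

#' Read a newline-delimited procedure-code list
#' @param path Text file, one code per line; blank lines and `#` comments ignored.
#' @param label Group label.
#' @return A `procedure_filter`.
#' @export
read_procedure_codes <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop(sprintf("procedure list not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  procedure_filter(lines, label = label)
}

#' Filter records to a procedure group
#'
#' @param records A records `data.table`.
#' @param filter A `procedure_filter` (or a bare character vector of codes).
#' @return The subset of `records` whose `procedure_code` is in the filter,
#'   in the original order. Idempotent; an empty result is valid.
#' @export
filter_by_procedure <- function(records, filter) {
  if (!inherits(filter, "procedure_filter")) filter <- procedure_filter(filter)
  records[records$procedure_code %in% filter$codes]
}

#' @export
print.procedure_filter <- function(x, ...) {
  cat(sprintf("<procedure_filter> %s: %d code(s)\n", x$label, length(x$codes)))
  invisible(x)
}

#' @export
print.municipality_registry <- function(x, ...) {
  cat(sprintf("<municipality_registry> %d municipalities\n", nrow(x)))
  NextMethod()
}
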