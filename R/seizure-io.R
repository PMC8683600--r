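# Reading, validation and writing of curated seizure records.
#
# Documented CSV schema (one row per reported confiscation event):
#   record_id         opaque string, unique within a file
#   date              ISO date at day ("2019-07-21"), month ("2019-07") or
#                     year ("2019") precision; year is mandatory
#   scales,meat,claws,other
#                     masses by derivative kind; either a bare number (kg) or
#                     a number with unit: kg, g, t / tonne(s) / mt, lb(s).
#                     Empty cell = not reported.
#   item_count        integer count of items/sacks when no mass was reported
#   route             ordered country list, "|"-separated (names or alpha-3)
#   seizure_country   country where the confiscation occurred; must lie on
#                     the route
#   mode              air | land | sea | warehouse | unknown
#   detection_method  intelligence | routine_inspection | scanner |
#                     sniffer_dogs | unknown
#   suspects_arrested, prosecuted   non-negative integers or empty (unknown)
#   source_db         reporting database label (e.g. "TRAFFIC")
#   co_seized         free text on co-seized contraband (e.g. ivory mass)

.mode_levels <- c("air", "land", "sea", "warehouse", "unknown")
.detection_levels <- c("intelligence", "routine_inspection", "scanner",
                       "sniffer_dogs", "unknown")
.derivative_kinds <- c("scales", "meat", "claws", "other")

.unit_to_kg <- c(kg = 1, kgs = 1, kilogram = 1, kilograms = 1,
                 g = 0.001, gram = 0.001, grams = 0.001,
                 t = 1000, tonne = 1000, tonnes = 1000, ton = 1000,
                 tons = 1000, mt = 1000,
                 lb = 0.45359237, lbs = 0.45359237, pound = 0.45359237,
                 pounds = 0.45359237)

#' Parse a mass field to kilograms
#'
#' Accepts a bare number (interpreted as kg) or a number followed by a unit
#' (`kg`, `g`, `t`/`tonnes`, `lb`). The canonical unit is kg with 3-decimal
#' precision.
#'
#' @param x character or numeric vector.
#' @return numeric vector in kg; `NA` for empty fields; `NaN` never returned.
#'   Unparseable or negative values raise an error naming the offending value.
#' @examples
#' parse_mass(c("2.5 t", "500 g", "12", NA))
#' @export
parse_mass <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    s <- trimws(x[i])
    if (is.na(s) || !nzchar(s)) next
    m <- regmatches(s, regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*([A-Za-z]*)$",
                               s))[[1]]
    if (length(m) == 0) {
      # allow a leading minus so the negative-mass error is specific
      m2 <- regmatches(s, regexec("^(-[0-9]*\\.?[0-9]+)\\s*([A-Za-z]*)$", s))[[1]]
      if (length(m2)) stop("negative mass: '", s, "'", call. = FALSE)
      stop("unparseable mass: '", s, "'", call. = FALSE)
    }
    val <- as.numeric(m[2])
    unit <- tolower(m[3])
    if (!nzchar(unit)) unit <- "kg"
    if (!unit %in% names(.unit_to_kg))
      stop("unknown mass unit '", unit, "' in '", s, "'", call. = FALSE)
    out[i] <- round(val * .unit_to_kg[[unit]], 3)
  }
  out
}

# Parse a date string at day/month/year precision.
# Returns list(date = Date, year, month, precision) or NULL if malformed.
.parse_seizure_date <- function(s) {
  s <- trimws(as.character(s))
  if (is.na(s) || !nzchar(s)) return(NULL)
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", s)) {
    d <- as.Date(s)
    if (is.na(d)) return(NULL)
    return(list(date = d, year = as.integer(format(d, "%Y")),
                month = as.integer(format(d, "%m")), precision = "day"))
  }
  if (grepl("^\\d{4}-\\d{2}$", s)) {
    d <- as.Date(paste0(s, "-01"))
    if (is.na(d)) return(NULL)
    return(list(date = d, year = as.integer(substr(s, 1, 4)),
                month = as.integer(substr(s, 6, 7)), precision = "month"))
  }
  if (grepl("^\\d{4}$", s)) {
    y <- as.integer(s)
    return(list(date = as.Date(paste0(s, "-01-01")), year = y,
                month = NA_integer_, precision = "year"))
  }
  NULL
}

.format_seizure_date <- function(date, precision) {
  switch(precision,
         day   = format(date, "%Y-%m-%d"),
         month = format(date, "%Y-%m"),
         year  = format(date, "%Y"))
}

.norm_enum <- function(x, levels, default = "unknown") {
  x <- tolower(gsub("[ -]+", "_", trimws(as.character(x))))
  x[is.na(x) | !nzchar(x)] <- default
  x[!x %in% levels] <- NA_character_
  x
}

.parse_count <- function(x) {
  x <- suppressWarnings(as.integer(as.character(x)))
  x
}

#' Read seizure records from CSV
#'
#' Parses the documented seizure schema, converting all masses to kg,
#' normalising countries to alpha-3 codes and transport modes / detection
#' methods to their canonical levels. Rows that cannot be parsed (malformed
#' date, negative mass, empty route, seizure country off the route,
#' multi-country warehouse record) are rejected, never silently dropped:
#' diagnostics are attached as the `"diagnostics"` attribute and summarised
#' in a warning.
#'
#' @param path path to a CSV file following the documented schema.
#' @return a tibble of seizure records with one row per event and columns
#'   `record_id`, `date`, `year`, `month`, `date_precision`,
#'   `mass_scales_kg`, `mass_meat_kg`, `mass_claws_kg`, `mass_other_kg`,
#'   `mass_total_kg`, `mass_known`, `item_count`, `route` (list column of
#'   alpha-3 codes), `seizure_country`, `mode`, `detection_method`,
#'   `suspects_arrested`, `prosecuted`, `source_db`, `co_seized`.
#' @seealso [write_seizures()], [deduplicate_seizures()]
#' @export
read_seizures <- function(path) {
  stopifnot(file.exists(path))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  needed <- c("record_id", "date", "route", "source_db")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("seizure CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  opt <- function(col) if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))

  rows <- vector("list", nrow(raw))
  diag <- list()
  reject <- function(i, id, reason) {
    diag[[length(diag) + 1L]] <<- tibble::tibble(row = i, record_id = id,
                                                 reason = reason)
  }
  for (i in seq_len(nrow(raw))) {
    id <- raw$record_id[i]
    dt <- .parse_seizure_date(raw$date[i])
    if (is.null(dt)) { reject(i, id, "malformed or missing date"); next }
    masses <- tryCatch(
      setNames(parse_mass(vapply(.derivative_kinds, function(k) opt(k)[i],
                                 character(1))), .derivative_kinds),
      error = function(e) conditionMessage(e))
    if (is.character(masses)) { reject(i, id, masses); next }
    route <- parse_route(raw$route[i])[[1]]
    if (length(route) == 0 || anyNA(route)) {
      reject(i, id, "empty or unrecognised route"); next
    }
    sc <- opt("seizure_country")[i]
    sc <- if (is.na(sc) || !nzchar(trimws(sc))) route[length(route)] else
      suppressWarnings(normalize_country(sc))
    if (is.na(sc) || !sc %in% route) {
      reject(i, id, "seizure country absent from route"); next
    }
    mode <- .norm_enum(opt("mode")[i], .mode_levels)
    if (is.na(mode)) { reject(i, id, "unrecognised transport mode"); next }
    if (mode == "warehouse" && length(route) != 1) {
      reject(i, id, "warehouse seizure must have a single-country route"); next
    }
    det <- .norm_enum(opt("detection_method")[i], .detection_levels)
    if (is.na(det)) det <- "unknown"
    mass_known <- any(!is.na(masses))
    rows[[i]] <- tibble::tibble(
      record_id = id,
      date = dt$date, year = dt$year, month = dt$month,
      date_precision = dt$precision,
      mass_scales_kg = masses[["scales"]], mass_meat_kg = masses[["meat"]],
      mass_claws_kg = masses[["claws"]], mass_other_kg = masses[["other"]],
      mass_total_kg = if (mass_known) sum(masses, na.rm = TRUE) else NA_real_,
      mass_known = mass_known,
      item_count = .parse_count(opt("item_count")[i]),
      route = list(route), seizure_country = sc, mode = mode,
      detection_method = det,
      suspects_arrested = .parse_count(opt("suspects_arrested")[i]),
      prosecuted = .parse_count(opt("prosecuted")[i]),
      source_db = raw$source_db[i],
      co_seized = {
        cs <- opt("co_seized")[i]
        if (is.na(cs) || !nzchar(cs)) NA_character_ else cs
      })
  }
  records <- dplyr::bind_rows(rows)
  diagnostics <- if (length(diag)) dplyr::bind_rows(diag) else
    tibble::tibble(row = integer(), record_id = character(), reason = character())
  if (nrow(diagnostics))
    warning(nrow(diagnostics), " row(s) rejected; see attr(, 'diagnostics')",
            call. = FALSE)
  attr(records, "diagnostics") <- diagnostics
  records
}

#' Write seizure records to CSV
#'
#' Inverse of [read_seizures()]: emits the documented schema so that a
#' read/write round trip preserves every field (masses as bare kg numbers,
#' dates at their original precision, routes `|`-joined).
#'
#' @param records tibble from [read_seizures()] or [simulate_seizures()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_seizures <- function(records, path) {
  fmt_num <- function(x) ifelse(is.na(x), "", as.character(x))
  out <- data.frame(
    record_id = records$record_id,
    date = mapply(.format_seizure_date, records$date, records$date_precision),
    scales = fmt_num(records$mass_scales_kg),
    meat = fmt_num(records$mass_meat_kg),
    claws = fmt_num(records$mass_claws_kg),
    other = fmt_num(records$mass_other_kg),
    item_count = fmt_num(records$item_count),
    route = vapply(records$route, paste, character(1), collapse = "|"),
    seizure_country = records$seizure_country,
    mode = records$mode,
    detection_method = records$detection_method,
    suspects_arrested = fmt_num(records$suspects_arrested),
    prosecuted = fmt_num(records$prosecuted),
    source_db = records$source_db,
    co_seized = ifelse(is.na(records$co_seized), "", records$co_seized),
    stringsAsFactors = FALSE, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate seizure-record invariants
#'
#' Checks the type invariants every curated table must satisfy: non-negative
#' masses, `mass_known` false exactly when all mass fields are absent,
#' non-empty routes containing the seizure country, and single-country routes
#' for warehouse seizures. Stops with an informative error on the first
#' violation.
#'
#' @param records seizure tibble.
#' @return `records`, invisibly, if valid.
#' @export
validate_seizures <- function(records) {
  mass_cols <- paste0("mass_", .derivative_kinds, "_kg")
  m <- as.matrix(records[mass_cols])
  if (any(m < 0, na.rm = TRUE)) stop("negative mass present", call. = FALSE)
  any_mass <- apply(!is.na(m), 1, any)
  if (!identical(unname(any_mass), unname(records$mass_known)))
    stop("mass_known inconsistent with mass fields", call. = FALSE)
  lens <- lengths(records$route)
  if (any(lens == 0)) stop("empty route present", call. = FALSE)
  on_route <- mapply(function(r, sc) sc %in% r, records$route,
                     records$seizure_country)
  if (!all(on_route)) stop("seizure country off route", call. = FALSE)
  wh <- records$mode == "warehouse"
  if (any(wh & lens != 1))
    stop("warehouse seizure with multi-country route", call. = FALSE)
  if (!all(records$mode %in% .mode_levels))
    stop("invalid transport mode", call. = FALSE)
  invisible(records)
}

#' Classify the transport mode of a multi-leg route
#'
#' A shipment's mode is the transport method used for the longest portion of
#' its route. Confiscations on premises with no origin/destination
#' information are warehouse seizures; routes with no mode information at
#' all are classed unknown.
#'
#' @param legs data frame with columns `mode` (character) and `length`
#'   (distance, or a rank where larger means longer). Zero rows means a
#'   premises seizure with no route.
#' @return one of `"air"`, `"land"`, `"sea"`, `"warehouse"`, `"unknown"`.
#' @examples
#' classify_transport_mode(data.frame(mode = c("land", "sea"), length = 1:2))
#' @export
classify_transport_mode <- function(legs) {
  if (is.null(legs) || nrow(legs) == 0) return("warehouse")
  known <- !is.na(legs$mode) & nzchar(legs$mode) &
    tolower(legs$mode) != "unknown"
  if (!any(known)) return("unknown")
  legs <- legs[known, , drop = FALSE]
  tolower(legs$mode[which.max(legs$length)])
}
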