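# Origin / transit / import classification of trade routes and flow
# aggregation over time intervals.
#
# Each country on a shipment route plays exactly one role per record: the
# first recorded location is the shipment origin, the final location the
# import country, and any intermediate locations transit countries. A
# single-location record means a seizure at source: that country is the
# origin and there is no import country. A country occurring several times
# on one route is counted at most once per role per record.

.default_intervals <- list(
  "2010-12" = c(2010, 2012),
  "2013-15" = c(2013, 2015),
  "2016-18" = c(2016, 2018),
  "2019-21" = c(2019, 2021)
)

#' Classify countries on a route into origin/transit/import roles
#'
#' @param route character vector of alpha-3 codes in travel order.
#' @return tibble with columns `country` and `role`
#'   (`"origin"`/`"transit"`/`"import"`); one row per distinct
#'   country-role pair.
#' @examples
#' classify_country_roles(c("CIV", "NGA", "VNM"))
#' @export
classify_country_roles <- function(route) {
  stopifnot(length(route) >= 1)
  n <- length(route)
  role <- c("origin", rep("transit", max(0, n - 2)),
            if (n >= 2) "import")
  out <- tibble::tibble(country = route, role = role)
  dplyr::distinct(out)
}

# records eligible for flow analysis: warehouse and unknown-mode excluded,
# and 2021 truncated at end of September
.flow_records <- function(records) {
  keep <- !records$mode %in% c("warehouse", "unknown") &
    records$date <= as.Date("2021-09-30")
  records[keep, ]
}

.interval_of <- function(year, intervals) {
  lab <- rep(NA_character_, length(year))
  for (nm in names(intervals)) {
    rng <- intervals[[nm]]
    lab[year >= rng[1] & year <= rng[2]] <- nm
  }
  lab
}

#' Aggregate country roles over time intervals
#'
#' Counts, for every implicated country and interval, how often it played
#' the origin, transit and import role, and normalises the counts to
#' proportions. Warehouse and unknown-mode confiscations are excluded, and
#' any 2021 records after September are dropped. Records falling outside
#' all intervals are excluded with a warning.
#'
#' @param records curated seizure tibble.
#' @param intervals named list of `c(first_year, last_year)` ranges, closed
#'   on both ends; the default is the four study intervals 2010-12,
#'   2013-15, 2016-18 and 2019-September 2021.
#' @return tibble with columns `country`, `interval`, `n_origin`,
#'   `n_transit`, `n_import`, `n_total`, `p_origin`, `p_transit`,
#'   `p_import`.
#' @export
aggregate_roles <- function(records, intervals = .default_intervals) {
  records <- .flow_records(records)
  lab <- .interval_of(records$year, intervals)
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " record(s) outside all intervals excluded",
            call. = FALSE)
    records <- records[!is.na(lab), ]
    lab <- lab[!is.na(lab)]
  }
  if (nrow(records) == 0)
    return(tibble::tibble(country = character(), interval = character(),
                          n_origin = integer(), n_transit = integer(),
                          n_import = integer(), n_total = integer(),
                          p_origin = numeric(), p_transit = numeric(),
                          p_import = numeric()))
  rr <- dplyr::bind_rows(lapply(seq_len(nrow(records)), function(i) {
    cr <- classify_country_roles(records$route[[i]])
    cr$interval <- lab[i]
    cr
  }))
  counts <- dplyr::summarise(dplyr::group_by(rr, country, interval, role),
                             n = dplyr::n(), .groups = "drop")
  wide <- tidyr_pivot(counts)
  wide$n_total <- wide$n_origin + wide$n_transit + wide$n_import
  wide$p_origin <- wide$n_origin / wide$n_total
  wide$p_transit <- wide$n_transit / wide$n_total
  wide$p_import <- wide$n_import / wide$n_total
  wide[order(wide$interval, wide$country), ]
}

# minimal long-to-wide for the three fixed roles (avoids a tidyr dependency)
tidyr_pivot <- function(counts) {
  keys <- unique(counts[c("country", "interval")])
  for (r in c("origin", "transit", "import")) {
    sub <- counts[counts$role == r, c("country", "interval", "n")]
    names(sub)[3] <- paste0("n_", r)
    keys <- dplyr::left_join(keys, sub, by = c("country", "interval"))
  }
  keys[is.na(keys)] <- 0L
  tibble::as_tibble(keys)
}

#' Barycentric (ternary) coordinates of a role profile
#'
#' Normalises origin/transit/import counts to the unit simplex for ternary
#' plotting. Invariant to scaling all counts by a positive constant.
#'
#' @param counts numeric vector of length 3 (origin, transit, import), or a
#'   role-profile tibble from [aggregate_roles()] (rows are converted).
#' @return for a vector, a named numeric `c(origin=, transit=, import=)`
#'   summing to 1; for a tibble, the tibble with `t_origin`, `t_transit`,
#'   `t_import` columns appended.
#' @export
ternary_coordinates <- function(counts) {
  if (is.data.frame(counts)) {
    tot <- counts$n_origin + counts$n_transit + counts$n_import
    if (any(tot <= 0)) stop("zero-count profile", call. = FALSE)
    counts$t_origin <- counts$n_origin / tot
    counts$t_transit <- counts$n_transit / tot
    counts$t_import <- counts$n_import / tot
    return(counts)
  }
  stopifnot(length(counts) == 3)
  tot <- sum(counts)
  if (tot <= 0) stop("zero-count profile", call. = FALSE)
  setNames(as.numeric(counts) / tot, c("origin", "transit", "import"))
}

#' Flow edge list from consecutive route positions
#'
#' Each pair of consecutive countries on a route contributes one directed
#' edge carrying the record's mass. Edges are aggregated per interval.
#'
#' @inheritParams aggregate_roles
#' @return tibble with columns `from`, `to`, `interval`, `mass_kg`,
#'   `n_records`.
#' @export
flow_edges <- function(records, intervals = .default_intervals) {
  records <- .flow_records(records)
  lab <- .interval_of(records$year, intervals)
  records <- records[!is.na(lab), ]
  lab <- lab[!is.na(lab)]
  rows <- list()
  for (i in seq_len(nrow(records))) {
    rt <- records$route[[i]]
    if (length(rt) < 2) next
    m <- if (isTRUE(records$mass_known[i])) records$mass_total_kg[i] else 0
    for (j in seq_len(length(rt) - 1)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        from = rt[j], to = rt[j + 1], interval = lab[i], mass_kg = m,
        n_records = 1L)
    }
  }
  if (!length(rows))
    return(tibble::tibble(from = character(), to = character(),
                          interval = character(), mass_kg = numeric(),
                          n_records = integer()))
  ed <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(dplyr::group_by(ed, from, to, interval),
                          mass_kg = sum(mass_kg), n_records = sum(n_records),
                          .groups = "drop")
  out[order(out$interval, -out$mass_kg), ]
}

#' Total mass destined per import country
#'
#' Sums the masses of records whose final route position (the import
#' country) matches, over records with a route of at least two countries.
#'
#' @param records curated seizure tibble.
#' @return tibble with columns `country`, `mass_kg`, `n_records`, sorted by
#'   decreasing mass.
#' @export
summarize_destinations <- function(records) {
  has_import <- lengths(records$route) >= 2
  records <- records[has_import, ]
  if (nrow(records) == 0)
    return(tibble::tibble(country = character(), mass_kg = numeric(),
                          n_records = integer()))
  dest <- vapply(records$route, function(r) r[length(r)], character(1))
  mass <- ifelse(records$mass_known, records$mass_total_kg, 0)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(country = dest, mass_kg = mass), country),
    mass_kg = sum(mass_kg), n_records = dplyr::n(), .groups = "drop")
  out[order(-out$mass_kg), ]
}

#' Detection-method summary table
#'
#' Groups seizures by incident country and detection method, summing mass
#' and counting incidents; records whose detection method is unknown are
#' excluded. A grand-total row (`country = "Total"`) is appended.
#'
#' @param records curated seizure tibble.
#' @return tibble with columns `country`, `method`, `mass_kg`,
#'   `n_incidents`.
#' @export
summarize_detection_methods <- function(records) {
  records <- records[records$detection_method != "unknown", ]
  mass <- ifelse(records$mass_known, records$mass_total_kg, 0)
  tab <- tibble::tibble(country = records$seizure_country,
                        method = records$detection_method, mass_kg = mass)
  out <- dplyr::summarise(dplyr::group_by(tab, country, method),
                          mass_kg = sum(mass_kg), n_incidents = dplyr::n(),
                          .groups = "drop")
  dplyr::bind_rows(out, tibble::tibble(country = "Total", method = "-",
                                       mass_kg = sum(out$mass_kg),
                                       n_incidents = sum(out$n_incidents)))
}

#' Totals and country shares for one detection method
#'
#' Operates on a detection-method table (as produced by
#' [summarize_detection_methods()] or read from a published summary):
#' sums mass and incidents for the given method and computes each
#' country's share of that method's mass.
#'
#' @param table tibble with columns `country`, `method`, `mass_kg`,
#'   `n_incidents` (a `Total` row, if present, is ignored).
#' @param method detection method to summarise (e.g. `"intelligence"`).
#' @return list with `mass_kg`, `n_incidents`, and `share` (tibble:
#'   `country`, `mass_kg`, `share_pct`).
#' @export
detection_totals <- function(table, method) {
  tab <- table[table$country != "Total" & table$method == method, ]
  tot <- sum(tab$mass_kg)
  list(mass_kg = tot, n_incidents = sum(tab$n_incidents),
       share = tibble::tibble(country = tab$country, mass_kg = tab$mass_kg,
                              share_pct = 100 * tab$mass_kg / tot))
}
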