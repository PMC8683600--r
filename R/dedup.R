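# Multi-source deduplication of seizure records.
#
# Reporting databases overlap heavily: one physical seizure typically appears
# in at least two of the source databases, often with inconsistent masses
# (reported mass is the most inconsistent field across sources). One database
# is designated the reference; all other records are compared against the
# accepted set and merged when they plausibly describe the same event.

#' Deduplication key for a seizure record
#'
#' Deterministically derives the matching key used by
#' [deduplicate_seizures()]: seizure country, date bucketed to the matching
#' window, and mass quantised to the relative tolerance (or the item count
#' when no mass was reported).
#'
#' @param records seizure tibble.
#' @param date_window matching window in days.
#' @param mass_rtol relative mass tolerance.
#' @return character vector of keys, one per record.
#' @export
dedup_key <- function(records, date_window = 7, mass_rtol = 0.1) {
  day <- as.integer(records$date)
  bucket <- day %/% max(1L, as.integer(date_window))
  qmass <- ifelse(records$mass_known,
                  round(log(pmax(records$mass_total_kg, 1e-6)) /
                          log1p(mass_rtol)),
                  -1)
  paste(records$seizure_country, bucket,
        ifelse(records$mass_known, paste0("m", qmass),
               paste0("n", records$item_count)),
        sep = "|")
}

# TRUE if two records plausibly describe the same seizure event.
.same_seizure <- function(a, b, date_window, mass_rtol) {
  if (a$seizure_country != b$seizure_country) return(FALSE)
  if (abs(as.numeric(a$date - b$date)) > date_window) return(FALSE)
  if (a$mass_known && b$mass_known) {
    hi <- max(a$mass_total_kg, b$mass_total_kg)
    if (hi == 0) return(TRUE)
    return(abs(a$mass_total_kg - b$mass_total_kg) / hi <= mass_rtol)
  }
  if (!a$mass_known && !b$mass_known) {
    return(isTRUE(a$item_count == b$item_count) ||
             (is.na(a$item_count) && is.na(b$item_count)))
  }
  FALSE
}

#' Deduplicate multi-source seizure records
#'
#' Merges records that describe the same confiscation event: same seizure
#' country, dates within `date_window` days, and reported masses within
#' relative tolerance `mass_rtol` (records without mass match on equal item
#' counts). Records from `reference_db` are processed first so that, when
#' merged sources disagree, the reference database's date is kept; when
#' masses disagree, the lowest reported mass is kept. Total mass can
#' therefore only decrease. The operation is idempotent: running it on its
#' own output changes nothing.
#'
#' @param records seizure tibble (masses already harmonised to kg).
#' @param reference_db source database used as the reference (default
#'   `"TRAFFIC"`).
#' @param date_window matching window in days (default 7, i.e. +/- one week).
#' @param mass_rtol relative mass tolerance (default 0.10).
#' @return the deduplicated tibble, with a `"merge_log"` attribute: one row
#'   per merge with `kept_id`, `merged_id`, `kept_source`, `merged_source`,
#'   `kept_mass_kg`, `merged_mass_kg`, `n_way` (running size of the merged
#'   group).
#' @export
deduplicate_seizures <- function(records, reference_db = "TRAFFIC",
                                 date_window = 7, mass_rtol = 0.1) {
  if (nrow(records) == 0) {
    attr(records, "merge_log") <- .empty_merge_log()
    return(records)
  }
  ord <- order(records$source_db != reference_db, records$date)
  records <- records[ord, ]
  kept <- records[0, ]
  group_size <- integer(0)
  log_rows <- list()

  for (i in seq_len(nrow(records))) {
    cand <- records[i, ]
    hit <- 0L
    for (j in seq_len(nrow(kept))) {
      if (.same_seizure(kept[j, ], cand, date_window, mass_rtol)) { hit <- j; break }
    }
    if (hit == 0L) {
      kept <- dplyr::bind_rows(kept, cand)
      group_size <- c(group_size, 1L)
      next
    }
    group_size[hit] <- group_size[hit] + 1L
    log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
      kept_id = kept$record_id[hit], merged_id = cand$record_id,
      kept_source = kept$source_db[hit], merged_source = cand$source_db,
      kept_mass_kg = kept$mass_total_kg[hit],
      merged_mass_kg = cand$mass_total_kg,
      n_way = group_size[hit])
    # lowest-mass rule: replace the kept masses when the newcomer reports less
    if (isTRUE(cand$mass_known) && isTRUE(kept$mass_known[hit]) &&
        cand$mass_total_kg < kept$mass_total_kg[hit]) {
      mass_cols <- c("mass_scales_kg", "mass_meat_kg", "mass_claws_kg",
                     "mass_other_kg", "mass_total_kg")
      kept[hit, mass_cols] <- cand[, mass_cols]
    }
    # prefer the record that has mass over one that lacks it
    if (isTRUE(cand$mass_known) && !isTRUE(kept$mass_known[hit])) {
      mass_cols <- c("mass_scales_kg", "mass_meat_kg", "mass_claws_kg",
                     "mass_other_kg", "mass_total_kg", "mass_known")
      kept[hit, mass_cols] <- cand[, mass_cols]
    }
    kept$source_db[hit] <- paste(unique(c(strsplit(kept$source_db[hit],
                                                   "\\+")[[1]],
                                          cand$source_db)), collapse = "+")
  }
  merge_log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
    .empty_merge_log()
  attr(kept, "merge_log") <- merge_log
  kept
}

.empty_merge_log <- function() {
  tibble::tibble(kept_id = character(), merged_id = character(),
                 kept_source = character(), merged_source = character(),
                 kept_mass_kg = numeric(), merged_mass_kg = numeric(),
                 n_way = integer())
}

#' Write a merge log as JSON lines
#'
#' @param records output of [deduplicate_seizures()] (carries the
#'   `"merge_log"` attribute) or a merge-log tibble.
#' @param path output file; one JSON object per merged record.
#' @return `path`, invisibly.
#' @export
write_merge_log <- function(records, path) {
  log <- attr(records, "merge_log")
  if (is.null(log)) log <- records
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(log)) {
    for (i in seq_len(nrow(log)))
      writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                  na = "null"), con)
  }
  invisible(path)
}
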