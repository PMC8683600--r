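# Seeded synthetic generators for seizure databases and sampled scale
# sacks. The defaults emulate the study conditions of the Nigeria-linked
# trade: 67 sampled sacks of 6-104 kg dominated by single-species
# white-bellied sacks, and lognormal seizure masses with a year-by-mode
# trend (sea shipments growing, air and land declining). All generators are
# pure functions of (config, seed).

#' Configuration for the seizure-database simulator
#'
#' @param years inclusive year range of simulated seizures.
#' @param mode_probs named probabilities of the five transport-mode classes;
#'   must sum to 1.
#' @param base_log10 named per-mode baseline log10 mass (kg) at the first
#'   year, for the three transported modes plus warehouse/unknown.
#' @param trend_log10 named per-mode yearly trend on the log10 scale;
#'   defaults have sea increasing and air/land declining.
#' @param sd_log10 residual standard deviation on the log10 scale.
#' @param route_len_probs probabilities of route lengths 1-4.
#' @param origin_pool,transit_pool,import_pool alpha-3 country pools; every
#'   route passes through Nigeria in one of its roles.
#' @param p_no_mass probability that a record lacks mass data (an item
#'   count is reported instead).
#' @return list of class `seizure_sim_config`.
#' @export
seizure_sim_config <- function(
    years = c(2010, 2021),
    mode_probs = c(air = 0.30, land = 0.13, sea = 0.27, warehouse = 0.12,
                   unknown = 0.18),
    base_log10 = c(air = 2.5, land = 2.7, sea = 3.0, warehouse = 3.4,
                   unknown = 2.7),
    trend_log10 = c(air = -0.06, land = -0.10, sea = 0.15, warehouse = 0.02,
                    unknown = 0.00),
    sd_log10 = 0.5,
    route_len_probs = c(0.15, 0.45, 0.30, 0.10),
    origin_pool = c("NGA", "CMR", "COD", "GAB", "NER", "CAF", "COG", "CIV"),
    transit_pool = c("NGA", "GHA", "KEN", "TUR", "FRA", "NLD", "MYS", "THA"),
    import_pool = c("CHN", "VNM", "HKG", "LAO", "KHM", "SGP"),
    p_no_mass = 0.04) {
  cfg <- list(years = years, mode_probs = mode_probs,
              base_log10 = base_log10, trend_log10 = trend_log10,
              sd_log10 = sd_log10, route_len_probs = route_len_probs,
              origin_pool = origin_pool, transit_pool = transit_pool,
              import_pool = import_pool, p_no_mass = p_no_mass)
  class(cfg) <- "seizure_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname seizure_sim_config
#' @param cfg a config object.
#' @export
validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$mode_probs) - 1) > 1e-8)
    stop("mode probabilities must sum to 1", call. = FALSE)
  if (any(cfg$mode_probs < 0) || any(cfg$route_len_probs < 0))
    stop("probabilities must be non-negative", call. = FALSE)
  if (cfg$sd_log10 < 0) stop("sd must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' Simulate a seizure database
#'
#' Draws `n` seizure records: mode from `mode_probs`; mass lognormal on the
#' log10 scale with per-mode baseline and yearly trend; routes of 1-4
#' countries always involving Nigeria; warehouse records get
#' single-country Nigerian routes; a small fraction of records carry only
#' an item count (no mass), mirroring real reporting gaps. Deterministic
#' given `seed`.
#'
#' @param n number of records (default 80).
#' @param cfg a [seizure_sim_config()].
#' @param seed integer seed.
#' @param source_db source label stamped on the records.
#' @return seizure tibble passing [validate_seizures()].
#' @export
simulate_seizures <- function(n = 80, cfg = seizure_sim_config(), seed = 1,
                              source_db = "TRAFFIC") {
  validate_sim_config(cfg)
  set.seed(seed)
  y0 <- cfg$years[1]
  year <- sample(cfg$years[1]:cfg$years[2], n, replace = TRUE)
  month <- ifelse(year == 2021, sample(1:9, n, replace = TRUE),
                  sample(1:12, n, replace = TRUE))
  day <- sample(1:28, n, replace = TRUE)
  mode <- sample(names(cfg$mode_probs), n, replace = TRUE,
                 prob = cfg$mode_probs)
  mu <- cfg$base_log10[mode] + cfg$trend_log10[mode] * (year - y0)
  mass <- round(10^rnorm(n, mean = mu, sd = cfg$sd_log10), 3)
  no_mass <- runif(n) < cfg$p_no_mass

  route <- vector("list", n)
  for (i in seq_len(n)) {
    if (mode[i] == "warehouse") { route[[i]] <- "NGA"; next }
    len <- sample(1:4, 1, prob = cfg$route_len_probs)
    if (len == 1) { route[[i]] <- "NGA"; next }
    org <- sample(cfg$origin_pool, 1)
    imp <- sample(cfg$import_pool, 1)
    mid <- if (len > 2)
      sample(setdiff(cfg$transit_pool, c(org, imp)), len - 2) else character(0)
    r <- c(org, mid, imp)
    if (!"NGA" %in% r) r[min(2, length(r))] <- "NGA"
    route[[i]] <- unique(r)
  }
  seizure_country <- vapply(route, function(r) r[length(r)], character(1))
  det <- sample(c("intelligence", "routine_inspection", "scanner",
                  "sniffer_dogs", "unknown"), n, replace = TRUE,
                prob = c(0.2, 0.25, 0.06, 0.02, 0.47))
  det[mode == "warehouse"] <- "intelligence"

  rec <- tibble::tibble(
    record_id = sprintf("SIM-%04d", seq_len(n)),
    date = as.Date(sprintf("%d-%02d-%02d", year, month, day)),
    year = as.integer(year), month = as.integer(month),
    date_precision = "day",
    mass_scales_kg = ifelse(no_mass, NA_real_, mass),
    mass_meat_kg = NA_real_, mass_claws_kg = NA_real_,
    mass_other_kg = NA_real_,
    mass_total_kg = ifelse(no_mass, NA_real_, mass),
    mass_known = !no_mass,
    item_count = as.integer(ifelse(no_mass, sample(5:40, n, replace = TRUE),
                                   NA_integer_)),
    route = route, seizure_country = seizure_country, mode = mode,
    detection_method = det,
    suspects_arrested = as.integer(sample(c(NA, 0:4), n, replace = TRUE)),
    prosecuted = NA_integer_,
    source_db = source_db, co_seized = NA_character_)
  validate_seizures(rec)
  rec
}

#' Configuration for the sack-sample simulator
#'
#' Defaults emulate the sampled warehouse stock: 67 sacks with total masses
#' uniform on 6-104 kg, single-species white-bellied sacks with probability
#' 43/67 and black-bellied-only with probability 3/67; the remaining sacks
#' are mixed, with compositions drawn from a Dirichlet distribution whose
#' mean solves for an overall mean composition of (0.67, 0.11, 0.21, 0.01)
#' across white-bellied, black-bellied, Smutsia spp. and unidentified.
#'
#' @param n_sacks number of sacks (default 67).
#' @param mass_range sack-mass range in kg.
#' @param p_single_wb,p_single_bb probabilities of single-species sacks.
#' @param mixed_alpha Dirichlet concentration parameters of mixed-sack
#'   compositions, in group order (white-bellied, black-bellied, Smutsia,
#'   unidentified); low total concentration gives few-species-dominant
#'   sacks.
#' @param sampled_frac_range range of the fraction of each sack that is
#'   scooped and sorted (ten handfuls of a 6-104 kg sack).
#' @return list of class `sack_sim_config`.
#' @export
sack_sim_config <- function(
    n_sacks = 67,
    mass_range = c(6, 104),
    p_single_wb = 43 / 67,
    p_single_bb = 3 / 67,
    mixed_alpha = 2 * c(0.090, 0.208, 0.670, 0.032),
    sampled_frac_range = c(0.04, 0.12)) {
  cfg <- list(n_sacks = n_sacks, mass_range = mass_range,
              p_single_wb = p_single_wb, p_single_bb = p_single_bb,
              mixed_alpha = mixed_alpha,
              sampled_frac_range = sampled_frac_range)
  class(cfg) <- "sack_sim_config"
  if (n_sacks < 1) stop("need at least one sack", call. = FALSE)
  if (any(mass_range <= 0) || diff(mass_range) < 0)
    stop("invalid mass range", call. = FALSE)
  if (p_single_wb < 0 || p_single_bb < 0 || p_single_wb + p_single_bb > 1)
    stop("invalid single-species probabilities", call. = FALSE)
  if (any(mixed_alpha <= 0)) stop("Dirichlet parameters must be positive",
                                  call. = FALSE)
  cfg
}

# Dirichlet sampling via normalised gammas
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Expected mean composition of a sack-simulator configuration
#'
#' Analytic mean of the per-sack p_rm vector under the mixture of
#' single-species and Dirichlet-mixed sacks; used for parameter-recovery
#' and coverage checks.
#'
#' @param cfg a [sack_sim_config()].
#' @return named numeric vector over the four groups, summing to 1.
#' @export
sack_sim_mean <- function(cfg) {
  p_mix <- 1 - cfg$p_single_wb - cfg$p_single_bb
  dir_mean <- cfg$mixed_alpha / sum(cfg$mixed_alpha)
  out <- p_mix * dir_mean
  out[1] <- out[1] + cfg$p_single_wb
  out[2] <- out[2] + cfg$p_single_bb
  setNames(out, .sack_groups)
}

#' Simulate sampled scale sacks
#'
#' @param cfg a [sack_sim_config()].
#' @param seed integer seed.
#' @return sack tibble passing [validate_sacks()].
#' @export
simulate_sacks <- function(cfg = sack_sim_config(), seed = 1) {
  set.seed(seed)
  n <- cfg$n_sacks
  total <- runif(n, cfg$mass_range[1], cfg$mass_range[2])
  u <- runif(n)
  kind <- ifelse(u < cfg$p_single_wb, "wb",
                 ifelse(u < cfg$p_single_wb + cfg$p_single_bb, "bb", "mixed"))
  comp <- matrix(0, n, 4)
  comp[kind == "wb", 1] <- 1
  comp[kind == "bb", 2] <- 1
  n_mix <- sum(kind == "mixed")
  if (n_mix > 0)
    comp[kind == "mixed", ] <- .rdirichlet(n_mix, cfg$mixed_alpha)
  sampled <- total * runif(n, cfg$sampled_frac_range[1],
                           cfg$sampled_frac_range[2])
  sorted <- round(comp * sampled, 4)
  out <- tibble::tibble(sack_id = sprintf("SACK-%03d", seq_len(n)),
                        total_mass_kg = round(total, 2),
                        white_bellied = sorted[, 1],
                        black_bellied = sorted[, 2],
                        smutsia = sorted[, 3],
                        unidentified = sorted[, 4])
  # rounding of tiny components can zero a sack only if sampled mass ~ 0;
  # the config's positive ranges prevent that
  validate_sacks(out)
  out
}

#' Inject near-duplicate records for deduplication testing
#'
#' Copies `n_dupes` randomly chosen records under an alternate source
#' label, jittering dates and masses within (by default) the
#' deduplication tolerances, and returns the ground-truth merge map.
#'
#' @param records seizure tibble.
#' @param n_dupes number of duplicates to inject.
#' @param date_jitter maximum absolute date shift in days.
#' @param mass_jitter maximum relative mass perturbation.
#' @param source_db label stamped on the injected copies.
#' @param seed integer seed.
#' @return list with `records` (original plus injected, shuffled) and
#'   `truth` (tibble `dup_id`, `original_id`).
#' @export
inject_duplicates <- function(records, n_dupes, date_jitter = 3,
                              mass_jitter = 0.05, source_db = "WCS",
                              seed = 1) {
  set.seed(seed)
  pick <- sample(nrow(records), n_dupes, replace = TRUE)
  dup <- records[pick, ]
  shift <- sample(-date_jitter:date_jitter, n_dupes, replace = TRUE)
  dup$date <- dup$date + shift
  dup$year <- as.integer(format(dup$date, "%Y"))
  dup$month <- as.integer(format(dup$date, "%m"))
  fac <- 1 + runif(n_dupes, -mass_jitter, mass_jitter)
  for (cl in c("mass_scales_kg", "mass_meat_kg", "mass_claws_kg",
               "mass_other_kg", "mass_total_kg"))
    dup[[cl]] <- round(dup[[cl]] * fac, 3)
  dup$record_id <- sprintf("DUP-%04d", seq_len(n_dupes))
  dup$source_db <- source_db
  out <- dplyr::bind_rows(records, dup)
  out <- out[sample(nrow(out)), ]
  list(records = out,
       truth = tibble::tibble(dup_id = dup$record_id,
                              original_id = records$record_id[pick]))
}
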