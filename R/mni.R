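# Minimum-number-of-individuals (MNI) estimation from sampled scale sacks.
#
# The estimator has three stages:
#   1. per-sack relative proportional mass p_rm of each species group
#      (white-bellied, black-bellied, Smutsia spp., unidentified);
#   2. BCa bootstrap over sacks of the mean p_rm per group, giving a mean
#      and 95% CI of the composition of the trafficked scale stream;
#   3. conversion to individuals: p_rm x m_cs / CF, where m_cs is the total
#      confiscated scale mass across curated seizures and CF the mean dried
#      scale-plus-claw mass per individual of the group.
# Conversion-factor uncertainty is not propagated: the CI bounds of p_rm are
# pushed through the deterministic equation.

.sack_groups <- c("white_bellied", "black_bellied", "smutsia", "unidentified")

#' Read sack samples from CSV
#'
#' Expected columns: `sack_id`, `total_mass_kg` (mass of the whole sack),
#' `wb_kg`, `bb_kg`, `smutsia_kg`, `unid_kg` (sorted sub-sample masses for
#' white-bellied, black-bellied, Smutsia spp. and unidentified scales).
#'
#' @param path CSV path.
#' @return tibble with columns `sack_id`, `total_mass_kg`, `white_bellied`,
#'   `black_bellied`, `smutsia`, `unidentified` (kg).
#' @export
read_sacks <- function(path) {
  stopifnot(file.exists(path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sack_id", "total_mass_kg", "wb_kg", "bb_kg", "smutsia_kg",
            "unid_kg")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("sack CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- tibble::tibble(sack_id = as.character(raw$sack_id),
                        total_mass_kg = as.numeric(raw$total_mass_kg),
                        white_bellied = as.numeric(raw$wb_kg),
                        black_bellied = as.numeric(raw$bb_kg),
                        smutsia = as.numeric(raw$smutsia_kg),
                        unidentified = as.numeric(raw$unid_kg))
  validate_sacks(out)
}

#' Validate sack-sample invariants
#'
#' All masses non-negative and the sorted sub-sample cannot exceed the sack
#' total (within `tol` kg, allowing for weighing error).
#'
#' @param sacks sack tibble.
#' @param tol tolerance in kg on the sorted-vs-total comparison.
#' @return `sacks`, invisibly, if valid.
#' @export
validate_sacks <- function(sacks, tol = 1e-6) {
  m <- as.matrix(sacks[.sack_groups])
  if (any(m < 0, na.rm = TRUE)) stop("negative sorted mass", call. = FALSE)
  if (any(sacks$total_mass_kg < 0)) stop("negative sack mass", call. = FALSE)
  if (any(rowSums(m) > sacks$total_mass_kg + tol))
    stop("sorted mass exceeds sack mass", call. = FALSE)
  invisible(sacks)
}

#' Read conversion factors from CSV
#'
#' Expected columns: `group`, `cf_kg` (mean dried scale-plus-claw mass per
#' individual, kg), `n` (number of individuals the mean is based on).
#'
#' @param path CSV path.
#' @return tibble with columns `group`, `cf_kg`, `n`.
#' @export
read_conversion_factors <- function(path) {
  stopifnot(file.exists(path))
  raw <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  out <- tibble::tibble(group = as.character(raw$group),
                        cf_kg = as.numeric(raw$cf_kg),
                        n = suppressWarnings(as.integer(raw$n)))
  if (any(out$cf_kg <= 0)) stop("conversion factors must be positive",
                                call. = FALSE)
  out
}

#' Conversion factor for the aggregated Smutsia group
#'
#' Giant ground and Temminck's pangolin scales cannot be told apart
#' reliably, so their masses are pooled and the group uses the arithmetic
#' mean of the two species' conversion factors.
#'
#' @param giant_cf,temminck_cf conversion factors (kg/individual).
#' @return the mean, a single positive number.
#' @export
smutsia_cf <- function(giant_cf, temminck_cf) {
  stopifnot(giant_cf > 0, temminck_cf > 0)
  (giant_cf + temminck_cf) / 2
}

#' Per-sack relative proportional mass
#'
#' For every sack, divides each group's sorted mass by the sack's total
#' sorted mass (identified plus unidentified), so the four fractions sum
#' to 1 within each sack.
#'
#' @param sacks sack tibble (see [read_sacks()]).
#' @return tibble with columns `sack_id` and one `p_rm` column per group
#'   (`white_bellied`, `black_bellied`, `smutsia`, `unidentified`).
#' @export
relative_proportional_mass <- function(sacks) {
  m <- as.matrix(sacks[.sack_groups])
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("sack(s) with zero sorted mass: ",
         paste(sacks$sack_id[tot <= 0], collapse = ", "), call. = FALSE)
  prm <- m / tot
  out <- tibble::as_tibble(prm)
  out <- dplyr::bind_cols(tibble::tibble(sack_id = sacks$sack_id), out)
  out
}

#' Pooled scale composition across sacks
#'
#' Mass-weighted composition: each group's total sorted mass divided by a
#' denominator that defaults to the sum of all sorted masses but can be set
#' to an externally reported identified total. When the internal sum and an
#' explicit `total` disagree by more than `tol` kg the result carries a
#' `discrepancy_kg` attribute and a warning is raised, so inconsistent
#' source totals are surfaced rather than hidden.
#'
#' @param masses named numeric vector of pooled sorted masses (kg) or a sack
#'   tibble (columns are summed).
#' @param total denominator in kg; default `sum(masses)`.
#' @param tol discrepancy tolerance in kg (default 0.5).
#' @return named numeric vector of percentages.
#' @export
pooled_composition <- function(masses, total = NULL, tol = 0.5) {
  if (is.data.frame(masses))
    masses <- colSums(as.matrix(masses[.sack_groups]))
  internal <- sum(masses)
  if (is.null(total)) total <- internal
  pct <- 100 * masses / total
  if (abs(internal - total) > tol) {
    warning(sprintf(
      "sum of sorted masses (%.2f kg) differs from stated total (%.2f kg)",
      internal, total), call. = FALSE)
    attr(pct, "discrepancy_kg") <- internal - total
  }
  pct
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Nonparametric bootstrap of `stat` with the adjusted bootstrap percentile
#' interval, implemented from first principles:
#' \itemize{
#'   \item bias correction \eqn{z_0 = \Phi^{-1}(\#\{\hat\theta^* <
#'     \hat\theta\}/B)} (ties with the observed statistic count half);
#'   \item acceleration \eqn{a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})} from
#'     jackknife deviations \eqn{d_i = \bar\theta_{(\cdot)} -
#'     \hat\theta_{(i)}};
#'   \item interval endpoints at the adjusted levels
#'     \eqn{\alpha_k = \Phi(z_0 + (z_0 + z^{(k)})/(1 - a(z_0 + z^{(k)})))},
#'     read off the bootstrap distribution with type-7 quantile
#'     interpolation.
#' }
#' Resampling draws `n_boot` index vectors with [sample.int()] after
#' `set.seed(seed)`, so results are fully reproducible.
#'
#' @param values numeric vector (at least 2 values).
#' @param n_boot number of bootstrap replicates (default 1000; at least
#'   200).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param stat statistic, a function of a numeric vector (default `mean`).
#' @param conf confidence level (default 0.95).
#' @return list with `mean` (the observed statistic), `ci_low`, `ci_high`,
#'   `n_boot`, `z0`, `accel`. Constant input yields the degenerate interval
#'   `[c, c]` with a warning rather than an error.
#' @examples
#' bca_bootstrap(c(0.6, 0.7, 0.65, 0.8, 0.55), n_boot = 1000, seed = 1)
#' @export
bca_bootstrap <- function(values, n_boot = 1000, seed = NULL, stat = mean,
                          conf = 0.95) {
  n <- length(values)
  stopifnot(n >= 2, n_boot >= 200)
  t0 <- stat(values)
  if (isTRUE(all(values == values[1]))) {
    warning("constant input: degenerate interval", call. = FALSE)
    return(list(mean = t0, ci_low = t0, ci_high = t0, n_boot = n_boot,
                z0 = 0, accel = 0))
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  theta_star <- if (identical(stat, mean)) .colMeans(values[idx], n, n_boot)
    else apply(idx, 2, function(j) stat(values[j]))

  below <- (sum(theta_star < t0) + 0.5 * sum(theta_star == t0)) / n_boot
  if (below <= 0 || below >= 1) {
    warning("observed statistic outside bootstrap distribution; ",
            "falling back to percentile interval", call. = FALSE)
    q <- quantile(theta_star, c((1 - conf) / 2, (1 + conf) / 2), names = FALSE,
                  type = 7)
    return(list(mean = t0, ci_low = q[1], ci_high = q[2], n_boot = n_boot,
                z0 = NA_real_, accel = NA_real_))
  }
  z0 <- qnorm(below)

  jk <- vapply(seq_len(n), function(i) stat(values[-i]), numeric(1))
  d <- mean(jk) - jk
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)

  alpha <- c((1 - conf) / 2, (1 + conf) / 2)
  zq <- qnorm(alpha)
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  q <- quantile(theta_star, adj, names = FALSE, type = 7)
  list(mean = t0, ci_low = q[1], ci_high = q[2], n_boot = n_boot,
       z0 = z0, accel = a)
}

# deterministic per-group seeds below 2^31, derived from a master seed
.group_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}

#' Bootstrap the mean relative proportional mass per group
#'
#' Applies [bca_bootstrap()] to the per-sack p_rm values of each species
#' group. By default each group is resampled independently over sacks
#' (matching per-group bootstrap reporting); `joint = TRUE` instead
#' resamples sacks once per replicate and evaluates all groups on the same
#' resample, as a sensitivity analysis.
#'
#' @param sacks sack tibble.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed master integer seed; per-group seeds are derived from it.
#' @param joint resample sacks jointly across groups (default `FALSE`).
#' @param conf confidence level.
#' @return tibble of class `prm_estimate` with columns `group`, `mean`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_sacks`; per-sack values in the
#'   `"prm_values"` attribute.
#' @export
bootstrap_prm <- function(sacks, n_boot = 1000, seed = NULL, joint = FALSE,
                          conf = 0.95) {
  prm <- relative_proportional_mass(sacks)
  groups <- .sack_groups
  if (joint) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(prm)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    res <- lapply(groups, function(g) {
      v <- prm[[g]]
      theta_star <- .colMeans(v[idx], n, n_boot)
      # BCa corrections still per group, on the shared resamples
      t0 <- mean(v)
      below <- (sum(theta_star < t0) + 0.5 * sum(theta_star == t0)) / n_boot
      below <- min(max(below, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
      z0 <- qnorm(below)
      jk <- vapply(seq_len(n), function(i) mean(v[-i]), numeric(1))
      d <- mean(jk) - jk
      denom <- sum(d^2)^1.5
      a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
      zq <- qnorm(c((1 - conf) / 2, (1 + conf) / 2))
      adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
      q <- quantile(theta_star, adj, names = FALSE, type = 7)
      list(mean = t0, ci_low = q[1], ci_high = q[2])
    })
  } else {
    res <- lapply(seq_along(groups), function(k) {
      v <- prm[[groups[k]]]
      if (all(v == v[1]))
        suppressWarnings(bca_bootstrap(v, n_boot, .group_seed(seed, k)))
      else bca_bootstrap(v, n_boot, .group_seed(seed, k))
    })
  }
  out <- tibble::tibble(
    group = groups,
    mean = vapply(res, `[[`, numeric(1), "mean"),
    ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(res, `[[`, numeric(1), "ci_high"),
    n_boot = n_boot, n_sacks = nrow(prm))
  attr(out, "prm_values") <- prm
  class(out) <- c("prm_estimate", class(out))
  out
}

#' Convert composition estimates to seizure-level masses
#'
#' Multiplies the bootstrap mean and CI bounds of p_rm by the total
#' confiscated scale mass m_cs; exactly linear in m_cs.
#'
#' @param prm `prm_estimate` tibble from [bootstrap_prm()], or any tibble
#'   with `group`, `mean`, `ci_low`, `ci_high` columns on the fraction
#'   scale.
#' @param m_cs total confiscated scale mass in kg (must be positive).
#' @return tibble with `group`, `est_mass_kg`, `mass_ci_low_kg`,
#'   `mass_ci_high_kg`.
#' @export
estimate_group_mass <- function(prm, m_cs) {
  if (!is.numeric(m_cs) || length(m_cs) != 1 || m_cs <= 0)
    stop("m_cs must be a single positive mass in kg", call. = FALSE)
  tibble::tibble(group = prm$group,
                 est_mass_kg = prm$mean * m_cs,
                 mass_ci_low_kg = prm$ci_low * m_cs,
                 mass_ci_high_kg = prm$ci_high * m_cs)
}

#' Convert group masses to minimum numbers of individuals
#'
#' Divides each mass bound by the group's mass-to-individual conversion
#' factor. Groups without a conversion factor (unidentified scales) get
#' `NA` MNIs but keep their mass row.
#'
#' @param group_mass tibble from [estimate_group_mass()].
#' @param cf conversion-factor tibble (see [read_conversion_factors()]).
#' @return tibble with the mass columns plus `cf_kg`, `mni`, `mni_ci_low`,
#'   `mni_ci_high` (real-valued; round only for display).
#' @export
estimate_mni <- function(group_mass, cf) {
  if (any(cf$cf_kg <= 0)) stop("conversion factors must be positive",
                               call. = FALSE)
  out <- dplyr::left_join(group_mass, cf[c("group", "cf_kg")], by = "group")
  out$mni <- out$est_mass_kg / out$cf_kg
  out$mni_ci_low <- out$mass_ci_low_kg / out$cf_kg
  out$mni_ci_high <- out$mass_ci_high_kg / out$cf_kg
  out
}

#' Aggregate per-group MNI estimates
#'
#' Sums the group means and each CI bound (groups are converted from the
#' same multiplicative equation, so bounds add), and expresses each group's
#' point MNI as a percentage of the total.
#'
#' @param mni tibble from [estimate_mni()] (or any tibble with `mni`,
#'   `mni_ci_low`, `mni_ci_high` columns; `NA` rows are dropped from the
#'   totals).
#' @return object of class `mni_table`: the input with a `pct_of_mni`
#'   column and a `Total` row appended.
#' @export
aggregate_mni <- function(mni) {
  est <- mni[!is.na(mni$mni), ]
  tot <- sum(est$mni)
  mni$pct_of_mni <- ifelse(is.na(mni$mni), NA_real_, 100 * mni$mni / tot)
  total_row <- tibble::tibble(group = "Total")
  for (cl in c("est_mass_kg", "mass_ci_low_kg", "mass_ci_high_kg"))
    if (cl %in% names(mni)) total_row[[cl]] <- sum(est[[cl]], na.rm = TRUE)
  total_row$mni <- tot
  total_row$mni_ci_low <- sum(est$mni_ci_low)
  total_row$mni_ci_high <- sum(est$mni_ci_high)
  total_row$pct_of_mni <- 100
  out <- dplyr::bind_rows(mni, total_row)
  class(out) <- c("mni_table", class(out))
  out
}

#' @export
print.mni_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 1))
  for (cl in c("mni", "mni_ci_low", "mni_ci_high"))
    if (cl %in% names(df)) df[[cl]] <- round(df[[cl]])
  print(df, row.names = FALSE)
  invisible(x)
}

#' End-to-end MNI report from sack samples
#'
#' Runs the full estimator: per-sack p_rm, BCa bootstrap per group,
#' conversion through m_cs and the conversion factors, and aggregation to
#' a table mirroring the standard report layout (sorted mass, estimated
#' mass in seizures with CI, MNI with CI, percent of total MNI).
#'
#' @param sacks sack tibble (see [read_sacks()]).
#' @param cf conversion-factor tibble.
#' @param m_cs total confiscated scale mass in kg.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed master seed.
#' @param joint joint resampling across groups (default `FALSE`).
#' @return `mni_table` with one row per group plus a total row; the
#'   `prm_estimate` is attached as attribute `"prm"`.
#' @export
mni_report <- function(sacks, cf, m_cs, n_boot = 1000, seed = NULL,
                       joint = FALSE) {
  prm <- bootstrap_prm(sacks, n_boot = n_boot, seed = seed, joint = joint)
  gm <- estimate_group_mass(prm, m_cs)
  mni <- estimate_mni(gm, cf)
  sorted <- colSums(as.matrix(sacks[.sack_groups]))
  mni <- dplyr::bind_cols(
    tibble::tibble(sorted_mass_kg = as.numeric(sorted[mni$group])),
    mni)[, c("group", "sorted_mass_kg", "est_mass_kg", "mass_ci_low_kg",
             "mass_ci_high_kg", "cf_kg", "mni", "mni_ci_low", "mni_ci_high")]
  out <- aggregate_mni(mni)
  out$sorted_mass_kg[out$group == "Total"] <- sum(sorted)
  attr(out, "prm") <- prm
  out
}
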