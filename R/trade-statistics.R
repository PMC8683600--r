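# Shipment-mass statistics across transport modes and years.
#
# Two questions are addressed: (i) does per-seizure mass differ between air,
# land and sea shipments (rank-based tests, since masses are heavily skewed),
# and (ii) how has mass changed over the years within each mode (OLS on
# log10 mass with AIC model selection).

#' Kruskal-Wallis test of seizure mass across transport modes
#'
#' Rank-based k-sample test with tie correction (delegated to
#' [stats::kruskal.test()]), plus Dunn's pairwise post-hoc comparisons.
#' Being rank-based, the statistic is invariant under monotone
#' transformations of mass.
#'
#' @param masses numeric vector of seizure masses (kg).
#' @param groups factor or character vector of the same length (e.g.
#'   transport mode).
#' @param adjust p-value adjustment for the pairwise comparisons; `"none"`
#'   (default) reports unadjusted two-sided p-values, or any method of
#'   [stats::p.adjust()].
#' @return object of class `rank_test`: list with `H`, `df`, `n`, `p_value`
#'   and a `pairwise` tibble (`group_a`, `group_b`, `z`, `p`).
#' @examples
#' mass_rank_test(c(1, 2, 3, 4, 5, 6), rep(c("air", "sea"), each = 3))
#' @export
mass_rank_test <- function(masses, groups, adjust = "none") {
  keep <- !is.na(masses) & !is.na(groups)
  masses <- masses[keep]
  groups <- as.character(groups)[keep]
  if (length(unique(groups)) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  if (all(masses == masses[1])) {
    # all observations tied: no rank variation at all, H is 0 by definition
    # (kruskal.test's tie correction degenerates to 0/0 here)
    out <- list(H = 0, df = length(unique(groups)) - 1L, n = length(masses),
                p_value = 1,
                pairwise = dunn_posthoc(masses, groups, adjust = adjust))
    class(out) <- "rank_test"
    return(out)
  }
  kw <- kruskal.test(masses, factor(groups))
  out <- list(H = unname(kw$statistic), df = unname(kw$parameter),
              n = length(masses), p_value = kw$p.value,
              pairwise = dunn_posthoc(masses, groups, adjust = adjust))
  class(out) <- "rank_test"
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, n = %d, p = %.3g\n",
              x$H, x$df, x$n, x$p_value))
  cat("Dunn post-hoc comparisons:\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' For each pair of groups computes the standardised difference in mean
#' midranks, with the tie-corrected pooled variance
#' \eqn{(N(N+1)/12 - T)(1/n_i + 1/n_j)} where
#' \eqn{T = \sum(t^3 - t) / (12(N-1))} sums over tied values, and a
#' two-sided normal p-value.
#'
#' @inheritParams mass_rank_test
#' @return tibble with columns `group_a`, `group_b`, `z`, `p`.
#' @export
dunn_posthoc <- function(masses, groups, adjust = "none") {
  keep <- !is.na(masses) & !is.na(groups)
  masses <- masses[keep]
  groups <- as.character(groups)[keep]
  lv <- sort(unique(groups))
  if (length(lv) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  N <- length(masses)
  r <- rank(masses)
  tie_tab <- table(masses)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(p) {
    a <- p[1]; b <- p[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    c(z = z)
  })
  z <- as.numeric(res)
  p <- 2 * pnorm(-abs(z))
  p <- stats::p.adjust(p, method = adjust)
  tibble::tibble(group_a = pairs[1, ], group_b = pairs[2, ], z = z, p = p)
}

#' Fit the log10-mass year-by-mode regression
#'
#' Ordinary least squares on log10-transformed seizure mass (the log
#' transform meets the residual-normality assumption for the heavily skewed
#' masses), with year as a continuous predictor and transport mode as a
#' categorical predictor (baseline level `air`, alphabetically first).
#' Warehouse and unknown-mode records and records without mass are excluded;
#' the analysis is restricted to complete calendar years.
#'
#' @param records curated seizure tibble.
#' @param formula model formula on the internal variables `log10_mass`,
#'   `year` and `mode` (default `log10_mass ~ year * mode`).
#' @param years range of complete years to keep (default `2010:2020`).
#' @return object of class `mass_model`: list with `fit` (the `lm` object),
#'   `coefficients` (tibble: term, estimate, se, p), `r_squared`, `f_stat`
#'   (value, df1, df2), `aic`, `n`.
#' @export
fit_mass_model <- function(records, formula = log10_mass ~ year * mode,
                           years = 2010:2020) {
  dat <- records[records$mass_known &
                   records$mode %in% c("air", "land", "sea") &
                   records$year %in% years, ]
  dat <- data.frame(log10_mass = log10(dat$mass_total_kg),
                    year = dat$year, mode = factor(dat$mode))
  fit <- lm(formula, data = dat)
  if (fit$rank < length(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  r2 <- sm$r.squared
  # constant response: no variance to explain (summary.lm's 0/0 is noise)
  if (!is.finite(r2) || isTRUE(var(dat$log10_mass) == 0)) r2 <- 0
  out <- list(
    fit = fit,
    coefficients = tibble::tibble(term = rownames(co),
                                  estimate = co[, 1], se = co[, 2],
                                  p = co[, 4]),
    r_squared = r2,
    f_stat = if (is.null(sm$fstatistic)) c(value = NA, df1 = NA, df2 = NA) else
      c(value = unname(sm$fstatistic[1]), df1 = unname(sm$fstatistic[2]),
        df2 = unname(sm$fstatistic[3])),
    aic = AIC(fit), n = nrow(dat))
  class(out) <- "mass_model"
  out
}

#' @export
print.mass_model <- function(x, ...) {
  cat(sprintf("log10-mass model: n = %d, R^2 = %.3f, AIC = %.2f\n",
              x$n, x$r_squared, x$aic))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' Back-transform model predictions to the kg scale
#'
#' @param model a `mass_model`.
#' @param newdata data frame with `year` and `mode` columns.
#' @return predicted masses in kg (`10^fitted`).
#' @export
predict_mass <- function(model, newdata) {
  10^predict(model$fit, newdata = newdata)
}

#' Compare candidate mass models by information criterion
#'
#' Fits each candidate formula on the same records and ranks them by AIC
#' (or the small-sample AICc). Ties within `tol` are broken in favour of the
#' model with fewer parameters.
#'
#' @param records curated seizure tibble.
#' @param formulas named list of model formulas (see [fit_mass_model()]).
#' @param criterion `"AIC"` (default) or `"AICc"`.
#' @param years complete years to keep.
#' @param tol tie tolerance on the criterion (default 1e-8).
#' @return tibble ranked best-first with columns `model`, `k` (number of
#'   parameters), `aic` (the chosen criterion) and `delta`.
#' @export
compare_mass_models <- function(records,
                                formulas = list(
                                  year = log10_mass ~ year,
                                  mode = log10_mass ~ mode,
                                  additive = log10_mass ~ year + mode,
                                  interaction = log10_mass ~ year * mode),
                                criterion = c("AIC", "AICc"),
                                years = 2010:2020, tol = 1e-8) {
  criterion <- match.arg(criterion)
  fits <- lapply(formulas, function(f)
    fit_mass_model(records, formula = f, years = years))
  k <- vapply(fits, function(f) length(coef(f$fit)) + 1, numeric(1))
  ic <- vapply(fits, `[[`, numeric(1), "aic")
  if (criterion == "AICc") {
    n <- vapply(fits, `[[`, numeric(1), "n")
    ic <- ic + 2 * k * (k + 1) / (n - k - 1)
  }
  ord <- order(round(ic / tol) * tol, k)
  tibble::tibble(model = names(formulas)[ord], k = unname(k[ord]),
                 aic = unname(ic[ord]), delta = unname(ic[ord] - min(ic)))
}

#' Summary quantities of a curated seizure database
#'
#' Recomputes, from any curated seizure table, the headline quantities used
#' to check a database against its published description: number of records,
#' number and total mass of seizures with mass data, scale-only mass, and
#' the Kruskal-Wallis mass-by-mode test over air/land/sea records.
#'
#' @param records curated seizure tibble (or path to a CSV readable by
#'   [read_seizures()]).
#' @return list with `n_records`, `n_with_mass`, `total_mass_kg`,
#'   `scales_mass_kg`, and `mode_test` (a `rank_test`, or `NULL` if fewer
#'   than two transport modes have data).
#' @export
verify_seizure_database <- function(records) {
  if (is.character(records)) records <- read_seizures(records)
  withmass <- records[records$mass_known, ]
  modal <- withmass[withmass$mode %in% c("air", "land", "sea"), ]
  mt <- if (length(unique(modal$mode)) >= 2)
    mass_rank_test(modal$mass_total_kg, modal$mode) else NULL
  list(n_records = nrow(records),
       n_with_mass = nrow(withmass),
       total_mass_kg = sum(withmass$mass_total_kg),
       scales_mass_kg = sum(withmass$mass_scales_kg, na.rm = TRUE),
       mode_test = mt)
}
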