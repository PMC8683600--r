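test_that("Kruskal-Wallis H matches the rank-sum oracle", {
  set.seed(42)
  cases <- list(
    list(x = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b", "c"), each = 2)),
    list(x = c(10, 12, 12, 15, 8, 8, 30, 2), g = rep(c("a", "b"), each = 4)),
    list(x = rlnorm(30, 5, 1), g = sample(c("air", "land", "sea"), 30,
                                          replace = TRUE)))
  for (cs in cases) {
    rt <- mass_rank_test(cs$x, cs$g)
    expect_equal(rt$H, oracle_kw(cs$x, cs$g), tolerance = 1e-12)
    expect_equal(rt$df, length(unique(cs$g)) - 1)
    expect_equal(rt$n, length(cs$x))
  }
})

test_that("H is invariant under monotone transformations of mass", {
  set.seed(7)
  x <- rlnorm(40, 4, 1.5)
  g <- sample(c("air", "land", "sea"), 40, replace = TRUE)
  h0 <- mass_rank_test(x, g)$H
  expect_equal(mass_rank_test(log10(x), g)$H, h0)
  expect_equal(mass_rank_test(sqrt(x), g)$H, h0)
})

test_that("degenerate designs are handled: all-tied data and single group", {
  rt <- mass_rank_test(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(rt$H, 0)
  expect_equal(rt$p_value, 1)
  expect_true(all(rt$pairwise$z == 0) && all(rt$pairwise$p == 1))
  expect_error(mass_rank_test(1:5, rep("a", 5)), "two")
})

test_that("Dunn z matches the direct formula and identical groups give z=0", {
  set.seed(11)
  x <- c(rlnorm(8, 3), rlnorm(8, 4), rlnorm(8, 5))
  g <- rep(c("air", "land", "sea"), each = 8)
  pw <- dunn_posthoc(x, g)
  for (i in seq_len(nrow(pw)))
    expect_equal(pw$z[i], oracle_dunn_z(x, g, pw$group_a[i], pw$group_b[i]),
                 tolerance = 1e-12)
  expect_true(all(pw$p >= 0 & pw$p <= 1))
  # two copies of the same data: mean ranks coincide
  same <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
})

test_that("Holm adjustment is available behind a flag and only grows p", {
  set.seed(3)
  x <- rlnorm(30, 4, 1)
  g <- sample(c("a", "b", "c"), 30, replace = TRUE)
  raw <- dunn_posthoc(x, g, adjust = "none")
  adj <- dunn_posthoc(x, g, adjust = "holm")
  expect_true(all(adj$p >= raw$p))
})

fake_records <- function(year, mode, mass) {
  tibble::tibble(record_id = sprintf("R%03d", seq_along(year)),
                 date = as.Date(sprintf("%d-06-15", year)),
                 year = as.integer(year), month = 6L, date_precision = "day",
                 mass_scales_kg = mass, mass_meat_kg = NA_real_,
                 mass_claws_kg = NA_real_, mass_other_kg = NA_real_,
                 mass_total_kg = mass, mass_known = !is.na(mass),
                 item_count = NA_integer_,
                 route = replicate(length(year), c("NGA", "CHN"),
                                   simplify = FALSE),
                 seizure_country = "CHN", mode = mode,
                 detection_method = "unknown",
                 suspects_arrested = NA_integer_, prosecuted = NA_integer_,
                 source_db = "TRAFFIC", co_seized = NA_character_)
}

test_that("a noiseless linear trend is recovered to machine precision", {
  yr <- rep(2010:2020, each = 3)
  recs <- fake_records(yr, "air", 10^(2 + 0.1 * (yr - 2010)))
  fit <- fit_mass_model(recs, formula = log10_mass ~ year)
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(co["year"]), 0.1, tolerance = 1e-10)
  expect_equal(unname(co["(Intercept)"]), 2 - 0.1 * 2010, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("a constant response yields zero slopes and zero R-squared", {
  yr <- rep(2010:2020, each = 2)
  recs <- fake_records(yr, rep(c("air", "sea"), length(yr) / 2), rep(100, length(yr)))
  # summary.lm warns about the (intentionally) perfect degenerate fit
  fit <- suppressWarnings(fit_mass_model(recs))
  sl <- unname(fit$coefficients$estimate[fit$coefficients$term != "(Intercept)"])
  expect_equal(sl, rep(0, length(sl)), tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)
})

test_that("OLS solution equals the normal-equation oracle", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 40
    yr <- sample(2010:2020, n, replace = TRUE)
    md <- sample(c("air", "land", "sea"), n, replace = TRUE)
    mass <- 10^(rnorm(n, 2.5, 0.6))
    recs <- fake_records(yr, md, mass)
    fit <- fit_mass_model(recs, formula = log10_mass ~ year + mode)
    X <- cbind(1, yr, md == "land", md == "sea")
    beta <- oracle_ols(X, log10(mass))
    expect_equal(unname(fit$coefficients$estimate), as.numeric(beta),
                 tolerance = 1e-8)
  }
})

test_that("model filters respect years, modes and mass availability", {
  yr <- c(2009, 2015, 2021, 2015, 2015)
  recs <- fake_records(yr, c("air", "air", "air", "warehouse", "air"),
                       c(100, 200, 300, 400, NA))
  fit <- fit_mass_model(recs, formula = log10_mass ~ 1)
  expect_equal(fit$n, 1)  # only the 2015 air record with mass survives
})

test_that("AIC selection prefers true interaction structure and breaks ties by size", {
  set.seed(23)
  yr <- rep(2010:2020, each = 6)
  md <- rep(c("air", "land", "sea"), length(yr) / 3)
  mu <- 2.5 - 0.05 * (yr - 2010) + ifelse(md == "sea", 0.4 * (yr - 2010), 0)
  recs <- fake_records(yr, md, 10^(mu + rnorm(length(yr), 0, 0.3)))
  rk <- compare_mass_models(recs)
  expect_equal(rk$model[1], "interaction")
  expect_equal(rk$delta[1], 0)
  # identical candidate formulas: the tie is broken by parameter count
  rk2 <- compare_mass_models(
    recs, formulas = list(big = log10_mass ~ year + mode,
                          small = log10_mass ~ year + mode,
                          tiny = log10_mass ~ year))
  expect_true(rk2$aic[1] <= rk2$aic[2])
})

test_that("a useless extra parameter raises AIC by about two on null data", {
  set.seed(31)
  deltas <- replicate(300, {
    y <- rnorm(50)
    x <- rnorm(50)
    AIC(lm(y ~ x)) - AIC(lm(y ~ 1))
  })
  # E[delta] = 2 - E[chi2_1] ~ 1; most null fits should be penalised
  expect_gt(mean(deltas), 0.5)
  expect_lt(mean(deltas), 2.5)
  expect_gt(mean(deltas > 0), 0.7)
})

test_that("database verification recomputes headline totals from records", {
  recs <- simulate_seizures(80, seed = 301)
  v <- verify_seizure_database(recs)
  expect_equal(v$n_records, 80)
  expect_equal(v$n_with_mass, sum(recs$mass_known))
  expect_equal(v$total_mass_kg,
               sum(recs$mass_total_kg[recs$mass_known]))
  expect_s3_class(v$mode_test, "rank_test")
  expect_equal(v$mode_test$df, 2)
  expect_gte(v$mode_test$H, 0)
})
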