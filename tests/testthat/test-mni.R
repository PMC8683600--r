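toy_sacks <- function(wb, bb = 0, sm = 0, un = 0) {
  tibble::tibble(sack_id = sprintf("S%02d", seq_along(wb)),
                 total_mass_kg = rep(1000, length(wb)),
                 white_bellied = wb, black_bellied = bb,
                 smutsia = sm, unidentified = un)
}

test_that("per-sack relative proportional mass normalises over sorted mass", {
  one <- relative_proportional_mass(toy_sacks(10))
  expect_equal(one$white_bellied, 1)
  two <- relative_proportional_mass(toy_sacks(3, bb = 1))
  expect_equal(c(two$white_bellied, two$black_bellied), c(0.75, 0.25))
  set.seed(5)
  many <- relative_proportional_mass(simulate_sacks(seed = 5))
  expect_equal(rowSums(many[, -1]), rep(1, nrow(many)))
  expect_error(relative_proportional_mass(toy_sacks(0)), "zero sorted mass")
})

test_that("pooled composition supports an external identified total and flags gaps", {
  masses <- c(white_bellied = 207.86, black_bellied = 31.17,
              smutsia = 7.96, unidentified = 0.876)
  expect_warning(pct <- pooled_composition(masses, total = 291), "differs")
  expect_equal(unname(pct["white_bellied"]), 71.4, tolerance = 0.001)
  expect_equal(unname(pct["black_bellied"]), 10.7, tolerance = 0.005)
  expect_equal(attr(pct, "discrepancy_kg"), sum(masses) - 291,
               tolerance = 1e-9)
  # with the internal denominator the fractions close to 100%
  pct2 <- pooled_composition(masses)
  expect_equal(sum(pct2), 100, tolerance = 1e-9)
})

test_that("BCa matches the straight-line oracle to 1e-9 on fixed-seed samples", {
  set.seed(101)
  samples <- list(runif(10), rbeta(15, 2, 5), rlnorm(12, 0, 0.4),
                  c(0.1, 0.1, 0.2, 0.5, 0.9, 0.95, 0.4, 0.3))
  for (k in seq_along(samples)) {
    x <- samples[[k]]
    got <- bca_bootstrap(x, n_boot = 1000, seed = 400 + k)
    want <- oracle_bca_mean(x, n_boot = 1000, seed = 400 + k)
    expect_equal(c(got$ci_low, got$ci_high), want, tolerance = 1e-9)
    expect_equal(got$mean, mean(x))
    expect_lte(got$ci_low, got$mean)
    expect_gte(got$ci_high, got$mean)
  }
})

test_that("BCa agrees with the boot package on the same data", {
  set.seed(202)
  x <- rbeta(40, 3, 2)
  got <- bca_bootstrap(x, n_boot = 20000, seed = 7)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 20000)
  bc <- boot::boot.ci(b, type = "bca")$bca[4:5]
  # independent resampling streams: agreement up to Monte-Carlo error
  expect_equal(c(got$ci_low, got$ci_high), bc, tolerance = 0.01)
})

test_that("degenerate and symmetric inputs behave as limits", {
  expect_warning(deg <- bca_bootstrap(rep(0.5, 8), seed = 1), "constant")
  expect_equal(c(deg$mean, deg$ci_low, deg$ci_high), c(0.5, 0.5, 0.5))
  # symmetric data: z0 ~ 0, a ~ 0, BCa ~ plain percentile interval
  x <- seq(-1, 1, length.out = 41)
  got <- bca_bootstrap(x, n_boot = 5000, seed = 9)
  set.seed(9)
  idx <- matrix(sample.int(41, 41 * 5000, replace = TRUE), nrow = 41)
  perc <- quantile(colMeans(matrix(x[idx], nrow = 41)), c(0.025, 0.975),
                   names = FALSE)
  expect_lt(abs(got$z0), 0.05)
  expect_lt(abs(got$accel), 0.01)
  expect_lt(max(abs(c(got$ci_low, got$ci_high) - perc)), 0.01)
})

test_that("bootstrap is seed-deterministic with small Monte-Carlo drift", {
  set.seed(32)
  x <- rbeta(67, 4, 2)
  a <- bca_bootstrap(x, n_boot = 10000, seed = 33)
  b <- bca_bootstrap(x, n_boot = 10000, seed = 33)
  expect_identical(a, b)
  c <- bca_bootstrap(x, n_boot = 10000, seed = 34)
  expect_lt(abs(a$ci_low - c$ci_low), 0.02)
  expect_lt(abs(a$ci_high - c$ci_high), 0.02)
})

test_that("group-mass conversion is exactly linear in m_cs", {
  prm <- tibble::tibble(group = c("white_bellied", "black_bellied"),
                        mean = c(0.5, 0.25), ci_low = c(0.4, 0.2),
                        ci_high = c(0.6, 0.3))
  gm <- estimate_group_mass(prm, 100)
  expect_equal(gm$est_mass_kg, c(50, 25))
  gm3 <- estimate_group_mass(prm, 300)
  expect_equal(as.matrix(gm3[-1]), 3 * as.matrix(gm[-1]))
  expect_error(estimate_group_mass(prm, 0), "positive")
})

test_that("MNI is inverse in the conversion factor and zero mass gives zero", {
  gm <- tibble::tibble(group = "white_bellied", est_mass_kg = 5,
                       mass_ci_low_kg = 0, mass_ci_high_kg = 10)
  cf1 <- tibble::tibble(group = "white_bellied", cf_kg = 1, n = 7L)
  m1 <- estimate_mni(gm, cf1)
  expect_equal(c(m1$mni, m1$mni_ci_low, m1$mni_ci_high), c(5, 0, 10))
  cfk <- cf1; cfk$cf_kg <- 4
  mk <- estimate_mni(gm, cfk)
  expect_equal(mk$mni, m1$mni / 4)
  bad <- cf1; bad$cf_kg <- -1
  expect_error(estimate_mni(gm, bad), "positive")
})

test_that("the Smutsia factor is the mean of its two species' factors", {
  expect_equal(smutsia_cf(2, 4), 3)
  expect_equal(smutsia_cf(2.935, 2.935), 2.935)
  expect_equal(smutsia_cf(0.5, 1.7), mean(c(0.5, 1.7)))
})

test_that("aggregation sums groups and assigns percentages", {
  mni <- tibble::tibble(group = c("a", "b"), est_mass_kg = c(10, 30),
                        mass_ci_low_kg = c(8, 20), mass_ci_high_kg = c(12, 40),
                        cf_kg = c(1, 1), mni = c(10, 30),
                        mni_ci_low = c(8, 20), mni_ci_high = c(12, 40))
  agg <- aggregate_mni(mni)
  tot <- agg[agg$group == "Total", ]
  expect_equal(c(tot$mni, tot$mni_ci_low, tot$mni_ci_high), c(40, 28, 52))
  expect_equal(agg$pct_of_mni[agg$group == "a"], 25)
  one <- aggregate_mni(mni[1, ])
  expect_equal(one$pct_of_mni[one$group == "a"], 100)
})

test_that("bootstrap mean of p_rm recovers the generating mean at 67 sacks", {
  true_mean <- sack_sim_mean(sack_sim_config())
  means <- sapply(1:200, function(s) {
    prm <- relative_proportional_mass(simulate_sacks(seed = 5000 + s))
    mean(prm$white_bellied)
  })
  expect_lt(abs(mean(means) - true_mean[["white_bellied"]]), 0.01)
  # the reported bootstrap mean is the observed mean, exactly
  sk <- simulate_sacks(seed = 61)
  est <- bootstrap_prm(sk, n_boot = 1000, seed = 61)
  prm <- relative_proportional_mass(sk)
  expect_equal(est$mean, colMeans(as.matrix(prm[, -1]))[est$group],
               ignore_attr = TRUE)
  expect_true(all(est$ci_low <= est$mean & est$mean <= est$ci_high))
  expect_true(all(est$ci_low >= 0 & est$ci_high <= 1))
})

test_that("joint resampling is a coherent sensitivity variant", {
  sk <- simulate_sacks(seed = 71)
  joint <- bootstrap_prm(sk, n_boot = 1000, seed = 71, joint = TRUE)
  indep <- bootstrap_prm(sk, n_boot = 1000, seed = 71, joint = FALSE)
  expect_equal(joint$mean, indep$mean)
  expect_lt(max(abs(joint$ci_low - indep$ci_low)), 0.1)
})

test_that("the full report mirrors the standard table layout", {
  sk <- simulate_sacks(seed = 81)
  cf <- read_conversion_factors(ext_file("conversion_factors_derived.csv"))
  rep <- mni_report(sk, cf, m_cs = 190404, n_boot = 500, seed = 81)
  expect_s3_class(rep, "mni_table")
  expect_equal(rep$group, c("white_bellied", "black_bellied", "smutsia",
                            "unidentified", "Total"))
  est <- rep[rep$group != "Total" & !is.na(rep$mni), ]
  tot <- rep[rep$group == "Total", ]
  expect_equal(sum(est$mni), tot$mni)
  expect_equal(sum(est$mni_ci_low), tot$mni_ci_low)
  expect_equal(sum(est$mni_ci_high), tot$mni_ci_high)
  expect_equal(sum(est$pct_of_mni), 100)
  # unidentified scales carry mass but no conversion factor, hence no MNI
  expect_true(is.na(rep$mni[rep$group == "unidentified"]))
})

test_that("sack CSV reading validates masses and structure", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sack_id,total_mass_kg,wb_kg,bb_kg,smutsia_kg,unid_kg",
               "S1,50,3.2,0.5,0,0.1", "S2,20,2.0,0,0,0"), f)
  sk <- read_sacks(f)
  expect_equal(nrow(sk), 2)
  expect_equal(sk$white_bellied, c(3.2, 2.0))
  writeLines(c("sack_id,total_mass_kg,wb_kg,bb_kg,smutsia_kg,unid_kg",
               "S1,1,3.2,0.5,0,0.1"), f)
  expect_error(read_sacks(f), "exceeds")
})
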