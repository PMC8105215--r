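noise_free_config <- function(seed = 1) {
  synthetic_config(
    seed = seed, response_slope = 0.01, response_intercept = 0,
    calibration_levels = c(100, 500),
    cv_by_level = c("100" = 0, "500" = 0),
    pk_model = list(dose_mgkg = 2.5, ka = 11.4, ke = 0.8,
                    V_over_F = 1.124, between_animal_cv = 0))
}

test_that("config invariants are enforced", {
  expect_error(synthetic_config(calibration_levels = c(-10, 100)),
               "positive")
  expect_error(synthetic_config(cv_by_level = c("10" = -0.1)), ">= 0")
  expect_error(synthetic_config(
    pk_model = list(dose_mgkg = 2.5, ka = 0.8, ke = 0.8,
                    V_over_F = 1, between_animal_cv = 0)),
    "ka == ke")
  expect_error(synthetic_config(sampling_times = c(1, 1, 2)),
               "strictly increasing")
  expect_error(synthetic_config(decay_rate_by_condition = c("4C" = -1)),
               ">= 0")
})

test_that("identical seed and config give byte-identical datasets", {
  cfg <- synthetic_config(seed = 42)
  for (gen in list(simulate_calibration_set, simulate_lod_panel,
                   simulate_pk_dataset, simulate_stability_series)) {
    a <- gen(cfg)
    b <- gen(cfg)
    expect_identical(a, b)
    expect_identical(serialize(a, NULL), serialize(b, NULL))
  }
  sp1 <- simulate_specificity_panel(cfg)
  sp2 <- simulate_specificity_panel(cfg)
  expect_identical(sp1, sp2)
  # a different seed changes the draws
  expect_false(identical(
    simulate_calibration_set(cfg),
    simulate_calibration_set(synthetic_config(seed = 43))))
  # different run indices draw independent noise, reproducibly
  expect_false(identical(simulate_calibration_set(cfg),
                         simulate_calibration_set(cfg, run = 2L)))
  expect_identical(simulate_calibration_set(cfg, run = 2L),
                   simulate_calibration_set(cfg, run = 2L))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_pk_dataset(synthetic_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("noise-free calibration reproduces the line exactly", {
  d <- simulate_calibration_set(noise_free_config())
  expect_equal(d$area_ratio[d$nominal_conc == 100], rep(1.0, 3))
  expect_equal(d$area_ratio[d$nominal_conc == 500], rep(5.0, 3))
  expect_false(any(d$truncated))
})

test_that("calibration noise is relative with truncation at zero", {
  cfg <- synthetic_config(seed = 7,
                          calibration_levels = c(100),
                          cv_by_level = c("100" = 0.06),
                          replicates_per_level = 2000L)
  d <- simulate_calibration_set(cfg)
  mu <- 0.0113 * 100 - 0.1093
  emp_cv <- stats::sd(d$area_ratio) / mean(d$area_ratio)
  # empirical CV converges to the configured one within 3 SE,
  # SE(CV-hat) ~ cv/sqrt(2n)
  expect_lt(abs(emp_cv - 0.06), 3 * 0.06 / sqrt(2 * 2000))
  expect_equal(mean(d$area_ratio), mu, tolerance = 0.01)
  expect_error(simulate_calibration_set(
    synthetic_config(calibration_levels = c(10, 77),
                     cv_by_level = c("10" = 0.1))),
    "does not cover level 77")
})

test_that("generated slope recovers the configured one within 3 fitted SE", {
  cfg <- synthetic_config(seed = 31)  # plasma-like slope/intercept/CVs
  d <- simulate_calibration_set(cfg)
  curve <- fit_weighted_curve(d)
  expect_lt(abs(curve$m - 0.0113), 3 * curve$sd_slope)
})

test_that("LOD panel has the configured size, level and reproducible SD", {
  cfg <- synthetic_config(seed = 5)
  p <- simulate_lod_panel(cfg, n = 10L)
  expect_equal(nrow(p), 10L)
  expect_equal(unique(p$nominal_conc), 10)
  expect_identical(sd(p$area_ratio), sd(simulate_lod_panel(cfg)$area_ratio))
  expect_error(simulate_lod_panel(cfg, n = 2L), "n >= 3")

  # cv = 0 collapses the panel and hence the downstream LOD to zero
  p0 <- simulate_lod_panel(noise_free_config(), lowest_level = 100)
  expect_equal(sd(p0$area_ratio), 0)
})

test_that("mean LOD over many seeds brackets the closed-form expectation", {
  # E[LOD] ~ 3.9 * cv * E[signal] / slope (up to the small-sample SD bias)
  cv <- 0.136
  slope <- 0.0113
  mu <- slope * 10 - 0.1093  # plasma-like level-10 signal
  expected <- 3.9 * cv * abs(mu) / slope
  lods <- vapply(1:300, function(s) {
    cfg <- synthetic_config(seed = s, cv_by_level = c(
      "10" = cv, "50" = 0.08, "100" = 0.06, "500" = 0.028,
      "1000" = 0.04, "2000" = 0.053))
    p <- simulate_lod_panel(cfg, n = 10L)
    3.9 * sd(p$area_ratio) / slope
  }, numeric(1))
  expect_gt(mean(lods), 0.85 * expected)
  expect_lt(mean(lods), 1.15 * expected)
})

test_that("noise-free PK curve matches the closed form at its maximum", {
  cfg <- noise_free_config()
  pk <- cfg$pk_model
  tmax <- pk_tmax(pk)
  expect_equal(tmax, log(pk$ka / pk$ke) / (pk$ka - pk$ke), tolerance = 1e-15)
  # numeric maximum of the curve equals C(tmax) to 1e-9 relative
  opt <- stats::optimize(function(t) pk_concentration(t, pk),
                         c(0.01, 2), maximum = TRUE, tol = 1e-12)
  expect_equal(opt$objective, pk_concentration(tmax, pk), tolerance = 1e-9)

  d <- simulate_pk_dataset(
    synthetic_config(seed = 1, sampling_times = round(tmax, 6),
                     pk_model = pk, lloq = 1e-6))
  expect_equal(unique(d$conc), pk_concentration(round(tmax, 6), pk),
               tolerance = 1e-9)
  expect_equal(nrow(d), 8L)
})

test_that("PK dataset censors below the LLOQ and supports contamination", {
  cfg <- synthetic_config(seed = 3)
  d <- simulate_pk_dataset(cfg)
  expect_equal(nrow(d), 14L * 8L)
  expect_true(all(d$censored[d$time == 24]))   # far into elimination
  expect_false(any(d$censored[d$time == 0.25]))

  contaminated <- synthetic_config(seed = 3, contaminated_first_point = TRUE,
                                   contamination_factor = 6)
  dc <- simulate_pk_dataset(contaminated)
  expect_equal(dc$conc[dc$time == 0.08], 6 * d$conc[d$time == 0.08],
               tolerance = 1e-12)
  expect_equal(dc$conc[dc$time == 1], d$conc[d$time == 1], tolerance = 1e-12)
})

test_that("two-point noise-free elimination recovers ke exactly downstream", {
  tt <- c(4, 6)
  cc <- exp(-0.8 * tt)
  f <- suppressWarnings(fit_kel(build_profile(
    data.frame(time = c(0.25, tt), conc = c(max(cc) * 2, cc)))))
  expect_equal(f$kel, 0.8, tolerance = 1e-12)
})

test_that("stability series follows first-order decay", {
  cfg0 <- synthetic_config(seed = 2,
                           decay_rate_by_condition = c("frz" = 0))
  s0 <- simulate_stability_series(cfg0, noise_cv = 0)
  expect_true(all(s0$measured_conc == s0$nominal_conc))

  cfg <- synthetic_config(seed = 2,
                          decay_rate_by_condition = c("4C" = 0.3))
  s <- simulate_stability_series(cfg, times = 1, noise_cv = 0)
  expect_equal(unique(s$measured_conc / s$nominal_conc), exp(-0.3),
               tolerance = 1e-12)

  expect_error(simulate_stability_series(cfg, times = c(-1, 2)), "negative")

  # default rates reproduce the qualitative storage finding: 4C and -20C
  # unstable within a week, -80C stable through week 4 (noise-free view of
  # the generator's design point)
  r <- evaluate_stability(simulate_stability_series(synthetic_config(seed = 4),
                                                    noise_cv = 0))
  bc <- r$by_condition
  expect_equal(bc$first_unstable_time[bc$condition == "4C"], 1)
  expect_equal(bc$first_unstable_time[bc$condition == "-20C"], 1)
  expect_gt(bc$first_unstable_time[bc$condition == "-80C"], 4)
})

test_that("specificity panel is 20/20 by default and supports interference", {
  cfg <- synthetic_config(seed = 6)
  panel <- simulate_specificity_panel(cfg)
  expect_equal(nrow(panel$blanks), 20L)
  expect_equal(nrow(panel$fortified), 20L)

  lloq_resp <- 0.0113 * 10 - 0.1093
  clean <- evaluate_specificity(panel$blanks, panel$fortified,
                                lloq_response = lloq_resp)
  expect_true(clean$pass)

  # an injected interferent above the blank threshold fails with 1 offender
  bad <- simulate_specificity_panel(cfg, interference = c("7" = 0.5))
  res <- evaluate_specificity(bad$blanks, bad$fortified,
                              lloq_response = lloq_resp,
                              threshold_fraction = 0.2)
  expect_false(res$pass)
  expect_equal(res$offending_blanks, 7)
})
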