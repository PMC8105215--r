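make_cal <- function(slope, intercept, levels, reps = 3, cv = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(replicate = seq_len(reps), nominal_conc = levels)
  mu <- slope * d$nominal_conc + intercept
  d$area_ratio <- stats::rnorm(nrow(d), mu, abs(cv * mu))
  d
}

test_that("noise-free data recover the generating line exactly", {
  d <- make_cal(0.01, 0, c(10, 50, 100, 500, 1000, 2000))
  curve <- fit_weighted_curve(d)
  expect_equal(curve$m, 0.01, tolerance = 1e-12)
  expect_equal(curve$b, 0, tolerance = 1e-12)
  expect_equal(curve$r2, 1, tolerance = 1e-12)
  expect_equal(curve$n_levels, 6L)
})

test_that("weighted fit equals independent oracles on random datasets", {
  set.seed(42)
  for (i in 1:25) {
    n_lev <- sample(3:7, 1)
    levels <- sort(stats::runif(n_lev, 5, 2000))
    d <- make_cal(stats::runif(1, 1e-3, 0.05), stats::runif(1, -0.2, 0.2),
                  levels, reps = sample(1:3, 1), cv = 0.1, seed = i)
    curve <- fit_weighted_curve(d)
    w <- 1 / d$nominal_conc
    oracle <- lm_wls_oracle(d$nominal_conc, d$area_ratio, w)
    expect_equal(curve$m, oracle$m, tolerance = 1e-10)
    expect_equal(curve$b, oracle$b, tolerance = 1e-10)
    # brute-force minimiser agrees too (looser: iterative optimiser)
    bf <- optim_wls_oracle(d$nominal_conc, d$area_ratio, w)
    expect_equal(curve$m, bf$m, tolerance = 1e-6)
    expect_equal(curve$b, bf$b, tolerance = 1e-5)
  }
})

test_that("standard errors match the lm reference", {
  d <- make_cal(0.0113, -0.1093, c(10, 50, 100, 500, 1000, 2000),
                cv = 0.08, seed = 7)
  curve <- fit_weighted_curve(d)
  ref <- summary(stats::lm(area_ratio ~ nominal_conc, data = d,
                           weights = 1 / nominal_conc))$coefficients
  expect_equal(curve$sd_slope, ref["nominal_conc", "Std. Error"],
               tolerance = 1e-10)
  expect_equal(curve$sd_intercept, ref["(Intercept)", "Std. Error"],
               tolerance = 1e-10)
})

test_that("equal weights reduce the fit to ordinary least squares", {
  # two-point closed form: line through the two level means
  d <- data.frame(nominal_conc = c(100, 400), area_ratio = c(1.1, 4.4))
  curve <- fit_weighted_curve(d, weighting = "none")
  expect_equal(curve$m, (4.4 - 1.1) / (400 - 100), tolerance = 1e-12)
  expect_equal(curve$b, 1.1 - curve$m * 100, tolerance = 1e-12)
})

test_that("degenerate and invalid fit sets are rejected", {
  one_level <- data.frame(nominal_conc = rep(100, 3),
                          area_ratio = c(1, 1.1, 0.9))
  expect_error(fit_weighted_curve(one_level), "singular")
  with_blank <- data.frame(nominal_conc = c(0, 100, 500),
                           area_ratio = c(0, 1, 5))
  expect_error(fit_weighted_curve(with_blank), "blank")
})

test_that("replicate structure yields an R^2 spread", {
  d <- make_cal(0.0113, -0.1093, c(10, 50, 100, 500, 1000, 2000),
                reps = 3, cv = 0.08, seed = 3)
  curve <- fit_weighted_curve(d)
  expect_false(is.na(curve$sd_r2))
  expect_gte(curve$sd_r2, 0)
})

test_that("back-calculation inverts prediction", {
  d <- make_cal(0.01, 0, c(10, 100, 1000))
  curve <- fit_weighted_curve(d)
  expect_equal(back_calculate(curve, 1.0), 100, tolerance = 1e-12)
  # printed plasma line round-trips a mid-range level exactly
  d2 <- make_cal(0.0113, -0.1093, c(10, 50, 100, 500, 1000, 2000))
  c2 <- fit_weighted_curve(d2)
  expect_equal(back_calculate(c2, 0.0113 * 500 - 0.1093), 500,
               tolerance = 1e-9)
  # property: invert(predict(x)) == x for random curves and targets
  set.seed(5)
  for (i in 1:20) {
    d3 <- make_cal(stats::runif(1, 0.001, 0.1), stats::runif(1, -1, 1),
                   c(10, 100, 1000), cv = 0.05, seed = i + 100)
    c3 <- fit_weighted_curve(d3)
    x <- stats::runif(1, 1, 2000)
    expect_equal(back_calculate(c3, predict(c3, x)), x, tolerance = 1e-9)
  }
  # zero slope cannot be inverted
  fake <- structure(list(m = 0, b = 0), class = "calibration_curve")
  expect_error(back_calculate(fake, 1), "slope is zero")
})

test_that("LOD/LOQ follow the guidance arithmetic", {
  d <- make_cal(0.0113, 0, c(10, 100, 1000))
  curve <- fit_weighted_curve(d)  # noise-free: slope is exactly 0.0113

  # replicate signals with a known SD: LOD = 3.9 * SD / slope
  sigs <- c(0.1, 0.11, 0.09, 0.1, 0.105, 0.095, 0.1, 0.11, 0.09, 0.1)
  panel <- data.frame(nominal_conc = 10, area_ratio = sigs)
  dl <- estimate_lod_loq(panel, curve)
  expect_equal(dl$lod, 3.9 * sd(sigs) / 0.0113, tolerance = 1e-12)
  expect_equal(dl$loq, 3.3 * dl$lod, tolerance = 1e-12)

  # hand arithmetic: SD 0.00895, slope 0.0113 -> LOD 3.089, LOQ 10.19
  sigs2 <- 0.1 + 0.00895 * scale(seq_len(10))[, 1]
  panel2 <- data.frame(nominal_conc = 10, area_ratio = sigs2)
  dl2 <- estimate_lod_loq(panel2, curve)
  expect_equal(dl2$sd_signals, 0.00895, tolerance = 1e-9)
  expect_equal(dl2$lod, 3.089, tolerance = 1e-3)
  expect_equal(dl2$loq, 10.19, tolerance = 2e-3)

  # zero spread collapses both limits to zero
  flat <- data.frame(nominal_conc = 10, area_ratio = rep(0.1, 10))
  dl0 <- estimate_lod_loq(flat, curve)
  expect_equal(dl0$lod, 0)
  expect_equal(dl0$loq, 0)

  # structural errors
  mixed <- data.frame(nominal_conc = c(10, 10, 50), area_ratio = c(1, 1, 2))
  expect_error(estimate_lod_loq(mixed, curve), "single spike level")
  tiny <- data.frame(nominal_conc = 10, area_ratio = c(1, 1.1))
  expect_error(estimate_lod_loq(tiny, curve), ">= 3 replicates")
})

test_that("scaling responses scales the curve but not the limits", {
  d <- make_cal(0.0113, -0.01, c(10, 100, 1000), cv = 0.05, seed = 9)
  panel <- data.frame(nominal_conc = 10,
                      area_ratio = 0.1 + c(-2:2, -2:2) * 0.004)
  c1 <- fit_weighted_curve(d)
  dl1 <- estimate_lod_loq(panel, c1)
  k <- 7.3
  d2 <- d
  d2$area_ratio <- d2$area_ratio * k
  panel2 <- panel
  panel2$area_ratio <- panel2$area_ratio * k
  c2 <- fit_weighted_curve(d2)
  dl2 <- estimate_lod_loq(panel2, c2)
  expect_equal(c2$m, k * c1$m, tolerance = 1e-10)
  expect_equal(c2$b, k * c1$b, tolerance = 1e-10)
  expect_equal(dl2$sd_signals, k * dl1$sd_signals, tolerance = 1e-10)
  expect_equal(dl2$lod, dl1$lod, tolerance = 1e-10)
  expect_equal(dl2$loq, dl1$loq, tolerance = 1e-10)
})

test_that("self-evaluated 1/x recovery is identically 100%", {
  # the weighted normal equation sum((y - b)/x) = n*m forces the mean
  # per-level recovery of the fit set against its own curve to 100
  set.seed(33)
  for (i in 1:5) {
    d <- make_cal(0.0113, -0.1093, c(10, 50, 100, 500, 1000, 2000),
                  reps = 3, cv = 0.1, seed = i)
    curve <- fit_weighted_curve(d)
    r <- compute_recovery(data.frame(
      level = d$nominal_conc,
      calculated_conc = back_calculate(curve, d$area_ratio)))
    expect_equal(r$mean_recovery, 100, tolerance = 1e-10)
  }
})

test_that("loq_from_lod applies the 3.3 multiplier", {
  expect_equal(loq_from_lod(1), 3.3)
  expect_equal(loq_from_lod(0), 0)
  expect_error(loq_from_lod(-1))
})
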