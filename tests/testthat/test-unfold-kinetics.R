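# Forward model of three-state irreversible unfolding and its descriptors.

test_that("rate constant follows the Tstar-anchored Arrhenius form", {
  p <- kinetic_params(200, 340, 300, 350)
  expect_equal(rate_constant(p, 1, 340), 1)   # k = 1 min^-1 at Tstar
  expect_equal(rate_constant(p, 2, 350), 1)
  # frozen high-precision oracle (30-digit arbitrary-precision evaluation)
  expect_equal(rate_constant(p, 1, 350), 7.54961519784327, tolerance = 1e-12)
  # Ea = 0 collapses the formula to k = 1 at any temperature
  p0 <- kinetic_params(0, 340, 0, 350)
  expect_equal(rate_constant(p0, 1, c(280, 320, 390)), rep(1, 3))
  # strictly increasing in T for positive Ea
  k <- rate_constant(p, 1, seq(300, 370, 5))
  expect_true(all(diff(k) > 0))
  expect_error(rate_constant(p, 1, -5), "positive")
})

test_that("kinetic_params enforces its physical invariants", {
  expect_error(kinetic_params(-10, 340, 300, 350))
  expect_error(kinetic_params(200, 250, 300, 350), "273")
  expect_error(kinetic_params(200, 340, 300, 350, dh1 = -1), ">= 0")
  expect_silent(kinetic_params(200, 340, 300, Inf)) # frozen second step
})

test_that("scan propagation conserves mass and freezes far below Tstar", {
  p <- kinetic_params(150, 340, 150, 345)
  fr <- propagate_scan(p, 250, 280, v = 1, n_grid = 151)
  expect_true(all(fr$xN >= 0.999))            # rates effectively zero
  for (v in c(0.3, 1, 2)) {
    fr <- propagate_scan(default_truth_params(), 293.15, 368.15, v,
                         n_grid = 201)
    expect_lt(max(abs(fr$xN + fr$xI + fr$xD - 1)), 1e-9)
    expect_true(all(diff(fr$xN) <= 1e-12))    # xN non-increasing
    expect_true(all(fr$xN >= 0 & fr$xN <= 1))
    expect_true(all(fr$xI >= 0 & fr$xI <= 1))
  }
})

test_that("scan propagation matches a brute-force explicit-Euler oracle", {
  # gentle rates so the first-order Euler reference is itself accurate
  p <- kinetic_params(100, 355, 100, 365)
  fr <- propagate_scan(p, 300, 320, v = 1, n_grid = 21)
  orc <- euler_scan_oracle(p, 300, 320, v = 1, h = 1e-3)
  at <- match(round(fr$grid, 6), round(orc$grid, 6))
  expect_false(anyNA(at))
  expect_lt(max(abs(as.matrix(fr[, c("xN", "xI", "xD")]) -
                    orc$fractions[at, ])), 1e-5)
})

test_that("scan propagation matches an adaptive ODE solver over a full transition", {
  skip_if_not_installed("deSolve")
  p <- default_truth_params()
  v <- 1
  rhs <- function(tt, y, parms) {
    k1 <- rate_constant(p, 1, tt); k2 <- rate_constant(p, 2, tt)
    list(c(-k1 * y[1] / v, (k1 * y[1] - k2 * y[2]) / v))
  }
  grid <- seq(293.15, 368.15, length.out = 151)
  sol <- deSolve::lsoda(c(1, 0), grid, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  fr <- propagate_scan(p, 293.15, 368.15, v, n_grid = 151, max_step = 0.002)
  expect_lt(max(abs(fr$xN - sol[, 2])), 1e-6)
  expect_lt(max(abs(fr$xI - sol[, 3])), 1e-6)
})

test_that("isothermal fractions follow the analytic solution and its limits", {
  p <- default_truth_params()
  fr <- propagate_isothermal(p, 330, c(0, 5, 10))
  expect_equal(unlist(fr[1, c("xN", "xI", "xD")]),
               c(xN = 1, xI = 0, xD = 0))
  k1 <- rate_constant(p, 1, 330)
  expect_equal(fr$xN, exp(-k1 * c(0, 5, 10)))
  # frozen second step: xD identically zero, xI = 1 - exp(-k1 t)
  p2 <- kinetic_params(400, 337, 300, Inf)
  fr2 <- propagate_isothermal(p2, 340, seq(0, 30, 5))
  expect_equal(fr2$xD, rep(0, 7), tolerance = 1e-12)
  expect_equal(fr2$xI, 1 - exp(-rate_constant(p2, 1, 340) * seq(0, 30, 5)))
})

test_that("degenerate k1 = k2 branch matches numerical ODE integration", {
  skip_if_not_installed("deSolve")
  # parameters tuned so k1 and k2 coincide to ~1e-9 at the hold temperature
  p <- kinetic_params(300, 335, 300, 335.000000001)
  tt <- 335
  k1 <- rate_constant(p, 1, tt); k2 <- rate_constant(p, 2, tt)
  expect_lt(abs(k1 - k2), 1e-8)
  times <- seq(0, 5, length.out = 51)
  rhs <- function(t_, y, parms)
    list(c(-k1 * y[1], k1 * y[1] - k2 * y[2]))
  sol <- deSolve::lsoda(c(1, 0), times, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  fr <- propagate_isothermal(p, tt, times)
  expect_lt(max(abs(fr$xI - sol[, 3])), 1e-6)
  expect_equal(fr$xI[-1], k1 * times[-1] * exp(-k1 * times[-1]),
               tolerance = 1e-6)
})

test_that("DSC signal integrates to the total calorimetric enthalpy", {
  p <- default_truth_params()
  for (v in c(0.5, 2)) {
    fr <- propagate_scan(p, 293.15, 368.15, v, n_grid = 751)
    y <- dsc_signal(p, fr, v)
    area <- sum(diff(fr$grid) * (head(y, -1) + y[-1]) / 2)
    expect_equal(area, p$dh1 + p$dh2, tolerance = 0.01)
  }
  p0 <- kinetic_params(400, 337, 300, 342, 0, 0)
  fr <- propagate_scan(p0, 293.15, 368.15, 1, n_grid = 101)
  expect_equal(dsc_signal(p0, fr, 1), rep(0, 101))
  expect_error(dsc_signal(p, fr, 2), "mismatch")
})

test_that("DSC peak shifts to higher temperature at faster scan rates", {
  p <- default_truth_params() # dh2 = 0: curve proportional to k1 xN alone
  peaks <- vapply(c(0.3, 0.5, 1, 2), function(v) {
    fr <- propagate_scan(p, 293.15, 368.15, v, n_grid = 1501)
    fr$grid[which.max(dsc_signal(p, fr, v))]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  # proportionality to k1 xN when dh2 = 0
  fr <- propagate_scan(p, 293.15, 368.15, 1, n_grid = 201)
  y <- dsc_signal(p, fr, 1)
  ref <- rate_constant(p, 1, fr$grid) * fr$xN
  expect_equal(y / max(y), ref / max(ref), tolerance = 1e-12)
})

test_that("spectroscopic signal combines per-state linear baselines", {
  p <- default_truth_params()
  fr <- propagate_scan(p, 293.15, 368.15, 1, n_grid = 51)
  flat <- matrix(c(7, 0, 7, 0, 7, 0), 3, 2, byrow = TRUE)
  expect_equal(spectro_signal(fr, flat), rep(7, 51))
  # pure native: y = a_N + b_N (T - Tref)
  grid <- seq(293.15, 313.15, 1)
  frN <- crypticfold:::new_state_fractions(grid, rep(1, 21), rep(0, 21),
                                           rep(0, 21))
  base <- matrix(c(2, 0.1, 50, 1, 80, 2), 3, 2, byrow = TRUE)
  expect_equal(spectro_signal(frN, base, tref = 298.15),
               2 + 0.1 * (grid - 298.15), tolerance = 1e-12)
  # hand-built two-point fractions with known baselines
  fr2 <- structure(data.frame(grid = c(300, 310), xN = c(1, 0.25),
                              xI = c(0, 0.5), xD = c(0, 0.25)),
                   axis = "temperature", class = c("state_fractions",
                                                   "data.frame"))
  attr(fr2, "axis") <- "temperature"
  y <- spectro_signal(fr2, base, tref = 300)
  expect_equal(y[1], 2)
  expect_equal(y[2], (2 + 0.1 * 10) * 0.25 + (50 + 1 * 10) * 0.5 +
                     (80 + 2 * 10) * 0.25)
})

test_that("Eyring barriers invert the rate constants exactly", {
  p <- default_truth_params()
  br <- barrier_at(p)
  expect_equal(br$temperature, c(313.15, 333.15, 353.15))
  # closed form at Tstar where k = 1 min^-1
  br_star <- barrier_at(p, p$tstar1)
  expect_equal(br_star$dG1,
               -8.314 * p$tstar1 *
                 log((1 / 60) * 6.62607015e-34 /
                     (1.380649e-23 * p$tstar1)) / 1000)
  # round trip: rates reconstructed from barriers match within 1e-9 relative
  temps <- seq(300, 370, 10)
  br2 <- barrier_at(p, temps)
  k1_back <- crypticfold:::rate_from_barrier(br2$dG1, temps)
  expect_equal(k1_back, rate_constant(p, 1, temps), tolerance = 1e-9)
  expect_true(all(br2$dG1 > 0) && all(br2$dG2 > 0))
  # dG decreasing in T when Ea dominates the Eyring prefactor slope
  p300 <- kinetic_params(300, 340, 300, 350)
  br3 <- barrier_at(p300, seq(300, 370, 1))
  expect_true(all(diff(br3$dG1) < 0))
})

test_that("barycentric mean is the intensity-weighted wavelength", {
  wl <- seq(300, 400, 10)
  ii <- rep(0, 11); ii[4] <- 5
  expect_equal(bcm_from_spectrum(wl, ii), 330)
  expect_equal(bcm_from_spectrum(c(300, 400), c(1, 3)), 375)
  sym <- dnorm(wl, 350, 20)
  expect_equal(bcm_from_spectrum(wl, sym), 350)
  expect_error(bcm_from_spectrum(wl, rep(0, 11)), "all-zero")
})

test_that("mean residue ellipticity conversion is exact and linear", {
  expect_equal(mre_convert(0, 33000, 300, 0.175, 0.1), 0)
  v1 <- mre_convert(10, 33000, 300, 0.175, 0.1)
  expect_equal(v1, 6285714.2857142857, tolerance = 1e-12) # arithmetic oracle
  expect_equal(mre_convert(10, 33000, 300, 0.35, 0.1), v1 / 2)
  expect_error(mre_convert(10, 33000, 300, 0, 0.1), "positive")
})

test_that("curve metrics recover planted descriptors", {
  x <- seq(293.15, 373.15, 0.5)
  gauss <- experiment_curve("DSC", x, exp(-(x - 338.15)^2 / 18), scan_rate = 1)
  expect_equal(curve_metrics(gauss, "tm_peak"), 338.15)
  logi <- experiment_curve("DSF_BCM", x, 1 / (1 + exp((330 - x) / 2)),
                           scan_rate = 1)
  expect_equal(curve_metrics(logi, "tm_midpoint"), 330, tolerance = 1e-3)
  # SLS fixture with a planted maximum of 4278 counts inside the 20-80 C window
  sls_y <- 50 + 4228 * exp(-(x - 338.15)^2 / 8)
  sls <- experiment_curve("SLS", x, sls_y, scan_rate = 1)
  expect_equal(curve_metrics(sls, "agg_max"), 4278)
  # onset: flat baseline then rise
  on_y <- c(rep(0, 100), seq(0.1, 5, length.out = 61))
  on_y[1:100] <- on_y[1:100] + sin(1:100) * 1e-3
  onset <- experiment_curve("SLS", x, on_y, scan_rate = 1)
  t_on <- curve_metrics(onset, "t_onset", k_sd = 5)
  expect_gte(t_on, x[100])
  expect_lte(t_on, x[105])
  flat <- experiment_curve("CD", x, rep(1, length(x)), scan_rate = 1)
  expect_true(is.na(curve_metrics(flat, "tm_midpoint")))
})

test_that("reversibility ratio is the reheat/first peak-area ratio", {
  x <- seq(303.15, 363.15, 0.5)
  y <- exp(-(x - 330)^2 / 20)
  first <- experiment_curve("DSC", x, y, scan_rate = 1)
  same <- experiment_curve("DSC", x, y, scan_rate = 1)
  expect_equal(reversibility_ratio(first, same), 100)
  zero <- experiment_curve("DSC", x, rep(0, length(x)), scan_rate = 1)
  expect_equal(reversibility_ratio(first, zero), 0)
  scaled <- experiment_curve("DSC", x, 0.29 * y, scan_rate = 1)
  expect_equal(reversibility_ratio(first, scaled), 29)
  expect_error(reversibility_ratio(zero, first), "zero first-scan")
})

test_that("SLS correlation identifies the aggregating species", {
  p <- default_truth_params()
  v <- 1
  fr <- propagate_scan(p, 293.15, 368.15, v, n_grid = 151)
  mkc <- function(y) experiment_curve("SLS", fr$grid, y, scan_rate = v)
  resD <- state_fraction_sls_correlation(p, v, mkc(fr$xD))
  expect_equal(resD$best_match, "D")
  expect_equal(unname(resD$correlations["D"]), 1, tolerance = 1e-9)
  resI <- state_fraction_sls_correlation(p, v, mkc(fr$xI))
  expect_equal(resI$best_match, "I")
  set.seed(3)
  noisy <- fr$xI + rnorm(151, 0, 0.05 * diff(range(fr$xI)))
  resN <- state_fraction_sls_correlation(p, v, mkc(noisy))
  expect_equal(resN$best_match, "I")
  expect_gt(resN$correlations["I"], 0.9)
  flatc <- state_fraction_sls_correlation(p, v, mkc(rep(2, 151)))
  expect_equal(flatc$flag, "constant_signal")
})

test_that("curve CSV round trip preserves data and Celsius file contract", {
  p <- default_truth_params()
  cur <- gen_thermal_datasets(p, scan_rates = 1, techniques = "DSC",
                              noise_sd = 0.01, seed = 4, n_points = 40)[[1]]
  f <- tempfile(fileext = ".csv")
  write_curve(cur, f)
  txt <- readLines(f)
  expect_match(txt[1], "^#technique=DSC$")
  expect_match(txt[2], "^#scan_rate_C_per_min=1$")
  back <- read_curve(f)
  expect_equal(back$x, cur$x, tolerance = 1e-9)
  expect_equal(back$y, cur$y, tolerance = 1e-12)
  iso <- gen_isothermal_traces(p, temps = 330, duration = 10, n_points = 20,
                               noise_sd = 0, seed = 1)[[1]]
  f2 <- tempfile(fileext = ".csv")
  write_curve(iso, f2)
  back2 <- read_curve(f2)
  expect_equal(back2$hold_temperature, 330, tolerance = 1e-9)
  expect_equal(back2$y, iso$y, tolerance = 1e-12)
})
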