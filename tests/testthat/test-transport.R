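# Diffusion, Green-Kubo viscosity, surface tension/excess, freezing
# bracket.

test_that("Einstein-relation diffusion recovers exact and random-walk inputs", {
  ## exact line msd = 6 D t with D = 1.3e-9 m^2/s
  D <- 1.3e-9
  t <- 0:1000
  msd <- 6 * (D / 1e-8) * t          # A^2 with t in ps
  est <- diffusion_einstein(t, msd, window = c(100, 900))
  expect_equal(est$D, D, tolerance = 1e-12)
  ## constant MSD -> zero
  expect_equal(suppressWarnings(diffusion_einstein(t, rep(5, length(t)),
                                                   window = c(100, 900))$D), 0)
  ## seeded 3D random walk: recovery within 5%
  rw <- make_random_walk(D, dt = 1, n_steps = 10000, n_walkers = 800, seed = 5)
  est2 <- diffusion_einstein(rw$time, rw$msd, window = c(500, 5000))
  expect_lt(abs(est2$D / D - 1), 0.05)
  expect_error(diffusion_einstein(t, msd, window = c(0, 3)), ">= 5")
})

test_that("the Yeh-Hummer correction has the exact analytic form and limits", {
  ## vanishes as L -> infinity
  expect_equal(yeh_hummer_correction(1e-9, 298, 0.893e-3, 1e6), 1e-9,
               tolerance = 1e-12)
  ## halving L doubles the correction term
  c1 <- yeh_hummer_correction(0, 298, 0.893e-3, 5e-9)
  c2 <- yeh_hummer_correction(0, 298, 0.893e-3, 2.5e-9)
  expect_equal(c2 / c1, 2, tolerance = 1e-12)
  ## independent constant-arithmetic oracle at T = 298 K, eta = 0.893 mPa s,
  ## L = 5 nm
  oracle <- 2.837297 * 1.380649e-23 * 298 / (6 * pi * 0.893e-3 * 5e-9)
  expect_equal(c1, oracle, tolerance = 1e-12)
  expect_error(yeh_hummer_correction(1e-9, -1, 1e-3, 1e-9), "positive")
})

test_that("Green-Kubo viscosity matches the analytic OU integral", {
  sigma2 <- 400; tau <- 2; dt <- 0.05; Tk <- 300; V <- 40000
  st <- make_ou_tensor(sigma2, tau, dt, n = 1e6, seed = 9)
  ## lag-0 autocorrelation is the channel variance
  gv0 <- green_kubo_viscosity(st, T = Tk, V = V, upper_time = 5)
  expect_lt(abs(mean(gv0$acf[1, ]) / sigma2 - 1), 0.05)
  ## integral to ~15 tau: eta = V/(kB T) sigma2 tau within 10%
  gv <- green_kubo_viscosity(st, T = Tk, V = V, upper_time = 30)
  truth <- V * 1e-30 / (1.380649e-23 * Tk) * sigma2 * tau * 1e-2
  expect_lt(abs(gv$eta / truth - 1), 0.10)
  ## direct and FFT autocorrelations are algebraically identical
  short <- make_ou_tensor(sigma2, tau, dt, n = 20000, seed = 10)
  gd <- green_kubo_viscosity(short, T = Tk, V = V, upper_time = 5, method = "direct")
  gf <- green_kubo_viscosity(short, T = Tk, V = V, upper_time = 5, method = "fft")
  expect_lt(max(abs(gd$acf - gf$acf)), 1e-10)
  ## zero fluctuations -> zero viscosity
  z <- make_ou_tensor(0, tau, dt, n = 1000, seed = 1)
  expect_equal(green_kubo_viscosity(z, T = Tk, V = V, upper_time = 5)$eta, 0)
  ## channel relabeling leaves the estimate unchanged
  sw <- ptensor_series(st$time, Pxy = st$Pyz, Pxz = st$Pxy, Pyz = st$Pxz)
  gsw <- green_kubo_viscosity(sw, T = Tk, V = V, upper_time = 30)
  expect_equal(gsw$eta, gv$eta, tolerance = 1e-12)
})

test_that("the OU estimator error shrinks as the sample count grows", {
  sigma2 <- 400; tau <- 2; dt <- 0.05; Tk <- 300; V <- 40000
  truth <- V * 1e-30 / (1.380649e-23 * Tk) * sigma2 * tau * 1e-2
  err <- vapply(c(2e4, 2e5, 1e6), function(n) {
    ## average over 3 seeds to damp single-run fluctuations
    es <- vapply(1:3, function(s) {
      st <- make_ou_tensor(sigma2, tau, dt, n = n, seed = 100 + s)
      green_kubo_viscosity(st, T = Tk, V = V, upper_time = 30)$eta
    }, 0)
    abs(mean(es) / truth - 1)
  }, 0)
  expect_lt(err[3], err[1])
})

test_that("non-uniform time grids are rejected", {
  expect_error(ptensor_series(c(0, 1, 3), Pxy = c(0, 0, 0)), "uniform")
})

test_that("virial surface tension handles the isotropic, constructed and scaled cases", {
  ## isotropic pressure -> zero
  expect_equal(surface_tension_virial(c(Pxx = 3, Pyy = 3, Pzz = 3), L_z = 80), 0)
  ## constructed anisotropy: Pzz = 1 bar, Lz = 100 A, 2 interfaces -> 0.5 mN/m
  expect_equal(surface_tension_virial(c(Pxx = 0, Pyy = 0, Pzz = 1),
                                      L_z = 100, n_interfaces = 2), 0.5)
  ## linear in the anisotropy
  g1 <- surface_tension_virial(c(Pxx = -1, Pyy = -2, Pzz = 4), L_z = 90)
  g3 <- surface_tension_virial(c(Pxx = -3, Pyy = -6, Pzz = 12), L_z = 90)
  expect_equal(g3, 3 * g1, tolerance = 1e-12)
  ## series input, with x/y channel relabeling invariance
  s <- ptensor_series(0:9, Pxx = rep(0, 10), Pyy = rep(0.4, 10), Pzz = rep(1, 10))
  s2 <- ptensor_series(0:9, Pxx = rep(0.4, 10), Pyy = rep(0, 10), Pzz = rep(1, 10))
  expect_equal(surface_tension_virial(s, 100), surface_tension_virial(s2, 100))
})

test_that("the Gibbs surface excess integrates constructed profiles exactly", {
  ## profile identical to the reference step -> zero excess
  flat <- make_step_profile(0.01, z_gds = 30)
  expect_equal(surface_excess(flat$z, flat$rho, 0.01, dividing_z = 30), 0)
  ## depletion layer of known deficit
  dep <- make_step_profile(0.01, z_gds = 30, layer_width = 5, layer_delta = -0.004)
  expect_equal(surface_excess(dep$z, dep$rho, 0.01, dividing_z = 30),
               dep$gamma_true, tolerance = 1e-9)
  expect_lt(dep$gamma_true, 0)
  ## sign flips for an enhancement layer
  enh <- make_step_profile(0.01, z_gds = 30, layer_width = 5, layer_delta = +0.004)
  expect_equal(surface_excess(enh$z, enh$rho, 0.01, dividing_z = 30),
               -dep$gamma_true, tolerance = 1e-9)
  ## the solvent equimolar surface of a perfect step is the step position
  expect_equal(equimolar_surface(flat$z, flat$rho, 0.01), 30, tolerance = 0.1)
  ## missing plateau is rejected
  ramp <- seq(0, 0.01, length.out = 61)
  expect_error(surface_excess(seq(0, 60, 1), ramp, dividing_z = 30), "plateau")
})

test_that("freezing-point bracketing returns the tightest consistent bracket", {
  b <- freezing_point_bracket(c(270, 272), c("grows", "melts"), T_ref = 273.15)
  expect_equal(b$T_low, 270); expect_equal(b$T_high, 272)
  expect_true(b$consistent)
  expect_equal(b$delta_T, 271 - 273.15)
  ## randomized consistent sets against an exhaustive scan oracle
  set.seed(8)
  for (k in 1:20) {
    Tf <- runif(1, 255, 272)
    Ts <- sort(runif(6, 250, 275))
    ind <- ifelse(Ts < Tf, "grows", "melts")
    if (!any(ind == "grows") || !any(ind == "melts")) next
    b <- freezing_point_bracket(Ts, ind)
    expect_equal(b$T_low, max(Ts[Ts < Tf]))
    expect_equal(b$T_high, min(Ts[Ts >= Tf]))
    expect_true(b$T_low <= Tf && Tf <= b$T_high)
  }
  ## single observation cannot bracket
  expect_error(freezing_point_bracket(270, "grows"), "at least one")
  ## inconsistent observations are flagged and widened
  expect_warning(b2 <- freezing_point_bracket(c(268, 271, 274), c("melts", "grows", "melts")),
                 "inconsistent")
  expect_false(b2$consistent)
  expect_lte(b2$T_low, b2$T_high)
})
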