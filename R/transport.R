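# Transport and interfacial estimators: Einstein-relation diffusion with
# the Yeh-Hummer finite-size correction, Green-Kubo shear viscosity from
# pressure-tensor fluctuations, virial-route surface tension, Gibbs
# surface excess, direct-coexistence freezing-point bracketing, and the
# picnometer density equation.

#' Pressure-tensor time series
#'
#' @param time Uniform time grid, ps.
#' @param Pxy,Pxz,Pyz Off-diagonal components, bar.
#' @param Pxx,Pyy,Pzz Optional diagonal components, bar.
#' @param box Optional box dimensions, A (length 3).
#' @return Object of class `"ptensor_series"` (a data.frame with the box
#'   as attribute).
#' @export
ptensor_series <- function(time, Pxy = NULL, Pxz = NULL, Pyz = NULL,
                           Pxx = NULL, Pyy = NULL, Pzz = NULL, box = NULL) {
  n <- length(time)
  if (n < 2L) .stopf("a pressure-tensor series needs at least 2 samples")
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-8 * max(abs(dt))))
    .stopf("pressure-tensor time grid must be uniform")
  df <- data.frame(time = time)
  for (nm in c("Pxy", "Pxz", "Pyz", "Pxx", "Pyy", "Pzz")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != n) .stopf("%s length differs from time grid", nm)
      if (any(!is.finite(v))) .stopf("%s contains non-finite values", nm)
      df[[nm]] <- v
    }
  }
  structure(df, class = c("ptensor_series", "data.frame"), box = box)
}

## autocorrelation up to lag m-1, unbiased normalization (sum / (n - k))
.acf_direct <- function(x, m) {
  n <- length(x)
  vapply(0:(m - 1L), function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / (n - k), 0)
}

.acf_fft <- function(x, m) {
  n <- length(x)
  npad <- 2^ceiling(log2(2 * n))
  xp <- c(x, rep(0, npad - n))
  s <- Re(stats::fft(Mod(stats::fft(xp))^2, inverse = TRUE)) / npad
  s[1:m] / (n - 0:(m - 1L))
}

#' Green-Kubo shear viscosity
#'
#' `eta = V/(k_B T) int_0^t ds <P_ab(0) P_ab(s)>`, averaging the
#' independent off-diagonal channels (Pxy, Pxz, Pyz) and, when diagonal
#' components are present, the rotated diagonal-difference channels
#' (Pxx-Pyy)/2 etc. The autocorrelation is computed by FFT (default) or by
#' the direct sum; the two are algebraically identical.
#'
#' @param series A `"ptensor_series"` (time in ps, pressures in bar).
#' @param T Temperature, K.
#' @param V Volume, A^3.
#' @param upper_time Upper integration limit, ps (must not exceed the
#'   series span; default one tenth of it).
#' @param method `"fft"` or `"direct"` autocorrelation.
#' @return List: `eta` (Pa s), per-channel `acf` matrix, `lag` times (ps),
#'   running integral `eta_t` (Pa s vs lag).
#' @export
green_kubo_viscosity <- function(series, T, V, upper_time = NULL,
                                 method = c("fft", "direct")) {
  stopifnot(inherits(series, "ptensor_series"))
  method <- match.arg(method)
  dt <- series$time[2] - series$time[1]
  span <- series$time[length(series$time)] - series$time[1]
  if (is.null(upper_time)) upper_time <- span / 10
  if (upper_time > span + 1e-12) .stopf("upper_time exceeds the series span")
  m <- max(2L, min(length(series$time), floor(upper_time / dt) + 1L))

  chans <- list()
  for (nm in c("Pxy", "Pxz", "Pyz"))
    if (!is.null(series[[nm]])) chans[[nm]] <- series[[nm]]
  if (all(c("Pxx", "Pyy", "Pzz") %in% names(series))) {
    chans[["(Pxx-Pyy)/2"]] <- (series$Pxx - series$Pyy) / 2
    chans[["(Pyy-Pzz)/2"]] <- (series$Pyy - series$Pzz) / 2
    chans[["(Pxx-Pzz)/2"]] <- (series$Pxx - series$Pzz) / 2
  }
  if (!length(chans)) .stopf("series carries no usable stress channels")
  acfm <- vapply(chans, function(x) {
    x <- x - mean(x)
    if (method == "fft") .acf_fft(x, m) else .acf_direct(x, m)
  }, numeric(m))
  cavg <- rowMeans(acfm)
  lag <- (0:(m - 1L)) * dt
  run_int <- c(0, cumsum((cavg[-1] + cavg[-m]) / 2 * dt))  # bar^2 ps
  ## bar^2 ps -> Pa^2 s : 1e10 * 1e-12 ; V A^3 -> m^3 : 1e-30
  conv <- V * 1e-30 / (.kB_J * T) * 1e10 * 1e-12
  list(eta = conv * run_int[m], lag = lag, acf = acfm,
       eta_t = conv * run_int, channels = names(chans), method = method)
}

#' Diffusion coefficient from the Einstein relation
#'
#' Linear fit of the mean-squared displacement against time over a stated
#' window (chosen to avoid short-time ballistic/subdiffusive transients);
#' `D = slope/6` in three dimensions, converted to m^2/s.
#'
#' @param time Time grid, ps.
#' @param msd Mean-squared displacement, A^2.
#' @param window Length-2 fit window in time units, `c(t_lo, t_hi)`;
#'   default the central 50% of the series. At least 5 points must fall in
#'   the window.
#' @return List: `D` (m^2/s), `slope` (A^2/ps), `intercept`, `se_D`.
#' @export
diffusion_einstein <- function(time, msd, window = NULL) {
  if (length(time) != length(msd)) .stopf("time and msd lengths differ")
  if (is.null(window)) window <- stats::quantile(time, c(0.25, 0.75), names = FALSE)
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 5L)
    .stopf("fit window [%g, %g] contains only %d points (need >= 5)",
           window[1], window[2], sum(sel))
  fit <- stats::lm(msd[sel] ~ time[sel])
  slope <- unname(stats::coef(fit)[2])
  if (slope < 0) warning("negative MSD slope: returning a negative diffusion coefficient")
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))[2]
  list(D = slope / 6 * .A2_PS_TO_M2_S, slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       se_D = unname(se) / 6 * .A2_PS_TO_M2_S)
}

#' Yeh-Hummer finite-size correction for diffusion
#'
#' `D_0 = D_pbc + xi k_B T / (6 pi eta L)` with `xi = 2.837297` for a
#' cubic periodic box.
#'
#' @param D_pbc Diffusion coefficient under periodic boundaries, m^2/s.
#' @param T Temperature, K.
#' @param eta Shear viscosity, Pa s.
#' @param L Box edge, m.
#' @return Corrected diffusion coefficient, m^2/s.
#' @export
yeh_hummer_correction <- function(D_pbc, T, eta, L) {
  if (any(c(T, eta, L) <= 0)) .stopf("T, eta and L must all be positive")
  D_pbc + .XI_YH * .kB_J * T / (6 * pi * eta * L)
}

#' Surface tension by the virial (mechanical) route
#'
#' For a liquid slab normal to z with `n_interfaces` liquid-vapor
#' interfaces, `gamma = (L_z/n) [<P_zz> - (<P_xx> + <P_yy>)/2]`,
#' unit-converted from bar A to mN/m (1 bar A = 1e-2 mN/m).
#'
#' @param series A `"ptensor_series"` with diagonal components, or a named
#'   numeric of means `c(Pxx=, Pyy=, Pzz=)` in bar.
#' @param L_z Box length normal to the interface, A.
#' @param n_interfaces Number of interfaces (2 for a slab).
#' @return Surface tension, mN/m.
#' @export
surface_tension_virial <- function(series, L_z, n_interfaces = 2) {
  if (L_z <= 0) .stopf("L_z must be > 0")
  if (inherits(series, "ptensor_series")) {
    if (!all(c("Pxx", "Pyy", "Pzz") %in% names(series)))
      .stopf("virial surface tension needs the diagonal pressure components")
    p <- c(Pxx = mean(series$Pxx), Pyy = mean(series$Pyy), Pzz = mean(series$Pzz))
  } else p <- series
  gamma_barA <- (L_z / n_interfaces) * (p[["Pzz"]] - (p[["Pxx"]] + p[["Pyy"]]) / 2)
  gamma_barA * .BAR_A_TO_mN_m
}

#' Equimolar dividing surface of a density profile
#'
#' Position `z_e` at which a sharp step of height `rho_bulk` (liquid at
#' low z) contains the same number of molecules as the actual profile.
#'
#' @param z Profile grid, A (increasing; liquid side first).
#' @param rho Number density profile, A^-3.
#' @param rho_bulk Bulk liquid density, A^-3.
#' @return `z_e` in A.
#' @export
equimolar_surface <- function(z, rho, rho_bulk) {
  if (rho_bulk <= 0) .stopf("rho_bulk must be > 0")
  total <- .trapz(z, rho)
  z[1] + total / rho_bulk
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Gibbs surface excess from a density profile
#'
#' `Gamma = int [rho(z) - rho_bulk * step(z)] dz` per interface, with the
#' step equal to `rho_bulk` on the liquid side of the dividing surface
#' (conventionally fixed at the solvent's equimolar position) and zero on
#' the vapor side. Negative values mean interfacial depletion (negative
#' adsorption), as found for alkali and hydroxide ions.
#'
#' @param z Profile grid, A (increasing; liquid at low z).
#' @param rho Solute number density profile, A^-3.
#' @param rho_bulk Bulk solute density, A^-3. `NULL` auto-detects it as the
#'   mean over the first quarter of the grid, requiring a plateau there
#'   (relative spread < 5%); otherwise an error asks for an explicit value.
#' @param dividing_z Dividing-surface position, A; typically
#'   [equimolar_surface()] of the solvent profile.
#' @return Surface excess in molecules/nm^2 (1 A^-2 = 100 nm^-2).
#' @export
surface_excess <- function(z, rho, rho_bulk = NULL, dividing_z) {
  if (length(z) != length(rho)) .stopf("z and rho lengths differ")
  if (is.null(rho_bulk)) {
    head_idx <- seq_len(max(4L, length(z) %/% 4L))
    plateau <- rho[head_idx]
    if (mean(plateau) <= 0 ||
        (max(plateau) - min(plateau)) > 0.05 * mean(plateau))
      .stopf("no bulk plateau detected at the liquid end; supply rho_bulk explicitly")
    rho_bulk <- mean(plateau)
  }
  if (dividing_z < z[1] || dividing_z > z[length(z)])
    .stopf("dividing surface %.3f lies outside the profile range", dividing_z)
  step <- ifelse(z <= dividing_z, rho_bulk, 0)
  gamma_A2 <- .trapz(z, rho - step)
  gamma_A2 * 100  # A^-2 -> nm^-2
}

#' Freezing-point bracket from direct-coexistence observations
#'
#' In the direct-coexistence method an explicit ice-solution interface is
#' simulated at a set of temperatures; ice growth means T below the
#' freezing point, melting means T above it. The tightest consistent
#' bracket is [highest growing T, lowest melting T].
#'
#' @param temperature Temperatures, K.
#' @param indicator Character vector: `"grows"`, `"melts"` or `"stable"`.
#' @param T_ref Optional pure-solvent freezing point, K, for the
#'   freezing-point depression.
#' @return List: `T_low`, `T_high` (K), `consistent` flag, and (with
#'   `T_ref`) `delta_T` = bracket midpoint minus `T_ref`.
#' @export
freezing_point_bracket <- function(temperature, indicator, T_ref = NULL) {
  if (length(temperature) != length(indicator)) .stopf("temperature and indicator lengths differ")
  indicator <- match.arg(indicator, c("grows", "melts", "stable"), several.ok = TRUE)
  tg <- temperature[indicator == "grows"]
  tm <- temperature[indicator == "melts"]
  if (!length(tg) || !length(tm))
    .stopf("need at least one 'grows' and one 'melts' observation to bracket")
  T_low <- max(tg); T_high <- min(tm)
  consistent <- T_low < T_high
  if (!consistent) {
    warning(sprintf("inconsistent observations (growth at %.2f K above melting at %.2f K); returning the widest consistent bracket", T_low, T_high))
    T_low <- min(tg); T_high <- max(tm)
    if (T_low >= T_high) { T_low <- min(temperature); T_high <- max(temperature) }
  }
  out <- list(T_low = T_low, T_high = T_high, consistent = consistent)
  if (!is.null(T_ref)) out$delta_T <- (T_low + T_high) / 2 - T_ref
  out
}

#' Picnometer density from the capillary meniscus position
#'
#' A picnometer is a calibrated flask of volume `V_f0` attached to a
#' capillary of cross-section `S_0`; the sample mass is fixed, so the
#' density at temperature T follows from mass conservation,
#' `rho(T) = rho_0 (V_f0 + S_0 L_0) / [(V_f0 + S_0 L) (1 + 3 delta)]`
#' with `delta = alpha (T - T_0)` the linear thermal expansion of the
#' glass. The default linearizes the glass volume factor as `1 + 3 delta`;
#' `exact_expansion = TRUE` uses `(1 + delta)^3` (identical to first order,
#' and both reduce to `rho_0` at the calibration point).
#'
#' @param L Meniscus position, same length unit as `L_0`.
#' @param calib Calibration list: `V_f0` (flask volume), `S_0` (capillary
#'   cross-section), `L_0` (meniscus at `T_0`), `alpha` (1/K), `T_0` (K),
#'   `rho_0` (kg/m^3). Volume units must be consistent (`V_f0` in the cube
#'   of the length unit of `L`, `S_0` in its square).
#' @param T Sample temperature, K.
#' @param exact_expansion Use the exact `(1 + delta)^3` volume factor?
#' @return Density, kg/m^3.
#' @export
picnometer_density <- function(L, calib, T, exact_expansion = FALSE) {
  need <- c("V_f0", "S_0", "L_0", "alpha", "T_0", "rho_0")
  miss <- setdiff(need, names(calib))
  if (length(miss)) .stopf("calibration is missing: %s", paste(miss, collapse = ", "))
  if (calib$V_f0 <= 0 || calib$S_0 <= 0) .stopf("flask volume and capillary section must be > 0")
  v_ref <- calib$V_f0 + calib$S_0 * calib$L_0
  v_now <- calib$V_f0 + calib$S_0 * L
  if (any(v_now <= 0)) .stopf("nonphysical negative sample volume")
  delta <- calib$alpha * (T - calib$T_0)
  glass <- if (exact_expansion) (1 + delta)^3 else 1 + 3 * delta
  calib$rho_0 * v_ref / (v_now * glass)
}
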