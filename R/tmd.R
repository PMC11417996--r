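# Temperature of maximum density: cubic polynomial fit to rho(T) with the
# TMD extracted analytically as the interior stationary point of negative
# curvature, plus Despretz group-contribution algebra for the TMD shift.

#' Fit the temperature of maximum density
#'
#' Least-squares cubic polynomial fit of density against temperature; the
#' TMD is the root of d(rho)/dT = 0 inside the data range with negative
#' second derivative, extracted analytically from the fitted coefficients.
#' The TMD uncertainty is first-order propagation from the coefficient
#' covariance (implicit-function gradient); an optional Monte-Carlo mode
#' additionally propagates stated per-point temperature and density
#' uncertainties, mirroring a fuller experimental uncertainty budget.
#'
#' @param temperature Temperatures, K (strictly increasing), or a
#'   `data.frame` with columns `T`/`temperature` and `rho`/`density`.
#' @param density Densities, kg/m^3 (ignored when a data.frame is given).
#' @param weights Optional least-squares weights.
#' @param mc Number of Monte-Carlo replicates for the optional budget mode
#'   (0 = off).
#' @param t_sigma,rho_sigma Per-point standard uncertainties used by the
#'   Monte-Carlo mode (K, kg/m^3).
#' @return Object of class `"tmd_fit"` with fields `tmd` (K; `NA` when no
#'   interior maximum exists), `density_at_tmd`, `tmd_se`, `coefficients`
#'   (rho = c0 + c1 T + c2 T^2 + c3 T^3), `vcov`, `status`, `data`, and
#'   (if requested) `tmd_se_mc`.
#' @examples
#' s <- make_cubic_density(tmd = 257.1, curvature = 0.008,
#'                         t_range = c(240, 280), noise_sd = 0, seed = 1)
#' fit_tmd(s)$tmd
#' @export
fit_tmd <- function(temperature, density = NULL, weights = NULL,
                    mc = 0L, t_sigma = 0, rho_sigma = 0) {
  if (is.data.frame(temperature)) {
    df <- temperature
    tn <- intersect(c("T", "temperature"), names(df))[1]
    rn <- intersect(c("rho", "density"), names(df))[1]
    if (is.na(tn) || is.na(rn))
      .stopf("data.frame must have temperature (T) and density (rho) columns")
    temperature <- df[[tn]]; density <- df[[rn]]
  }
  n <- length(temperature)
  if (n < 4L) .stopf("a cubic fit needs at least 4 (T, rho) points, got %d", n)
  if (length(density) != n) .stopf("temperature and density lengths differ")
  if (any(diff(temperature) <= 0)) .stopf("temperatures must be strictly increasing")

  ## center T for conditioning; report coefficients on the raw scale
  t0 <- mean(temperature)
  x <- temperature - t0
  fit <- stats::lm(density ~ x + I(x^2) + I(x^3), weights = weights)
  b <- stats::coef(fit)          # rho = b0 + b1 u + b2 u^2 + b3 u^3, u = T - t0
  V <- suppressWarnings(stats::vcov(fit))  # silent on an exact (noise-free) fit

  ## stationary points of the centered cubic
  roots_u <- if (abs(b[4]) < .Machine$double.eps * max(1, abs(b[3]))) {
    if (b[3] == 0) numeric(0) else -b[2] / (2 * b[3])
  } else {
    disc <- 4 * b[3]^2 - 12 * b[4] * b[2]
    if (disc < 0) numeric(0)
    else (-2 * b[3] + c(1, -1) * sqrt(disc)) / (6 * b[4])
  }
  rng <- range(x)
  is_max <- vapply(roots_u, function(u) (2 * b[3] + 6 * b[4] * u) < 0, TRUE)
  cand <- roots_u[is_max & roots_u >= rng[1] & roots_u <= rng[2]]

  obj <- list(coefficients = .uncenter_cubic(b, t0), vcov_centered = V,
              t0 = t0, fit = fit,
              data = data.frame(T = temperature, rho = density))
  if (!length(cand)) {
    obj$tmd <- NA_real_; obj$density_at_tmd <- NA_real_; obj$tmd_se <- NA_real_
    obj$status <- "no TMD in range"
    return(structure(obj, class = "tmd_fit"))
  }
  u_star <- cand[1]
  ## delta method on f(u,b) = b1 + 2 b2 u + 3 b3 u^2 = 0:
  ## du/db_k = -(df/db_k)/(df/du)
  dfdu <- 2 * b[3] + 6 * b[4] * u_star
  grad <- -c(0, 1, 2 * u_star, 3 * u_star^2) / dfdu
  se <- sqrt(drop(t(grad) %*% V %*% grad))

  obj$tmd <- unname(u_star + t0)
  obj$density_at_tmd <- unname(drop(b[1] + b[2] * u_star + b[3] * u_star^2 + b[4] * u_star^3))
  obj$tmd_se <- se
  obj$status <- "ok"

  if (mc > 0L) {
    tmds <- vapply(seq_len(mc), function(k) {
      tt <- temperature + stats::rnorm(n, 0, t_sigma)
      rr <- density + stats::rnorm(n, 0, rho_sigma)
      o <- order(tt)
      f <- tryCatch(fit_tmd(tt[o], rr[o]), error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$tmd
    }, 0)
    obj$tmd_se_mc <- stats::sd(tmds, na.rm = TRUE)
  }
  structure(obj, class = "tmd_fit")
}

## expand b0 + b1 (T-t0) + b2 (T-t0)^2 + b3 (T-t0)^3 to raw powers of T
.uncenter_cubic <- function(b, t0) {
  c0 <- b[1] - b[2] * t0 + b[3] * t0^2 - b[4] * t0^3
  c1 <- b[2] - 2 * b[3] * t0 + 3 * b[4] * t0^2
  c2 <- b[3] - 3 * b[4] * t0
  c3 <- b[4]
  stats::setNames(c(c0, c1, c2, c3), c("c0", "c1", "c2", "c3"))
}

#' @export
print.tmd_fit <- function(x, ...) {
  cat("Cubic density-maximum fit\n")
  if (x$status != "ok") {
    cat(sprintf("  %s (data span %.1f-%.1f K)\n", x$status,
                min(x$data$T), max(x$data$T)))
  } else {
    cat(sprintf("  TMD = %.2f +/- %.2f K,  rho(TMD) = %.2f kg/m^3\n",
                x$tmd, x$tmd_se, x$density_at_tmd))
    if (!is.null(x$tmd_se_mc))
      cat(sprintf("  Monte-Carlo budget: +/- %.2f K\n", x$tmd_se_mc))
  }
  invisible(x)
}

#' @export
summary.tmd_fit <- function(object, ...) {
  print(object)
  cat("\nCubic coefficients (rho = c0 + c1 T + c2 T^2 + c3 T^3):\n")
  print(object$coefficients)
  cat(sprintf("\nResidual sd: %.4g kg/m^3 over %d points\n",
              stats::sigma(object$fit), nrow(object$data)))
  invisible(object)
}

#' @export
coef.tmd_fit <- function(object, ...) object$coefficients

#' @export
predict.tmd_fit <- function(object, newdata = NULL, ...) {
  Tn <- if (is.null(newdata)) object$data$T
        else if (is.data.frame(newdata)) newdata[[intersect(c("T", "temperature"), names(newdata))[1]]]
        else newdata
  cc <- object$coefficients
  unname(drop(cc[1] + cc[2] * Tn + cc[3] * Tn^2 + cc[4] * Tn^3))
}

#' @export
residuals.tmd_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.tmd_fit <- function(x, ...) {
  plot(x$data$T, x$data$rho, xlab = "T (K)", ylab = expression(rho ~ (kg/m^3)), ...)
  Ts <- seq(min(x$data$T), max(x$data$T), length.out = 200)
  graphics::lines(Ts, predict(x, Ts))
  if (x$status == "ok") graphics::abline(v = x$tmd, lty = 2)
  invisible(x)
}

#' Signed and absolute relative deviation
#'
#' `100 (sim - ref) / ref`, reported with its sign and its magnitude (the
#' sign convention of a printed deviation is occasionally ambiguous, so
#' both are returned).
#'
#' @param sim Simulated value.
#' @param ref Reference (e.g. experimental) value, nonzero.
#' @return Named numeric `c(signed = , magnitude = )`, percent.
#' @examples
#' relative_deviation(257.1, 258.0)  # -0.35 % (NaOH TMD)
#' @export
relative_deviation <- function(sim, ref) {
  if (any(ref == 0)) .stopf("reference value must be nonzero")
  s <- 100 * (sim - ref) / ref
  c(signed = s, magnitude = abs(s))
}

#' Relative average deviation (s-statistic)
#'
#' `s = (1/N) sum_i |X_i - x_i| / X_i`, the mean absolute relative
#' deviation of simulated values `x` from fitted reference values `X`.
#'
#' @param X Reference values (nonzero), e.g. from a fit of experimental
#'   data.
#' @param x Simulated values, same length.
#' @return The s-statistic as a fraction (multiply by 100 for percent).
#' @export
relative_average_deviation <- function(X, x) {
  if (length(X) != length(x))
    .stopf("length mismatch: %d reference vs %d simulated values", length(X), length(x))
  if (any(X == 0)) .stopf("reference values must be nonzero")
  mean(abs(X - x) / X)
}

#' Despretz group-contribution algebra
#'
#' The Despretz constant of a salt decomposes into ionic group
#' contributions, `K_m = nu+ K_m^+ + nu- K_m^-`. `despretz_salt()` composes
#' the salt constant from the ion values; `despretz_anion()` inverts it for
#' the anion contribution given the salt and cation values. Signs are
#' preserved end-to-end (hydroxide contributions are negative).
#'
#' @param K_cation,K_anion,K_salt Despretz constants, K kg/mol.
#' @param nu_p,nu_m Stoichiometric coefficients (>= 1).
#' @return Despretz constant, K kg/mol.
#' @export
despretz_salt <- function(K_cation, K_anion, nu_p = 1, nu_m = 1) {
  if (nu_p < 1 || nu_m < 1) .stopf("stoichiometric coefficients must be >= 1")
  nu_p * K_cation + nu_m * K_anion
}

#' @rdname despretz_salt
#' @export
despretz_anion <- function(K_salt, K_cation, nu_p = 1, nu_m = 1) {
  if (nu_p < 1 || nu_m < 1) .stopf("stoichiometric coefficients must be >= 1")
  (K_salt - nu_p * K_cation) / nu_m
}

#' Despretz constant from TMD shifts
#'
#' `K_m = lim_{m -> 0} Delta/m` with `Delta = TMD_solution - TMD_water`:
#' estimated as the slope of a through-origin (weighted) least-squares fit
#' of the shifts against molality. A single dilute point returns
#' `Delta/m` directly.
#'
#' @param m Molalities, mol/kg (> 0).
#' @param delta TMD shifts, K.
#' @param weights Optional weights.
#' @return List: `K_m` (K kg/mol) and its standard error `se` (`NA` for a
#'   single point).
#' @export
despretz_from_shifts <- function(m, delta, weights = NULL) {
  if (length(m) != length(delta)) .stopf("m and delta lengths differ")
  if (any(m <= 0)) .stopf("molalities must be > 0 (the m = 0 point carries no shift information)")
  if (length(m) == 1L) return(list(K_m = delta / m, se = NA_real_))
  fit <- stats::lm(delta ~ 0 + m, weights = weights)
  list(K_m = unname(stats::coef(fit)[1]),
       se = unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[1]))
}
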