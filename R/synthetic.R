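# Synthetic fixtures with analytically known ground truth. These are
# truth-bearing test inputs, not imitations of real water: each generator
# documents the exact value its matching estimator must recover. Every
# generator is deterministic for a fixed seed.

#' Ideal-gas (uniform) point fixture
#'
#' Uniformly random points in a periodic box: the pair correlation is
#' exactly 1 at all distances and the coordination number within r is
#' `(4/3) pi r^3 rho`.
#'
#' @param n Number of points per frame.
#' @param box Cubic box edge, A (or length-3 vector).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param type Atom-type label given to every site.
#' @return An `"md_traj"`.
#' @export
make_ideal_gas <- function(n, box = 30, n_frames = 1L, seed = 1, type = "IG") {
  if (length(box) == 1L) box <- rep(box, 3)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(k) {
    xyz <- cbind(stats::runif(n) * box[1], stats::runif(n) * box[2],
                 stats::runif(n) * box[3])
    md_config(box, xyz, rep(type, n), rep(type, n), seq_len(n), rep(type, n))
  })
  md_traj(frames)
}

#' Delta-shell coordination fixture
#'
#' Centers on a sparse grid, each surrounded by satellites at exactly
#' radius `a` in random directions: the center-satellite coordination
#' number for any `r_min > a` (below the inter-center spacing) is exactly
#' `k`. Fractional `k` is realized as a floor/ceiling mixture whose mean
#' satellite count equals `k` exactly (e.g. k = 5.5 from half 5s and half
#' 6s), so `n_centers * k` must be an integer.
#'
#' @param k Mean satellites per center (may be fractional).
#' @param a Shell radius, A.
#' @param n_centers Number of centers.
#' @param seed RNG seed.
#' @param spacing Center grid spacing, A (default `6 a`).
#' @return An `"md_traj"` with types `"C"` (centers) and `"S"` (satellites).
#' @export
make_delta_shell <- function(k, a, n_centers = 64L, seed = 1, spacing = NULL) {
  if (is.null(spacing)) spacing <- 6 * a
  n_hi <- .round_half_away(n_centers * (k - floor(k)))
  if (abs(n_hi - n_centers * (k - floor(k))) > 1e-9)
    .stopf("n_centers * fractional part of k must be an integer (got %g * %g)",
           n_centers, k - floor(k))
  counts <- c(rep(floor(k) + 1L, n_hi), rep(floor(k), n_centers - n_hi))
  side <- ceiling(n_centers^(1 / 3))
  grid <- as.matrix(expand.grid(0:(side - 1), 0:(side - 1), 0:(side - 1)))[seq_len(n_centers), , drop = FALSE]
  centers <- (grid + 0.5) * spacing
  box <- rep(side * spacing, 3)
  set.seed(seed)
  xyz <- centers; site <- rep("C", n_centers)
  for (i in seq_len(n_centers)) {
    m <- counts[i]
    if (m == 0) next
    u <- matrix(stats::rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    xyz <- rbind(xyz, sweep(u * a, 2, centers[i, ], `+`))
    site <- c(site, rep("S", m))
  }
  n <- nrow(xyz)
  md_traj(list(md_config(box, xyz, site, site, seq_len(n), site)))
}

#' Synthetic density-temperature series with a known TMD
#'
#' `rho(T) = rho_max - curvature (T - tmd)^2 + skew (T - tmd)^3` plus
#' Gaussian noise: the stationary point (and hence the fitted TMD) is
#' exactly `tmd` in the noise-free limit.
#'
#' @param tmd True temperature of maximum density, K.
#' @param curvature Quadratic coefficient, kg/m^3/K^2 (> 0).
#' @param t_range Length-2 temperature range, K (should contain `tmd`).
#' @param n Number of points.
#' @param noise_sd Gaussian noise, kg/m^3.
#' @param seed RNG seed.
#' @param rho_max Density at the maximum, kg/m^3.
#' @param skew Cubic coefficient, kg/m^3/K^3 (small, makes the series
#'   genuinely cubic).
#' @return `data.frame` with columns `T`, `rho`.
#' @export
make_cubic_density <- function(tmd, curvature = 0.007, t_range = c(tmd - 20, tmd + 20),
                               n = 20L, noise_sd = 0.05, seed = 1,
                               rho_max = 1000, skew = -5e-5) {
  if (curvature <= 0) .stopf("curvature must be > 0 for a density maximum")
  set.seed(seed)
  Ts <- seq(t_range[1], t_range[2], length.out = n)
  rho <- rho_max - curvature * (Ts - tmd)^2 + skew * (Ts - tmd)^3 +
    stats::rnorm(n, 0, noise_sd)
  data.frame(T = Ts, rho = rho)
}

#' Ornstein-Uhlenbeck pressure-tensor fixture
#'
#' Independent stationary OU processes per channel with variance `sigma2`
#' and correlation time `tau`: the autocorrelation is
#' `sigma2 exp(-t/tau)`, so the Green-Kubo integral per channel is exactly
#' `sigma2 * tau` (in bar^2 ps), and the viscosity estimate converges to
#' `V/(k_B T) sigma2 tau` (unit-converted).
#'
#' @param sigma2 Stationary variance, bar^2.
#' @param tau Correlation time, ps.
#' @param dt Sampling interval, ps.
#' @param n Number of samples.
#' @param seed RNG seed.
#' @param channels Channel names to generate.
#' @return A `"ptensor_series"`.
#' @export
make_ou_tensor <- function(sigma2, tau, dt, n, seed = 1,
                           channels = c("Pxy", "Pxz", "Pyz")) {
  set.seed(seed)
  phi <- exp(-dt / tau)
  innov_sd <- sqrt(sigma2 * (1 - phi^2))
  args <- list(time = (0:(n - 1L)) * dt)
  for (ch in channels) {
    if (sigma2 > 0) {
      ## stationary start, then exact AR(1) discretization of the OU process
      x0 <- stats::rnorm(1, 0, sqrt(sigma2))
      x <- as.numeric(stats::filter(c(x0, stats::rnorm(n - 1L, 0, innov_sd)),
                                    phi, method = "recursive"))
    } else x <- rep(0, n)
    args[[ch]] <- x
  }
  do.call(ptensor_series, args)
}

#' Random-walk MSD fixture
#'
#' Ensemble of 3D Gaussian random walks with per-step displacement
#' variance `2 D dt` per dimension, so the ensemble MSD grows as `6 D t`
#' exactly in expectation.
#'
#' @param D Diffusion coefficient, m^2/s.
#' @param dt Time step, ps.
#' @param n_steps Steps per walker.
#' @param n_walkers Ensemble size.
#' @param seed RNG seed.
#' @return `data.frame` with columns `time` (ps) and `msd` (A^2).
#' @export
make_random_walk <- function(D, dt, n_steps, n_walkers = 200L, seed = 1) {
  set.seed(seed)
  D_A2ps <- D / .A2_PS_TO_M2_S
  step_sd <- sqrt(2 * D_A2ps * dt)
  msd <- numeric(n_steps + 1L)
  for (w in seq_len(n_walkers)) {
    steps <- matrix(stats::rnorm(3 * n_steps, 0, step_sd), n_steps, 3)
    pos <- apply(steps, 2, cumsum)
    msd <- msd + c(0, rowSums(pos^2))
  }
  data.frame(time = (0:n_steps) * dt, msd = msd / n_walkers)
}

#' Step density profile with a known surface excess
#'
#' Solute profile equal to `rho_bulk` in the liquid, zero in the vapor,
#' with an optional rectangular depletion (or enhancement) layer of width
#' `layer_width` and density change `layer_delta` just inside the
#' interface: the Gibbs surface excess relative to the dividing surface at
#' `z_gds` is exactly `layer_delta * layer_width` (in A^-2; the estimator
#' reports nm^-2).
#'
#' @param rho_bulk Bulk solute density, A^-3.
#' @param z_gds Dividing-surface position, A.
#' @param z_max Profile extent, A.
#' @param dz Grid spacing, A.
#' @param layer_width Depletion-layer width, A.
#' @param layer_delta Density change in the layer, A^-3 (negative =
#'   depletion).
#' @return List: `z`, `rho`, and the exact `gamma_true` in nm^-2.
#' @export
make_step_profile <- function(rho_bulk, z_gds, z_max = 2 * z_gds, dz = 0.1,
                              layer_width = 0, layer_delta = 0) {
  z <- seq(0, z_max, by = dz)
  rho <- ifelse(z <= z_gds, rho_bulk, 0)
  if (layer_width > 0) {
    lay <- z > (z_gds - layer_width) & z <= z_gds
    rho[lay] <- rho[lay] + layer_delta
  }
  list(z = z, rho = rho, gamma_true = layer_delta * layer_width * 100)
}

#' Grid of water dimers straddling the hydrogen-bond criteria
#'
#' Isolated donor-acceptor oxygen pairs laid out on a widely spaced grid,
#' with prescribed O...O distances and donor angles, for brute-force
#' validation of the geometric H-bond criterion.
#'
#' @param distances O...O distances, A.
#' @param angles Donor H-O...O angles, degrees.
#' @param d_oh Donor O-H bond length, A.
#' @return List: `config` (an `"md_config"` of two-site "water" molecules,
#'   donor H placed at the requested angle) and `geometry` (data.frame of
#'   the distance/angle of every dimer).
#' @export
make_dimer_grid <- function(distances = seq(2.6, 3.8, by = 0.2),
                            angles = seq(2.5, 57.5, by = 5), d_oh = 0.9572) {
  combos <- expand.grid(r = distances, ang = angles)
  n <- nrow(combos)
  spacing <- 25
  side <- ceiling(sqrt(n))
  xyz <- NULL; site <- type <- mol_name <- character(0); mol_id <- integer(0)
  for (i in seq_len(n)) {
    gx <- ((i - 1) %% side) * spacing + spacing / 2
    gy <- ((i - 1) %/% side) * spacing + spacing / 2
    o_d <- c(gx, gy, 10)
    o_a <- o_d + c(0, 0, combos$r[i])                    # acceptor along +z
    th <- combos$ang[i] * pi / 180
    h_d <- o_d + d_oh * c(sin(th), 0, cos(th))           # H at the set angle
    xyz <- rbind(xyz, o_d, h_d, o_a)
    site <- c(site, "OW", "HW1", "OW")
    type <- c(type, "O_w", "H_w", "O_w")
    mol_id <- c(mol_id, 2L * i - 1L, 2L * i - 1L, 2L * i)
    mol_name <- c(mol_name, "SOL", "SOL", "SOL")
  }
  box <- c(side * spacing, side * spacing, 40)
  list(config = md_config(box, xyz, site, type, mol_id, mol_name),
       geometry = combos)
}
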