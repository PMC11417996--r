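# Pair-potential evaluation for small periodic systems.
#
# U = 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ] + k_e q_i q_j / r
# with eps/sig resolved through the registry (Lorentz-Berthelot plus stored
# deviations). Electrostatics: sharp-cutoff sum or direct Ewald summation
# (real + reciprocal + self + intramolecular-exclusion correction +
# neutralizing background), summed to convergence. Analytic LJ tail
# corrections follow the standard multicomponent form. Intramolecular pairs
# never interact (rigid templates carry no internal energy terms).

#' Energy of a single site pair
#'
#' @param registry An `"ff_registry"`.
#' @param a,b Atom-type names.
#' @param r Separation, A (> 0). Vectorized over `r`.
#' @return Energy in kJ/mol (LJ + unscreened Coulomb).
#' @examples
#' reg <- default_parameter_set()
#' pair_energy(reg, "O_oh", "O_oh", 3.40)  # LJ zero-crossing + ion-ion Coulomb
#' @export
pair_energy <- function(registry, a, b, r) {
  if (any(!is.finite(r)) || any(r <= 0)) .stopf("pair separation must be > 0")
  pp <- resolve_pair(registry, a, b)
  eps <- pp$epsilon_over_kB * .kB_kJmol
  qq <- registry$types[[a]]$charge * registry$types[[b]]$charge
  sr6 <- (pp$sigma / r)^6
  4 * eps * (sr6^2 - sr6) + .ke_kJmolA * qq / r
}

## per-site parameter lookup tables for a configuration
.site_tables <- function(config, registry) {
  utypes <- unique(config$type)
  for (t in utypes) if (is.null(registry$types[[t]]))
    .stopf("configuration contains unregistered atom type '%s'", t)
  q <- vapply(config$type, function(t) registry$types[[t]]$charge, 0)
  nt <- length(utypes)
  SIG <- EPS <- matrix(0, nt, nt, dimnames = list(utypes, utypes))
  for (i in seq_len(nt)) for (j in i:nt) {
    pp <- resolve_pair(registry, utypes[i], utypes[j])
    SIG[i, j] <- SIG[j, i] <- pp$sigma
    EPS[i, j] <- EPS[j, i] <- pp$epsilon_over_kB * .kB_kJmol
  }
  list(q = unname(q), tidx = match(config$type, utypes), SIG = SIG, EPS = EPS,
       utypes = utypes)
}

.pair_index <- function(n) {
  ij <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  list(i = ij[, 1], j = ij[, 2])
}

.min_image <- function(d, L) {
  if (is.matrix(d)) d - sweep(round(sweep(d, 2, L, `/`)), 2, L, `*`)
  else d - round(d / L) * L
}

## standard multicomponent LJ tail correction, kJ/mol
.lj_tail <- function(config, st, cutoff) {
  ## sites participating in any LJ interaction
  active <- which(vapply(seq_along(st$tidx), function(k) any(st$EPS[st$tidx[k], ] > 0), TRUE))
  if (!length(active)) return(0)
  V <- prod(config$box)
  counts <- table(factor(st$utypes[st$tidx[active]], levels = st$utypes))
  N <- sum(counts)
  x <- as.numeric(counts) / N
  acc <- 0
  for (i in seq_along(st$utypes)) for (j in seq_along(st$utypes)) {
    eps <- st$EPS[i, j]; if (eps == 0) next
    sig <- st$SIG[i, j]
    sr3 <- (sig / cutoff)^3
    acc <- acc + x[i] * x[j] * eps * sig^3 * (sr3^3 / 3 - sr3)
  }
  (8 * pi / 3) * (N^2 / V) * acc
}

## Ewald k-space setup: alpha and integer k ranges from target accuracy
.ewald_setup <- function(box, cutoff, alpha, accuracy) {
  if (is.null(alpha)) alpha <- 3.5 / cutoff
  kcut <- 2 * alpha * sqrt(log(1 / accuracy))
  nmax <- ceiling(kcut * box / (2 * pi))
  grid <- as.matrix(expand.grid(-nmax[1]:nmax[1], -nmax[2]:nmax[2], -nmax[3]:nmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  K <- sweep(grid, 2, 2 * pi / box, `*`)
  k2 <- rowSums(K^2)
  keep <- k2 <= kcut^2
  list(alpha = alpha, K = K[keep, , drop = FALSE], k2 = k2[keep])
}

#' Total potential energy of a periodic configuration
#'
#' Minimum-image Lennard-Jones with sharp cutoff and analytic tail
#' correction, plus Coulomb electrostatics by direct Ewald summation
#' (default) or plain cutoff truncation. Intramolecular pairs are excluded
#' throughout. In Ewald mode the reported reciprocal part also carries the
#' self, intramolecular-exclusion and net-charge background terms, so the
#' breakdown always sums to the total.
#'
#' @param config An `"md_config"`.
#' @param registry An `"ff_registry"`.
#' @param cutoff Real-space cutoff, A; must not exceed half the shortest
#'   box edge.
#' @param electrostatics `"ewald"` or `"cutoff"`.
#' @param alpha Ewald splitting parameter (1/A); default `3.5/cutoff`.
#' @param accuracy Target relative accuracy of the reciprocal sum.
#' @param tail_correction Apply the LJ tail correction?
#' @return List of class `"energy_breakdown"`: `lj`, `coulomb_real`,
#'   `coulomb_recip`, `lj_tail`, `total`, all kJ/mol.
#' @export
total_energy <- function(config, registry = default_parameter_set(), cutoff = 10,
                         electrostatics = c("ewald", "cutoff"), alpha = NULL,
                         accuracy = 1e-8, tail_correction = TRUE) {
  stopifnot(inherits(config, "md_config"))
  electrostatics <- match.arg(electrostatics)
  if (cutoff > min(config$box) / 2 + 1e-9)
    .stopf("cutoff %.3f A exceeds half the shortest box edge (%.3f A)",
           cutoff, min(config$box) / 2)
  st <- .site_tables(config, registry)
  n <- nrow(config$xyz)
  px <- .pair_index(n)
  inter <- config$mol_id[px$i] != config$mol_id[px$j]
  i <- px$i[inter]; j <- px$j[inter]
  d <- .min_image(config$xyz[j, , drop = FALSE] - config$xyz[i, , drop = FALSE], config$box)
  r <- sqrt(rowSums(d^2))
  within <- r < cutoff
  qq <- st$q[i] * st$q[j]

  eps <- st$EPS[cbind(st$tidx[i], st$tidx[j])]
  sig <- st$SIG[cbind(st$tidx[i], st$tidx[j])]
  sel <- within & eps > 0
  sr6 <- (sig[sel] / r[sel])^6
  e_lj <- sum(4 * eps[sel] * (sr6^2 - sr6))
  e_tail <- if (tail_correction) .lj_tail(config, st, cutoff) else 0

  if (electrostatics == "cutoff") {
    e_real <- .ke_kJmolA * sum(qq[within] / r[within])
    e_recip <- 0
  } else {
    ew <- .ewald_setup(config$box, cutoff, alpha, accuracy)
    a <- ew$alpha
    e_real <- .ke_kJmolA * sum(qq[within] * .erfc(a * r[within]) / r[within])
    V <- prod(config$box)
    Ak <- exp(-ew$k2 / (4 * a^2)) / ew$k2
    phase <- config$xyz %*% t(ew$K)
    ReS <- as.numeric(st$q %*% cos(phase))
    ImS <- as.numeric(st$q %*% sin(phase))
    e_k <- .ke_kJmolA * (2 * pi / V) * sum(Ak * (ReS^2 + ImS^2))
    e_self <- -.ke_kJmolA * a / sqrt(pi) * sum(st$q^2)
    ## intramolecular pairs: remove the full interaction the k-sum added
    ii <- px$i[!inter]; jj <- px$j[!inter]
    e_excl <- 0
    if (length(ii)) {
      dm <- .min_image(config$xyz[jj, , drop = FALSE] - config$xyz[ii, , drop = FALSE], config$box)
      rm_ <- sqrt(rowSums(dm^2))
      e_excl <- -.ke_kJmolA * sum(st$q[ii] * st$q[jj] * .erf(a * rm_) / rm_)
    }
    e_bg <- -.ke_kJmolA * pi / (2 * a^2 * V) * sum(st$q)^2
    e_recip <- e_k + e_self + e_excl + e_bg
  }
  structure(list(lj = e_lj, coulomb_real = e_real, coulomb_recip = e_recip,
                 lj_tail = e_tail, total = e_lj + e_real + e_recip + e_tail),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (kJ/mol)\n")
  for (f in c("lj", "lj_tail", "coulomb_real", "coulomb_recip", "total"))
    cat(sprintf("  %-14s %16.6f\n", f, x[[f]]))
  invisible(x)
}

#' Per-site forces
#'
#' Analytic gradient of [total_energy()] (the LJ tail is
#' configuration-independent and contributes no force). The net force on
#' the system vanishes to numerical precision.
#'
#' @inheritParams total_energy
#' @return n x 3 matrix of forces, kJ/mol/A.
#' @export
forces <- function(config, registry = default_parameter_set(), cutoff = 10,
                   electrostatics = c("ewald", "cutoff"), alpha = NULL,
                   accuracy = 1e-8) {
  stopifnot(inherits(config, "md_config"))
  electrostatics <- match.arg(electrostatics)
  if (cutoff > min(config$box) / 2 + 1e-9)
    .stopf("cutoff %.3f A exceeds half the shortest box edge (%.3f A)",
           cutoff, min(config$box) / 2)
  st <- .site_tables(config, registry)
  n <- nrow(config$xyz)
  F <- matrix(0, n, 3)
  px <- .pair_index(n)
  inter <- config$mol_id[px$i] != config$mol_id[px$j]
  i <- px$i[inter]; j <- px$j[inter]
  d <- .min_image(config$xyz[i, , drop = FALSE] - config$xyz[j, , drop = FALSE], config$box)
  r <- sqrt(rowSums(d^2))
  within <- r < cutoff
  qq <- st$q[i] * st$q[j]
  eps <- st$EPS[cbind(st$tidx[i], st$tidx[j])]
  sig <- st$SIG[cbind(st$tidx[i], st$tidx[j])]

  ## -dU/dr for each interacting pair (positive = repulsive)
  fmag <- numeric(length(r))
  sel <- within & eps > 0
  sr6 <- (sig[sel] / r[sel])^6
  fmag[sel] <- fmag[sel] + 24 * eps[sel] / r[sel] * (2 * sr6^2 - sr6)
  if (electrostatics == "cutoff") {
    fmag[within] <- fmag[within] + .ke_kJmolA * qq[within] / r[within]^2
  } else {
    ew <- .ewald_setup(config$box, cutoff, alpha, accuracy)
    a <- ew$alpha
    w <- within
    fmag[w] <- fmag[w] + .ke_kJmolA * qq[w] *
      (.erfc(a * r[w]) / r[w]^2 + 2 * a / sqrt(pi) * exp(-a^2 * r[w]^2) / r[w])
  }
  fv <- d * (fmag / r)
  ## accumulate equal-and-opposite pair forces
  for (dd in 1:3) {
    s <- rowsum(fv[, dd], group = i)
    F[as.integer(rownames(s)), dd] <- F[as.integer(rownames(s)), dd] + s
    s <- rowsum(-fv[, dd], group = j)
    F[as.integer(rownames(s)), dd] <- F[as.integer(rownames(s)), dd] + s
  }

  if (electrostatics == "ewald") {
    V <- prod(config$box)
    Ak <- exp(-ew$k2 / (4 * a^2)) / ew$k2
    phase <- config$xyz %*% t(ew$K)
    Cp <- cos(phase); Sp <- sin(phase)
    ReS <- as.numeric(st$q %*% Cp)
    ImS <- as.numeric(st$q %*% Sp)
    pref <- .ke_kJmolA * 4 * pi / V
    for (dd in 1:3) {
      w1 <- Ak * ew$K[, dd] * ReS
      w2 <- Ak * ew$K[, dd] * ImS
      F[, dd] <- F[, dd] + pref * st$q * (Sp %*% w1 - Cp %*% w2)
    }
    ## intramolecular exclusion correction forces
    ii <- px$i[!inter]; jj <- px$j[!inter]
    if (length(ii)) {
      dm <- .min_image(config$xyz[ii, , drop = FALSE] - config$xyz[jj, , drop = FALSE], config$box)
      rm_ <- sqrt(rowSums(dm^2))
      qqm <- st$q[ii] * st$q[jj]
      gm <- -.ke_kJmolA * qqm *
        (.erf(a * rm_) / rm_^2 - 2 * a / sqrt(pi) * exp(-a^2 * rm_^2) / rm_)
      gv <- dm * (gm / rm_)
      for (dd in 1:3) {
        s <- rowsum(gv[, dd], group = ii)
        F[as.integer(rownames(s)), dd] <- F[as.integer(rownames(s)), dd] + s
        s <- rowsum(-gv[, dd], group = jj)
        F[as.integer(rownames(s)), dd] <- F[as.integer(rownames(s)), dd] + s
      }
    }
  }
  F
}
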