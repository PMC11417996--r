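# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately avoid the package's own computational paths.

## maximum coordinate difference modulo the periodic cell
mi_maxdiff <- function(a, b, L) {
  d <- a - b
  d <- d - sweep(round(sweep(d, 2, L, `/`)), 2, L, `*`)
  max(abs(d))
}

## brute-force LJ energy: all pairs over 3^3 periodic images, cutoff r_b
brute_lj_images <- function(xyz, box, sigma, eps_kJ, r_b) {
  n <- nrow(xyz)
  img <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (k in seq_len(nrow(img))) {
      if (i == j && all(img[k, ] == 0)) next
      d <- xyz[j, ] + img[k, ] * box - xyz[i, ]
      r <- sqrt(sum(d^2))
      if (r < r_b) { s6 <- (sigma / r)^6; e <- e + 4 * eps_kJ * (s6^2 - s6) / 2 }
    }
  }
  e
}

## brute-force pair count within r_cut (minimum image, unordered pairs
## between two site index sets)
brute_pair_count <- function(xyz, box, ia, ib, r_cut) {
  cnt <- 0
  for (a in ia) for (b in ib) {
    if (a == b) next
    d <- xyz[b, ] - xyz[a, ]
    d <- d - round(d / box) * box
    if (sqrt(sum(d^2)) <= r_cut) cnt <- cnt + 1
  }
  cnt
}

## brute-force geometric H-bond check from raw coordinates
brute_hbond_count <- function(config, r_cut, angle_cut, convention = "HOO") {
  mi <- function(v) v - round(v / config$box) * config$box
  ox <- which(config$type %in% c("O_w", "O_oh"))
  total <- 0
  for (o in ox) {
    hs <- which(config$mol_id == config$mol_id[o] & config$type %in% c("H_w", "H_oh"))
    for (h in hs) for (a in ox[config$mol_id[ox] != config$mol_id[o]]) {
      doa <- mi(config$xyz[a, ] - config$xyz[o, ])
      r <- sqrt(sum(doa^2))
      if (r > r_cut) next
      if (convention == "HOO") {
        u <- mi(config$xyz[h, ] - config$xyz[o, ])
        ang <- acos(min(1, max(-1, sum(u * doa) / sqrt(sum(u^2)) / r))) * 180 / pi
        if (ang <= angle_cut) total <- total + 1
      } else {
        v1 <- mi(config$xyz[o, ] - config$xyz[h, ])
        v2 <- mi(config$xyz[a, ] - config$xyz[h, ])
        ang <- acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= 180 - angle_cut) total <- total + 1
      }
    }
  }
  as.integer(total)
}

## small NaOH solution box reused across energy tests (20 molecules)
small_solution_box <- function(seed = 3) {
  build_box(molality_to_counts(2, 18), density_guess = 0.8, seed = seed)
}

## registry with a single neutral LJ species, for LJ-only oracles
lj_only_registry <- function(sigma = 3, eps_K = 50) {
  load_parameter_set(list(atom_types = list(
    X = list(charge = 0, sigma = sigma, epsilon_over_kB = eps_K, mass = 1))))
}

## registry of +-1 point charges on a rocksalt lattice (Madelung oracle)
rocksalt_config <- function(n_cells = 4, a = 2) {
  g <- as.matrix(expand.grid(0:(n_cells - 1), 0:(n_cells - 1), 0:(n_cells - 1)))
  q <- (-1)^(g[, 1] + g[, 2] + g[, 3])
  types <- ifelse(q > 0, "P", "Mi")
  reg <- load_parameter_set(list(atom_types = list(
    P = list(charge = 1, sigma = 1, epsilon_over_kB = 0, mass = 1),
    Mi = list(charge = -1, sigma = 1, epsilon_over_kB = 0, mass = 1))))
  cfg <- md_config(rep(n_cells * a, 3), g * a, types, types,
                   seq_len(nrow(g)), types)
  list(config = cfg, registry = reg, a = a)
}
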