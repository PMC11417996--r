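# Configuration/trajectory containers and the molality-based box builder.

#' Create a configuration
#'
#' A configuration is a periodic orthorhombic cell plus per-site
#' coordinates and labels. Units: A throughout.
#'
#' @param box Length-3 box edge lengths (A).
#' @param xyz n x 3 coordinate matrix (A).
#' @param site Character vector of site names (e.g. `"OW"`).
#' @param type Character vector of atom-type names (e.g. `"O_w"`).
#' @param mol_id Integer vector, molecule index per site.
#' @param mol_name Character vector, molecule (residue) name per site.
#' @return Object of class `"md_config"`.
#' @export
md_config <- function(box, xyz, site, type, mol_id, mol_name) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    .stopf("box must be 3 positive edge lengths")
  stopifnot(ncol(xyz) == 3L, length(site) == n, length(type) == n,
            length(mol_id) == n, length(mol_name) == n)
  structure(list(box = as.numeric(box), xyz = unname(xyz),
                 site = as.character(site), type = as.character(type),
                 mol_id = as.integer(mol_id), mol_name = as.character(mol_name)),
            class = "md_config")
}

#' @export
print.md_config <- function(x, ...) {
  cat(sprintf("<md_config> %d sites, %d molecules, box %.3f x %.3f x %.3f A\n",
              nrow(x$xyz), length(unique(x$mol_id)), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Create a trajectory
#'
#' An ordered list of configurations with constant site count and species
#' ordering, plus optional per-frame channels.
#'
#' @param frames List of `"md_config"` objects.
#' @param temperature,pressure Optional per-frame scalars (K, bar).
#' @return Object of class `"md_traj"`.
#' @export
md_traj <- function(frames, temperature = NULL, pressure = NULL) {
  if (!length(frames)) .stopf("trajectory needs at least one frame")
  n0 <- nrow(frames[[1]]$xyz); t0 <- frames[[1]]$type
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!inherits(f, "md_config")) .stopf("frame %d is not an md_config", k)
    if (nrow(f$xyz) != n0 || !identical(f$type, t0))
      .stopf("frame %d breaks constant site count/ordering", k)
  }
  structure(list(frames = frames, temperature = temperature, pressure = pressure),
            class = "md_traj")
}

#' @export
print.md_traj <- function(x, ...) {
  cat(sprintf("<md_traj> %d frames, %d sites\n",
              length(x$frames), nrow(x$frames[[1]]$xyz)))
  invisible(x)
}

#' @export
length.md_traj <- function(x) length(x$frames)

.as_traj <- function(x) {
  if (inherits(x, "md_traj")) x else if (inherits(x, "md_config")) md_traj(list(x))
  else .stopf("expected an md_config or md_traj")
}

#' Wrap all sites into the primary cell
#'
#' Periodic wrapping `x - L*floor(x/L)` per component; idempotent.
#'
#' @param config An `"md_config"`.
#' @return The wrapped configuration.
#' @export
wrap_config <- function(config) {
  stopifnot(inherits(config, "md_config"))
  L <- config$box
  config$xyz <- config$xyz - sweep(floor(sweep(config$xyz, 2, L, `/`)), 2, L, `*`)
  config
}

#' Convert a target molality into integer ion-pair counts
#'
#' For a 1:1 hydroxide MOH in `n_water` water molecules, the number of ion
#' pairs is `round(m * M_water * n_water)` with `M_water = 0.018015 kg/mol`
#' (ties rounded half away from zero). Electroneutrality of the scaled-
#' charge model fixes `n_cation = n_anion`.
#'
#' @param m Target molality, mol/kg (>= 0).
#' @param n_water Number of water molecules (> 0). The reference
#'   simulations of this model family use 555.
#' @param salt One of `"LiOH"`, `"NaOH"`, `"KOH"`.
#' @return Object of class `"composition"`: `n_water`, `n_cation`,
#'   `n_anion`, `salt`, `molality` (requested) and `molality_achieved`.
#' @examples
#' molality_to_counts(1, 555)$n_anion   # 10 ion pairs
#' molality_to_counts(16, 555)$n_anion  # 160 ion pairs
#' @export
molality_to_counts <- function(m, n_water = 555, salt = c("NaOH", "LiOH", "KOH")) {
  salt <- match.arg(salt)
  if (!is.finite(m) || m < 0) .stopf("molality must be >= 0, got %g", m)
  if (!is.finite(n_water) || n_water <= 0) .stopf("n_water must be > 0")
  n_pairs <- as.integer(.round_half_away(m * .M_WATER_KG * n_water))
  structure(list(n_water = as.integer(n_water), n_cation = n_pairs,
                 n_anion = n_pairs, salt = salt, molality = m,
                 molality_achieved = n_pairs / (.M_WATER_KG * n_water)),
            class = "composition")
}

#' Molality achieved by an integer composition
#'
#' @param comp A `"composition"` object.
#' @return Molality in mol/kg.
#' @export
counts_to_molality <- function(comp) {
  stopifnot(inherits(comp, "composition"))
  comp$n_anion / (.M_WATER_KG * comp$n_water)
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> %s: %d waters + %d ion pairs (requested %.4g, achieved %.4g mol/kg)\n",
              x$salt, x$n_water, x$n_anion, x$molality, x$molality_achieved))
  invisible(x)
}

.salt_cation <- function(salt) c(LiOH = "Li", NaOH = "Na", KOH = "K")[[salt]]

#' Build a solution box by random insertion
#'
#' Inserts rigid templates (water, hydroxide, cations) at random poses into
#' an orthorhombic cell sized from `density_guess`, rejecting any insertion
#' that brings two intermolecular sites closer than
#' `overlap_factor * sigma_ij` (Lorentz-Berthelot sigma from the registry).
#' Deterministic for a fixed `seed`.
#'
#' @param comp A `"composition"` (see [molality_to_counts()]).
#' @param density_guess Target mass density, g/cm^3.
#' @param seed Integer RNG seed.
#' @param registry Force-field registry; default [default_parameter_set()].
#' @param overlap_factor Hard-core rejection threshold as a fraction of
#'   sigma_ij (default 0.8).
#' @param max_attempts Insertion attempts per molecule before giving up.
#' @return An `"md_config"`.
#' @export
build_box <- function(comp, density_guess = 1.0, seed = 1,
                      registry = default_parameter_set(),
                      overlap_factor = 0.8, max_attempts = 500L) {
  stopifnot(inherits(comp, "composition"))
  if (!is.finite(density_guess) || density_guess <= 0)
    .stopf("density_guess must be > 0")
  water <- tip4p2005_template(); oh <- hydroxide_template()
  cat_t <- ion_template(.salt_cation(comp$salt))
  templates <- c(rep(list(water), comp$n_water),
                 rep(list(cat_t), comp$n_cation),
                 rep(list(oh), comp$n_anion))
  mass_g <- 0
  for (tp in templates)
    mass_g <- mass_g + sum(vapply(tp$sites$type,
                                  function(t) registry$types[[t]]$mass, 0))
  vol_A3 <- mass_g / .NA_mol / density_guess * 1e24  # g / (g/cm3) -> cm3 -> A3
  L <- rep(vol_A3^(1 / 3), 3)

  type_names <- names(registry$types)
  sig <- vapply(type_names, function(t) registry$types[[t]]$sigma, 0)
  ## pairwise hard-core thresholds (LB arithmetic mean), skip massless M sites
  thr <- overlap_factor * outer(sig, sig, `+`) / 2
  is_virtual <- vapply(type_names, function(t) registry$types[[t]]$mass == 0, TRUE)
  thr[is_virtual, ] <- 0; thr[, is_virtual] <- 0
  dimnames(thr) <- list(type_names, type_names)

  set.seed(seed)
  xyz <- matrix(0, 0, 3); site <- type <- mol_name <- character(0); mol_id <- integer(0)
  for (im in seq_along(templates)) {
    tp <- templates[[im]]
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      pos <- stats::runif(3) * L
      cand <- place_template(tp, pos, .random_rotation())
      if (nrow(xyz)) {
        tmin <- thr[tp$sites$type, type, drop = FALSE]
        ok <- TRUE
        for (s in seq_len(nrow(cand))) {
          d <- sweep(xyz, 2, cand[s, ], `-`)
          d <- d - sweep(round(sweep(d, 2, L, `/`)), 2, L, `*`)
          if (any(rowSums(d^2) < tmin[s, ]^2)) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      xyz <- rbind(xyz, cand)
      site <- c(site, tp$sites$site); type <- c(type, tp$sites$type)
      mol_id <- c(mol_id, rep(im, nrow(cand)))
      mol_name <- c(mol_name, rep(tp$name, nrow(cand)))
      placed <- TRUE
      break
    }
    if (!placed) {
      vdw_vol <- sum((4 / 3) * pi * (sig[type] / 2)^3)
      .stopf("insertion failed for molecule %d/%d after %d attempts (packing fraction so far: %.3f)",
             im, length(templates), max_attempts, vdw_vol / prod(L))
    }
  }
  wrap_config(md_config(L, xyz, site, type, mol_id, mol_name))
}
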