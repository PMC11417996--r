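# Force-field registry: atom types, charge scaling, pair combination.
#
# The shipped defaults are the rigid hydroxide model for TIP4P/2005-type
# water: ADCH-derived charges scaled by the electronic-continuum factor
# 0.85, Lennard-Jones self terms for O_oh/H_oh, the TIP4P/2005 water
# constants, and Madrid-2019 alkali cations (+0.85 e). Cross terms default
# to Lorentz-Berthelot and may be overridden (flagged n-LB) in config.

#' Create an atom type
#'
#' An atom type carries the per-site nonbonded parameters: partial charge,
#' Lennard-Jones self parameters and mass. Units follow the package
#' convention: charge in elementary charges, `sigma` in angstrom, `epsilon`
#' as epsilon/k_B in kelvin, mass in g/mol.
#'
#' @param name Atom-type label (e.g. `"O_oh"`).
#' @param charge Partial charge, e.
#' @param sigma LJ diameter, A. Must be positive; sites without LJ
#'   interaction use `epsilon_over_kB = 0` (sigma is then inert).
#' @param epsilon_over_kB LJ well depth over k_B, K (non-negative).
#' @param mass Atomic mass, g/mol. Zero is allowed for massless virtual
#'   sites (the TIP4P/2005 M site).
#' @return Object of class `"atom_type"`.
#' @export
atom_type <- function(name, charge, sigma, epsilon_over_kB, mass) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    .stopf("atom type needs a non-empty name")
  if (!is.finite(charge)) .stopf("atom type '%s': charge must be finite", name)
  if (!is.finite(sigma) || sigma <= 0) .stopf("atom type '%s': sigma must be > 0", name)
  if (!is.finite(epsilon_over_kB) || epsilon_over_kB < 0)
    .stopf("atom type '%s': epsilon/kB must be >= 0", name)
  if (!is.finite(mass) || mass < 0) .stopf("atom type '%s': mass must be >= 0", name)
  structure(list(name = name, charge = charge, sigma = sigma,
                 epsilon_over_kB = epsilon_over_kB, mass = mass),
            class = "atom_type")
}

#' @export
print.atom_type <- function(x, ...) {
  cat(sprintf("<atom_type %s>  q = %+.4f e  sigma = %.4f A  eps/kB = %.4f K  m = %.3f g/mol\n",
              x$name, x$charge, x$sigma, x$epsilon_over_kB, x$mass))
  invisible(x)
}

#' Scale a set of partial charges by a common factor
#'
#' Applies the electronic-continuum-correction philosophy: every raw charge
#' (e.g. from an ADCH population analysis of the isolated ion) is multiplied
#' by one scaling factor so the net molecular charge scales exactly. The
#' factor is recorded on the result for provenance.
#'
#' @param raw Named numeric vector of raw charges (e).
#' @param factor Scaling factor in (0, 1].
#' @return Named numeric vector of scaled charges with attributes
#'   `"scale_factor"` and `"raw_charges"`.
#' @examples
#' scale_charges(c(O = -1.262, H = +0.262), 0.85)  # -1.0727, +0.2227
#' @export
scale_charges <- function(raw, factor) {
  if (!is.numeric(raw) || length(raw) == 0L) .stopf("raw charges must be numeric")
  if (any(!is.finite(raw))) .stopf("raw charges must all be finite")
  if (!is.finite(factor) || factor <= 0 || factor > 1)
    .stopf("scaling factor must lie in (0, 1], got %g", factor)
  out <- raw * factor
  attr(out, "scale_factor") <- factor
  attr(out, "raw_charges") <- raw
  out
}

#' Combine two atom types into pair parameters
#'
#' Applies the Lorentz-Berthelot rules, sigma_ij = (sigma_i + sigma_j)/2 and
#' epsilon_ij = sqrt(epsilon_i epsilon_j), optionally modified by
#' multiplicative deviation factors. Any deviation different from 1 flags
#' the pair as non-Lorentz-Berthelot (`"n-LB"`).
#'
#' @param a,b Objects of class `"atom_type"`.
#' @param deviation Length-2 numeric `c(sigma = 1, epsilon = 1)` of
#'   multiplicative deviations from the LB values.
#' @return List of class `"pair_params"`: `sigma` (A),
#'   `epsilon_over_kB` (K), `rule` (`"LB"` or `"n-LB"`), `deviation`, `pair`.
#' @export
combine_pair <- function(a, b, deviation = c(sigma = 1, epsilon = 1)) {
  stopifnot(inherits(a, "atom_type"), inherits(b, "atom_type"))
  dev <- .norm_deviation(deviation)
  sig <- dev[["sigma"]] * (a$sigma + b$sigma) / 2
  eps <- dev[["epsilon"]] * sqrt(a$epsilon_over_kB * b$epsilon_over_kB)
  if (!is.finite(eps) || eps < 0) .stopf("combined epsilon for %s-%s is negative", a$name, b$name)
  structure(list(pair = sort(c(a$name, b$name)), sigma = sig, epsilon_over_kB = eps,
                 rule = if (all(dev == 1)) "LB" else "n-LB", deviation = dev),
            class = "pair_params")
}

.norm_deviation <- function(deviation) {
  if (is.null(names(deviation))) names(deviation) <- c("sigma", "epsilon")[seq_along(deviation)]
  dev <- c(sigma = 1, epsilon = 1)
  dev[names(deviation)] <- deviation
  if (any(!is.finite(dev)) || any(dev < 0)) .stopf("deviation factors must be finite and >= 0")
  dev
}

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

## shipped parameter values ---------------------------------------------

## Rigid hydroxide model (this package's core): ADCH charges x 0.85.
.OH_RAW_CHARGES <- c(O_oh = -1.262, H_oh = +0.262)  # ADCH, isolated ion
.OH_SCALE <- 0.85
.OH_D_OH <- 0.98  # A, rigid O-H bond

## TIP4P/2005 literature constants (overridable through config).
.TIP4P2005 <- list(
  sigma_OO = 3.1589, eps_OO_kB = 93.2,      # A, K
  q_H = +0.5564, q_M = -1.1128,             # e
  d_OH = 0.9572, ang_HOH = 104.52, d_OM = 0.1546  # A, deg, A
)

#' Default force-field registry
#'
#' Builds the shipped parameter set: the scaled-charge hydroxide ion
#' (charges 0.85 x ADCH = -1.0727/+0.2227 e, sigma_OO = 3.40 A,
#' sigma_HH = 1.443 A, eps_OO/kB = 30.1753 K, eps_HH/kB = 22.1192 K),
#' TIP4P/2005 water, and the Madrid-2019 alkali cations (+0.85 e) read from
#' the editable file `inst/extdata/madrid2019_cations.yaml`. All cross
#' interactions default to Lorentz-Berthelot; override them via
#' [load_parameter_set()] config entries (they are then flagged n-LB).
#'
#' @param cations Path to the cation parameter YAML; `NULL` uses the file
#'   shipped with the package.
#' @return Object of class `"ff_registry"`.
#' @export
default_parameter_set <- function(cations = NULL) {
  q_oh <- scale_charges(.OH_RAW_CHARGES, .OH_SCALE)
  types <- list(
    atom_type("O_oh", q_oh[["O_oh"]], 3.40,   30.1753, 15.999),
    atom_type("H_oh", q_oh[["H_oh"]], 1.443,  22.1192, 1.008),
    atom_type("O_w", 0.0,           .TIP4P2005$sigma_OO, .TIP4P2005$eps_OO_kB, 15.999),
    atom_type("H_w", .TIP4P2005$q_H, 1.0, 0.0, 1.008),
    atom_type("M_w", .TIP4P2005$q_M, 1.0, 0.0, 0.0)
  )
  if (is.null(cations))
    cations <- system.file("extdata", "madrid2019_cations.yaml", package = "hydroxff")
  if (nzchar(cations) && file.exists(cations)) {
    cat_cfg <- yaml::read_yaml(cations)
    for (nm in names(cat_cfg$atom_types)) {
      p <- cat_cfg$atom_types[[nm]]
      types <- c(types, list(atom_type(nm, p$charge, p$sigma, p$epsilon_over_kB, p$mass)))
    }
  }
  names(types) <- vapply(types, `[[`, "", "name")
  structure(list(types = types, pairs = list(),
                 charge_scale = .OH_SCALE, raw_charges = .OH_RAW_CHARGES),
            class = "ff_registry")
}

#' Load a force-field registry from a config file or list
#'
#' Reads a flat YAML-style parameter config. The config may redefine atom
#' types (section `atom_types`) and supply cross-pair overrides (section
#' `pairs`, keys `"A-B"`, fields `sigma`/`epsilon_over_kB`); everything not
#' mentioned keeps the shipped defaults ([default_parameter_set()]).
#' An overridden pair is flagged n-LB, with deviation factors stored
#' relative to the Lorentz-Berthelot values.
#'
#' @param config Path to a YAML file, a list with the same structure, or
#'   `NULL` for pure defaults.
#' @return Object of class `"ff_registry"`.
#' @export
load_parameter_set <- function(config = NULL) {
  reg <- default_parameter_set()
  if (is.null(config)) return(reg)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (nm in names(cfg$atom_types)) {
    p <- cfg$atom_types[[nm]]
    cur <- reg$types[[nm]]
    get_or <- function(field, fallback) if (!is.null(p[[field]])) p[[field]] else fallback
    if (is.null(cur)) {
      need <- c("charge", "sigma", "epsilon_over_kB", "mass")
      miss <- need[!need %in% names(p)]
      if (length(miss))
        .stopf("new atom type '%s' is missing fields: %s", nm, paste(miss, collapse = ", "))
      reg$types[[nm]] <- atom_type(nm, p$charge, p$sigma, p$epsilon_over_kB, p$mass)
    } else {
      reg$types[[nm]] <- atom_type(nm, get_or("charge", cur$charge),
                                   get_or("sigma", cur$sigma),
                                   get_or("epsilon_over_kB", cur$epsilon_over_kB),
                                   get_or("mass", cur$mass))
    }
  }
  for (key in names(cfg$pairs)) {
    ab <- strsplit(key, "-", fixed = TRUE)[[1]]
    if (length(ab) != 2L) .stopf("pair key '%s' must have the form 'A-B'", key)
    reg <- set_pair_override(reg, ab[1], ab[2],
                             sigma = cfg$pairs[[key]]$sigma,
                             epsilon_over_kB = cfg$pairs[[key]]$epsilon_over_kB)
  }
  reg
}

#' Override a cross-pair interaction in a registry
#'
#' Stores explicit `sigma`/`epsilon` for an atom-type pair. The deviation
#' factors relative to Lorentz-Berthelot are recorded and the pair is
#' flagged `"n-LB"` whenever a stored value differs from the combining rule.
#'
#' @param registry An `"ff_registry"`.
#' @param a,b Atom-type names (must be registered).
#' @param sigma,epsilon_over_kB Values to store (A, K); `NULL` keeps the LB
#'   value for that field.
#' @return The modified registry.
#' @export
set_pair_override <- function(registry, a, b, sigma = NULL, epsilon_over_kB = NULL) {
  stopifnot(inherits(registry, "ff_registry"))
  for (nm in c(a, b)) if (is.null(registry$types[[nm]]))
    .stopf("unknown atom type '%s' in pair override", nm)
  lb <- combine_pair(registry$types[[a]], registry$types[[b]])
  sig <- if (is.null(sigma)) lb$sigma else sigma
  eps <- if (is.null(epsilon_over_kB)) lb$epsilon_over_kB else epsilon_over_kB
  if (eps < 0) .stopf("pair %s-%s: epsilon must be >= 0", a, b)
  dev <- c(sigma = sig / lb$sigma,
           epsilon = if (lb$epsilon_over_kB > 0) eps / lb$epsilon_over_kB else 1)
  pp <- structure(list(pair = sort(c(a, b)), sigma = sig, epsilon_over_kB = eps,
                       rule = if (isTRUE(all.equal(unname(dev), c(1, 1), tolerance = 1e-12)) &&
                                  (lb$epsilon_over_kB > 0 || eps == 0)) "LB" else "n-LB",
                       deviation = dev),
                  class = "pair_params")
  registry$pairs[[.pair_key(a, b)]] <- pp
  registry
}

#' Resolve the pair parameters for two atom types
#'
#' Looks up an explicit override first; otherwise applies the
#' Lorentz-Berthelot rules to the self terms.
#'
#' @inheritParams set_pair_override
#' @return A `"pair_params"` list.
#' @export
resolve_pair <- function(registry, a, b) {
  stopifnot(inherits(registry, "ff_registry"))
  ov <- registry$pairs[[.pair_key(a, b)]]
  if (!is.null(ov)) return(ov)
  ta <- registry$types[[a]]; tb <- registry$types[[b]]
  if (is.null(ta) || is.null(tb))
    .stopf("cannot resolve pair %s-%s: unregistered atom type '%s'",
           a, b, if (is.null(ta)) a else b)
  combine_pair(ta, tb)
}

#' @export
print.ff_registry <- function(x, ...) {
  cat(sprintf("<ff_registry> %d atom types, %d pair overrides (charge scale %.2f)\n",
              length(x$types), length(x$pairs), x$charge_scale))
  for (t in x$types)
    cat(sprintf("  %-5s q=%+.4f e  sigma=%.4f A  eps/kB=%.4f K\n",
                t$name, t$charge, t$sigma, t$epsilon_over_kB))
  for (p in x$pairs)
    cat(sprintf("  %s-%s  sigma=%.4f  eps/kB=%.4f  [%s]\n",
                p$pair[1], p$pair[2], p$sigma, p$epsilon_over_kB, p$rule))
  invisible(x)
}

#' Write a registry to a flat YAML config
#'
#' Numbers are emitted with 17 significant digits so that
#' `load_parameter_set(write_parameter_set(reg, f))` reproduces every
#' parameter bit-identically.
#'
#' @param registry An `"ff_registry"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(registry, path) {
  stopifnot(inherits(registry, "ff_registry"))
  num <- function(x) sprintf("%.17g", x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("atom_types:", con)
  for (t in registry$types)
    writeLines(sprintf("  %s: {charge: %s, sigma: %s, epsilon_over_kB: %s, mass: %s}",
                       t$name, num(t$charge), num(t$sigma), num(t$epsilon_over_kB), num(t$mass)), con)
  if (length(registry$pairs)) {
    writeLines("pairs:", con)
    for (p in registry$pairs)
      writeLines(sprintf("  %s-%s: {sigma: %s, epsilon_over_kB: %s}",
                         p$pair[1], p$pair[2], num(p$sigma), num(p$epsilon_over_kB)), con)
  }
  invisible(path)
}

#' Emit GROMACS-dialect topology fragments
#'
#' Writes `[ atomtypes ]` (sigma in nm, epsilon in kJ/mol),
#' `[ nonbond_params ]` for every stored pair override, and rigid molecule
#' blocks for TIP4P/2005 water (`[ settles ]` + virtual site) and the
#' hydroxide ion (`[ constraints ]`). Output is syntactically valid for
#' GROMACS topology parsing; it does not attempt to be a complete runnable
#' `.top` (no system/molecules counts unless `composition` is given).
#'
#' @param registry An `"ff_registry"`.
#' @param path Output `.itp`/`.top` path.
#' @param composition Optional `"composition"` object (see
#'   [molality_to_counts()]); when supplied, `[ system ]`/`[ molecules ]`
#'   sections are appended.
#' @return `path`, invisibly.
#' @export
write_gromacs_topology <- function(registry, path, composition = NULL) {
  stopifnot(inherits(registry, "ff_registry"))
  eps_kj <- function(K) K * .kB_kJmol
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("; hydroxff topology fragment (GROMACS dialect)")
  w("[ defaults ]")
  w("; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ")
  w("  1      2         no        1.0     1.0")
  w("")
  w("[ atomtypes ]")
  w("; name  mass      charge    ptype  sigma(nm)   epsilon(kJ/mol)")
  for (t in registry$types)
    w("  %-5s %9.4f %9.4f  %s  %12.6e %12.6e", t$name, t$mass, t$charge,
      if (t$mass == 0) "D" else "A", t$sigma / 10, eps_kj(t$epsilon_over_kB))
  if (length(registry$pairs)) {
    w("")
    w("[ nonbond_params ]")
    w("; i     j     func  sigma(nm)   epsilon(kJ/mol)")
    for (p in registry$pairs)
      w("  %-5s %-5s 1  %12.6e %12.6e", p$pair[1], p$pair[2],
        p$sigma / 10, eps_kj(p$epsilon_over_kB))
  }
  tp <- .TIP4P2005
  w("")
  w("[ moleculetype ]")
  w("SOL  2")
  w("[ atoms ]")
  w(";  nr type  resnr res  atom cgnr charge     mass")
  q <- function(nm) registry$types[[nm]]$charge
  m <- function(nm) registry$types[[nm]]$mass
  w("   1  O_w   1     SOL  OW   1  %9.4f %9.4f", q("O_w"), m("O_w"))
  w("   2  H_w   1     SOL  HW1  1  %9.4f %9.4f", q("H_w"), m("H_w"))
  w("   3  H_w   1     SOL  HW2  1  %9.4f %9.4f", q("H_w"), m("H_w"))
  w("   4  M_w   1     SOL  MW   1  %9.4f %9.4f", q("M_w"), m("M_w"))
  dHH <- 2 * tp$d_OH * sin(tp$ang_HOH / 2 * pi / 180)
  w("[ settles ]")
  w("; OW funct doh(nm) dhh(nm)")
  w("  1  1  %.5f  %.5f", tp$d_OH / 10, dHH / 10)
  ## M site as 3-site virtual: r_M = r_O + a (r_H1 - r_O) + a (r_H2 - r_O)
  a_vs <- tp$d_OM / (2 * tp$d_OH * cos(tp$ang_HOH / 2 * pi / 180))
  w("[ virtual_sites3 ]")
  w("; site from1 from2 from3 funct a b")
  w("  4    1     2     3     1  %.6f %.6f", a_vs, a_vs)
  w("[ exclusions ]")
  w("1 2 3 4"); w("2 1 3 4"); w("3 1 2 4"); w("4 1 2 3")
  w("")
  w("[ moleculetype ]")
  w("OHX  2")
  w("[ atoms ]")
  w("   1  O_oh  1     OHX  O1   1  %9.4f %9.4f", q("O_oh"), m("O_oh"))
  w("   2  H_oh  1     OHX  H1   1  %9.4f %9.4f", q("H_oh"), m("H_oh"))
  w("[ constraints ]")
  w("; i j funct length(nm)")
  w("  1 2 1 %.5f", .OH_D_OH / 10)
  w("[ exclusions ]")
  w("1 2"); w("2 1")
  for (ion in c("Li", "Na", "K")) {
    if (is.null(registry$types[[ion]])) next
    w("")
    w("[ moleculetype ]")
    w("%s  1", toupper(ion))
    w("[ atoms ]")
    w("   1  %-4s 1     %-4s %-3s 1  %9.4f %9.4f",
      ion, toupper(ion), toupper(ion), q(ion), m(ion))
  }
  if (!is.null(composition)) {
    w("")
    w("[ system ]")
    w("%s solution, %.4g mol/kg", composition$salt, composition$molality)
    w("[ molecules ]")
    w("SOL %d", composition$n_water)
    if (composition$n_cation > 0) {
      cat_name <- toupper(sub("OH$", "", composition$salt))
      w("%s %d", cat_name, composition$n_cation)
      w("OHX %d", composition$n_anion)
    }
  }
  invisible(path)
}
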