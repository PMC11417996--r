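# Internal unit system: angstrom, elementary charge, K (epsilon/kB), g/mol.
# Energies are reported in kJ/mol; all conversions live here.

## CODATA 2018 exact values
.kB_J      <- 1.380649e-23          # Boltzmann constant, J/K
.NA_mol    <- 6.02214076e23         # Avogadro constant, 1/mol
.e_C       <- 1.602176634e-19       # elementary charge, C
.eps0      <- 8.8541878128e-12      # vacuum permittivity, F/m

## derived
.kB_kJmol  <- .kB_J * .NA_mol / 1000        # kJ/(mol K): 0.008314462618
## Coulomb prefactor k_e in kJ A / (mol e^2): q_i q_j / r with r in A gives kJ/mol
.ke_kJmolA <- .e_C^2 * .NA_mol * 1e10 / (4 * pi * .eps0) / 1000  # 1389.3546

.M_WATER_KG <- 0.018015             # molar mass of water, kg/mol
.XI_YH      <- 2.837297             # Yeh-Hummer cubic-box constant (dimensionless)

## unit conversions
.BAR_A_TO_mN_m <- 1e-2              # 1 bar * A = 1e-2 mN/m
.A2_PS_TO_M2_S <- 1e-8              # 1 A^2/ps = 1e-8 m^2/s

#' Physical constants and unit conversions used by hydroxff
#'
#' Returns the package's centralized physical constants (CODATA 2018) and the
#' unit-conversion factors between the internal unit system (angstrom,
#' elementary charge, kelvin for epsilon/k_B, g/mol, picosecond) and SI.
#'
#' @return Named list with elements `kB_J` (J/K), `NA_mol` (1/mol),
#'   `kB_kJmol` (kJ/mol/K), `ke_kJmolA` (Coulomb prefactor, kJ A mol^-1 e^-2),
#'   `M_water_kg` (kg/mol), `xi_yeh_hummer` (dimensionless),
#'   `bar_A_to_mN_m` and `A2_ps_to_m2_s` (conversion factors).
#' @examples
#' hx_constants()$ke_kJmolA  # ~1389.35: two unit charges at 1 A, in kJ/mol
#' @export
hx_constants <- function() {
  list(
    kB_J = .kB_J, NA_mol = .NA_mol, e_C = .e_C,
    kB_kJmol = .kB_kJmol, ke_kJmolA = .ke_kJmolA,
    M_water_kg = .M_WATER_KG, xi_yeh_hummer = .XI_YH,
    bar_A_to_mN_m = .BAR_A_TO_mN_m, A2_ps_to_m2_s = .A2_PS_TO_M2_S
  )
}

## small numeric helpers -------------------------------------------------

.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
.erf  <- function(x) 1 - .erfc(x)

## round half away from zero (base round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
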