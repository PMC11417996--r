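---
title: "Methods: a scaled-charge hydroxide model and its estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a scaled-charge hydroxide model and its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroxff)
```

## The model

The hydroxide ion is rigid: two interaction sites at a fixed O–H
distance of 0.98 Å. Each site carries a partial charge and
Lennard-Jones self parameters; the pair energy between sites of types
$i$ and $j$ at distance $r$ is

$$u_{ij}(r) = 4\varepsilon_{ij}\left[\left(\frac{\sigma_{ij}}{r}\right)^{12} -
\left(\frac{\sigma_{ij}}{r}\right)^{6}\right] + \frac{k_e\,q_i q_j}{r}.$$

Charges follow the electronic-continuum-correction idea: electronic
polarization, absent from a nonpolarizable model, is represented by
scaling all ionic charges by a common factor. The shipped hydroxide uses
ADCH-derived charges of an isolated ion, $-1.262\,e$ and $+0.262\,e$,
scaled by 0.85 to $q_\mathrm{O} = -1.0727\,e$ and
$q_\mathrm{H} = +0.2227\,e$; the net ion charge $-0.85\,e$ matches the
$\pm 0.85\,e$ Madrid-2019 alkali cations, so all salts assembled here are
exactly electroneutral. `scale_charges()` performs this operation
exactly (no intermediate rounding) and records the factor as provenance.

Water is TIP4P/2005: a rigid three-atom geometry
($d_\mathrm{OH} = 0.9572$ Å, $\angle$HOH $= 104.52^\circ$) plus a
massless M site carrying the negative charge at 0.1546 Å along the HOH
bisector. Because the M position is an exact linear combination of the
three atomic sites, the file readers always rederive it from the atoms
and never trust it from input. These water constants are literature
values of the TIP4P/2005 model and can be overridden through the
parameter config. The `mass >= 0` relaxation in `atom_type()` exists
solely for this virtual site.

Cross interactions default to Lorentz–Berthelot,
$\sigma_{ij} = (\sigma_i + \sigma_j)/2$,
$\varepsilon_{ij} = \sqrt{\varepsilon_i\varepsilon_j}$. Models of this
family deliberately break LB for selected ion–water and ion–ion pairs;
`set_pair_override()` stores such values verbatim, computes the
multiplicative deviation factors relative to LB, and flags the pair
`n-LB`. We ship only the hydroxide and water self terms plus the
Madrid-2019 cation self parameters (an editable YAML under
`inst/extdata/`); cross terms tuned for specific salts are inputs the
user supplies via config, not values we guess — resolution falls back to
LB whenever no override is present.

## Units and constants

Internally: Å, elementary charges, K for $\varepsilon/k_B$, g/mol, ps.
Energies are reported in kJ/mol; the Coulomb prefactor
$k_e = 1389.3546$ kJ Å mol$^{-1}$ e$^{-2}$ and all other constants
(CODATA 2018) live in one place, `hx_constants()`, together with the
unit conversions the transport estimators need
(1 bar·Å $= 10^{-2}$ mN/m; 1 Å$^2$/ps $= 10^{-8}$ m$^2$/s).

## Energy evaluation

`total_energy()` targets verifiability at desk scale, not speed.
Lennard-Jones interactions are sharply truncated at the cutoff (default
10 Å, never more than half the shortest box edge) with the standard
analytic multicomponent tail correction
$\frac{8\pi}{3}\frac{N^2}{V}\sum_{ij} x_i x_j \varepsilon_{ij}\sigma_{ij}^3
\left[\tfrac13 (\sigma_{ij}/r_c)^9 - (\sigma_{ij}/r_c)^3\right]$.
Electrostatics default to direct Ewald summation — real-space
$\mathrm{erfc}$ sum, full reciprocal lattice sum, self term, an
intramolecular-exclusion correction (rigid molecules carry no internal
energy terms at all), and a neutralizing-background term for
hypothetically non-neutral inputs. The splitting parameter defaults to
$\alpha = 3.5/r_c$ and the reciprocal cutoff is chosen from a target
accuracy of $10^{-8}$; the total is flat against $\alpha$ over
$\alpha r_c \in [3.3, 4.5]$ (below $\approx 3.2$ the real-space
truncation error $\propto \mathrm{erfc}(\alpha r_c)$ becomes visible —
that is a property of any cutoff Ewald, not of this implementation). A
plain cutoff mode exists for parity with simple brute-force sums.
Correctness anchors in the tests: the rocksalt Madelung constant, a
$3^3$ periodic-image brute-force LJ sum, and central-difference forces.

`forces()` is the analytic gradient (pairwise LJ/real-space terms,
reciprocal-space gradient, exclusion corrections); the LJ tail is
configuration-independent and contributes none.

## Composition and box building

Molality is the composition variable because it is invariant under
volume fluctuations. With $M_w = 0.018015$ kg/mol,
`molality_to_counts()` gives $n_\mathrm{pairs} =
\mathrm{round}(m\,M_w\,N_w)$ (ties half away from zero) and reports the
achieved molality; the quantization error is at most half an ion pair,
vanishing as $N_w$ grows. The default $N_w = 555$ is the reference box
size of this model family (10 pairs at 1 mol/kg, 160 at 16 mol/kg).
`build_box()` inserts rigid templates at uniformly random positions and
orientations (quaternion-uniform rotations), rejecting any pose that
brings two intermolecular sites closer than $0.8\,\sigma_{ij}$; it is
deterministic under a fixed seed and reports the attained packing
fraction on failure. The builder produces starting points for external
MD engines, not equilibrated liquid structure.

## Structural estimators

`compute_rdf()` is the standard pair histogram normalized per frame by
the ideal-gas shell count and the partner density (per-frame volumes, so
NpT trajectories are handled); self and intramolecular pairs are
excluded. Default bin width 0.02 Å and $r_\mathrm{max} = \min(12, L/2)$ Å
resolve first-shell peaks near 2.7–2.8 Å at the 0.1 Å level.

Coordination numbers are $4\pi\rho\int_0^{r_\mathrm{min}} g(r)\,r^2\,dr$
by trapezoidal quadrature on the bin grid with linear interpolation of
the final partial bin — accurate to $<0.1\%$ for $g \equiv 1$ at 0.02 Å
bins, with the caveat that sharply peaked (delta-like) shells carry an
$O(\Delta r^2)$ quadrature error. The wrappers bind the conventional
densities: cation–anion CIP$_\pm$ uses the ion density, the
hydroxide–hydroxide contact count CIP$_\mathrm{OH}$ the hydroxide
density, the hydration number HN the water density. When
$r_\mathrm{min}$ is omitted it is auto-detected as the first local
minimum after the first $g>1$ maximum of a 5-bin moving-average smooth
(raw bin noise creates spurious extrema); because the
hydroxide–hydroxide first shell is often only a shoulder, the upper
integration limit materially changes CIP$_\mathrm{OH}$, so it remains an
explicit parameter and the auto-detector refuses rather than guesses
when no interior minimum exists.

The distance–angle joint distribution uses
$\theta = \angle(\mathrm{H_{OH}}, \mathrm{O_{OH}}, \mathrm{O}_w)$ —
vertex at the hydroxide oxygen, rays to its hydrogen and to a water
oxygen — in degrees at the interface, radians internally; the histogram
normalizes to unit mass and a zero-length O–H bond is rejected with a
diagnostic. Hydrogen bonds are geometric: O···O distance $\le r_c$
(default 3.5 Å) and an angular criterion with two selectable
conventions, since the donor-angle convention differs between
literatures: `"HOO"` (default) caps the angle at the donor oxygen at
30°, `"OHO"` requires the O–H···O angle at the hydrogen to exceed 150°.
An optional second distance threshold splits strong
($< 3.0$ Å) from weak (3.0–3.5 Å) bonds, mirroring the two-population
description of hydroxide hydration shells.

## Thermodynamic and transport estimators

**TMD.** `fit_tmd()` fits $\rho(T)$ with a least-squares cubic (centered
internally for conditioning, coefficients reported on the raw scale) and
extracts the stationary point with negative curvature inside the data
range analytically; outside-range or absent maxima report
`"no TMD in range"` rather than extrapolating. The uncertainty is
first-order propagation of the coefficient covariance through the
implicit stationarity condition; an optional Monte-Carlo mode
additionally resamples per-point $T$ and $\rho$ uncertainties, mirroring
the fuller experimental uncertainty budgets in which those dominate. The
object carries the usual model-fit surface (`print`, `summary`, `coef`,
`predict`, `residuals`, `plot`).

**Despretz algebra.** TMD shifts in the dilute regime are additive in
ionic group contributions, $K_m = \nu_+ K_m^+ + \nu_- K_m^-$; the
forward and inverse functions are exact linear algebra and preserve
signs end-to-end (hydroxide contributions are negative).
`despretz_from_shifts()` estimates $K_m = \lim_{m\to 0}\Delta/m$ as a
through-origin weighted regression, or $\Delta/m$ for a single dilute
point.

**Diffusion.** `diffusion_einstein()` fits the MSD slope over an
explicit window and divides by 6. The window is a required concept (not
auto-chosen) because short-time ballistic/subdiffusive transients bias
the slope and no universal bound exists; the default central 50% of the
series is only a convenience. The Yeh–Hummer correction
$D_0 = D_\mathrm{PBC} + \xi k_B T/(6\pi\eta L)$, $\xi = 2.837297$,
is exact arithmetic.

**Viscosity.** `green_kubo_viscosity()` integrates the averaged stress
autocorrelation, $\eta = \frac{V}{k_B T}\int_0^t \langle
P_{\alpha\beta}(0)P_{\alpha\beta}(s)\rangle ds$, over the three
off-diagonal channels plus, when diagonals are present, the rotated
differences $(P_{xx}-P_{yy})/2$ etc. The autocorrelation is computed by
FFT or direct summation (identical to $10^{-10}$, tested), with
unbiased $1/(n-k)$ normalization; the time grid must be uniform.

**Surface tension and excess.** The virial route
$\gamma = \frac{L_z}{n_\mathrm{int}}\left[\langle P_{zz}\rangle -
\tfrac12(\langle P_{xx}\rangle + \langle P_{yy}\rangle)\right]$ is
linear and exact given the pressure means. The Gibbs surface excess
integrates $\rho(z) - \rho_\mathrm{bulk}\,\Theta(z)$ against a dividing
surface conventionally fixed at the solvent equimolar position
(`equimolar_surface()`); if no bulk plateau is detectable and none is
supplied, the estimator refuses.

**Freezing bracket.** Direct-coexistence observations (ice grows /
melts / stable at each temperature) reduce to the tightest bracket
[highest growing $T$, lowest melting $T$]; inconsistent sets are flagged
and widened rather than silently reordered.

**Picnometer.** The printed form of the capillary-densimetry equation
was not available to us, so the implementation derives it from mass
conservation with a linearized glass volume expansion:
$\rho(T) = \rho_0\,(V_{f,0} + S_0 L_0)\,/\,[(V_{f,0} + S_0 L)(1 + 3\delta)]$,
$\delta = \alpha(T - T_0)$. An exact $(1+\delta)^3$ variant sits behind
`exact_expansion = TRUE`; the two agree to first order in $\delta$
(glass expansivities are $\sim 10^{-6}$/K, so the difference is far
below experimental resolution) and both satisfy the calibration-point
identity $\rho(T_0, L_0) = \rho_0$, which pins the functional form.

**Sign conventions.** Relative deviations are reported both signed,
$100(x_\mathrm{sim} - x_\mathrm{ref})/x_\mathrm{ref}$, and as
magnitudes, because printed deviations in the literature occasionally
mix the two (the KOH TMD comparison is an example: 261.0 K simulated vs
259.4 K experimental is $+0.62\%$ signed, usually quoted as a 0.6%
deviation). The s-statistic
$s = \frac1N\sum_i |X_i - x_i|/X_i$ is the magnitude-only summary.

## What the synthetic fixtures do and do not show

Each generator has an analytically known truth: uniform points give
$g \equiv 1$ and coordination $\frac43\pi r^3\rho$; delta shells give an
exact per-center neighbor count (fractional $k$ by floor/ceil mixture);
the cubic density series has its stationary point exactly at the set
TMD; the Ornstein–Uhlenbeck channels have autocovariance
$\sigma^2 e^{-t/\tau}$, hence a Green–Kubo integral of exactly
$\sigma^2\tau$; Gaussian random walks have MSD $6Dt$ in expectation.
Recovering these truths verifies the estimators' algebra, normalization
and unit conversions — it does not show that the force field reproduces
real water or real hydroxide solutions, which requires production MD
(nanosecond-to-microsecond GROMACS runs) outside this package's scope.
The fixtures are deliberately truth-bearing rather than realistic.

Test problem sizes (our choices, balancing statistical resolution
against suite runtime): 800-point ideal-gas frames, 64-center delta
shells, 100 TMD replicates at noise 0.05 kg/m$^3$ over 20 points,
$10^6$-sample OU series ($\tau/\Delta t = 40$, integral to $15\tau$),
800 walkers × $10^4$ steps for diffusion, 20–30-molecule boxes for
energies and forces. At these sizes the seeded recoveries sit well
inside their asserted tolerances (10% for Green–Kubo, 5% for diffusion,
0.1 K bias / 90% coverage for the TMD ensemble).

## Known limitations

- Orthorhombic boxes only; no triclinic cells.
- The Ewald evaluator is $O(N^2)$-ish by design (exactness over speed);
  it is meant for verification boxes, not production systems. No PME.
- No integrator, thermostat or barostat: trajectories come from outside.
- XYZ carries no topology, so each site reads back as its own molecule;
  GRO/PDB preserve molecule identity.
- Binary trajectory codecs (XTC/TRR) are not implemented; the reader
  interface (`md_traj` of `md_config`) is the plug-in point.
- The hydrogen-bond donor detection keys on the shipped atom-type names
  (`O_w`/`H_w`/`O_oh`/`H_oh`).
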