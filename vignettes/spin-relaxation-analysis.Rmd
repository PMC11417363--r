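---
title: "Models and methods for NMR spin-relaxation analysis with spindyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for NMR spin-relaxation analysis with spindyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindyn)
```

spindyn analyses backbone-amide ¹⁵N (and nucleic-acid ¹³C) spin-relaxation
data for proteins and protein–RNA complexes: it reduces peak-intensity
series to rates, maps conformational exchange on three timescales (RCZZ
Hahn-echo, CPMG, spin-lock R1ρ), and decomposes the fast dynamics by
Lipari–Szabo model-free analysis. This vignette states the models, the
conventions and defaults, the numerical choices, and what the synthetic-data
tests do and do not establish.

## Spin physics and constants

All rate expressions derive from an effective two-spin X–H treatment with
dipolar and CSA relaxation. The interaction constants are

- dipolar: d = μ₀ h γ_H γ_X / (8π² r³), stored as a positive magnitude
  (`dipolar_constant()`),
- CSA: c = ω_X Δσ / √3, signed with the anisotropy Δσ = σ∥ − σ⊥
  (`csa_constant()`).

Defaults for the amide pair are r = 1.02 Å, Δσ = −164 ppm, and β = 18°
between the CSA major axis and the bond vector. Gyromagnetic ratios use the
*shielded-proton* (H₂O) value γ′_H = 2.675153151 × 10⁸ rad s⁻¹ T⁻¹: a
spectrometer's nominal ¹H frequency references the water resonance, and the
field B₀ inferred from "750 MHz" therefore uses the shielded constant. With
this convention the cross-correlation factor

κ = −6 [(d²/8) + (c²/6)] / [√3 c d P₂(cos β)]

evaluates to 1.2283 at 750 MHz for the ¹⁵N defaults (`kappa_factor()`); the
free-proton CODATA value would give 1.2284 at the fourth decimal. Signs are
carried so that c < 0 and κ > 0 for ¹⁵N, and the ¹⁵N NOE uses the signed
ratio γ_H/γ_N < 0, allowing NOE < 1.

```{r kappa}
kappa_factor(spin_system("N15"), field_context(750))
```

Spectral densities are in s/rad, rates in s⁻¹, all internal frequencies in
rad/s; ppm ↔ rad/s conversions always go through a `field_context()`
(`ppm_to_rad()`).

## Cross-correlated relaxation and the RCZZ exchange map

The transverse CSA/dipole cross-correlated rate η_xy is normalised by the
identity κ·η_xy = [(d²/8) + (c²/6)][4J(0) + 3J(ω_X)] — exactly the
J(0)/J(ω_X) part of R₂. Fixing the prefactor through this identity (rather
than an independently chosen literature constant) guarantees that the
slow-exchange map

R_ex = R₂^RCZZ − κ·η_xy + R₁/2

returns exactly zero for an exchange-free spin: the package's forward model
and the extraction pipeline cancel at machine precision, which the test
suite asserts to 10⁻⁶ s⁻¹ end-to-end (tanh build-up fit → monoexponential
R₁ fit → echo-ratio R₂^RCZZ → R_ex).

## Reduced spectral density mapping

`reduced_spectral_density_map()` inverts (R₁, R₂, NOE) to J(0), J(ω_X),
J(0.87 ω_H) under the standard flat-high-frequency approximation
J(ω_H−ω_X) ≈ J(ω_H) ≈ J(ω_H+ω_X) ≈ J(0.87 ω_H) with R_ex = 0. Literature
variants differ slightly in the σ-coefficients; we use the **exact algebraic
inverse** of our forward rate expressions under that approximation:

- σ = (NOE − 1) R₁ γ_X/γ_H
- J(0.87 ω_H) = 4σ / (5 d²)
- J(ω_X) = [4R₁ − (28/5)σ] / (3d² + 4c²)
- J(0) from R₂ after removing the J(ω_X) and high-frequency terms.

The round-trip `reduced_spectral_density_map(rates_from_j(J))` is then an
identity at machine precision whenever J is flat across the three high
frequencies — that identity, not any particular coefficient, is the
correctness contract. For a true Lorentzian J the approximation error in
J(0) stays below 5 % at 700 MHz for τ_c ≈ 6.5 ns. A negative apparent J(0)
is preserved and flagged (`j0_negative`); it signals exchange or noise, not
an input error.

## CPMG dispersion: the general two-site model

`carver_richards_r2eff()` implements the closed-form general two-site
exchange expression

R₂eff(ν_CP) = ½(R_a + R_b + k_ex) − ν_CP · acosh[D₊cosh η₊ − D₋cos η₋]

with ψ = [R_a − R_b + (p_b − p_a)k_ex]² − Δω² + 4 p_a p_b k_ex²,
ξ = 2Δω[R_a − R_b + (p_b − p_a)k_ex], η± = [±ψ + (ψ²+ξ²)^½]^½ / (√8 ν_CP).
Two common typesetting defects of this expression (a missing inverse
hyperbolic cosine; "R_a + R_b" in place of R_a − R_b inside ψ) are resolved
to the standard form; the Δω = 0 and p_b → 0 limits are then *exactly* flat,
which the tests enforce, and the expression agrees with a numerical
Bloch–McConnell pulse-train propagator to better than 1 % in all regimes
(see "Oracle tolerances" below). ν_CP is the 180° pulse repetition
frequency; the inter-pulse delay is 1/(2ν_CP).

Numerics: for η₊ > 25 the acosh is evaluated in its asymptotic log form to
avoid cosh overflow; an acosh argument below 1 (deep slow exchange at
finite precision) is clamped to 1 with a warning.

### Fitting

`fit_cpmg()` (per residue) and `fit_cpmg_global()` (shared kinetics) are
weighted least-squares fits (Levenberg–Marquardt) with:

- Δω stored in ppm and scaled per field, so one Δω serves two-field fits;
- one intrinsic rate per field with R_a = R_b within a field;
- a multi-start grid over k_ex (log-spaced), p_b and Δω, because the
  Carver–Richards χ² surface is multimodal;
- bounded parameters: p_b ∈ (0, 0.5), k_ex ∈ [10², 10⁵] s⁻¹ and
  Δω ∈ (0, 10] ppm by default (`dw_max`).

The k_ex and Δω bounds are not cosmetic. Outside the sensitive window of a
constant-time CPMG experiment the slow-exchange branch of the closed form
becomes oscillatory in ν_CP and will chase point noise; and with Δω
unbounded, a slow-exchange solution with a physically absurd shift
difference (tens of ppm) can mimic a fast-exchange curve. Both failure
modes were observed on synthetic data and are excluded by the bounds, which
correspond to the physically plausible ranges for backbone amides.

Global fits share k_ex (and optionally p_b) across residues, keep Δω and
per-field intrinsic rates per residue, and report χ²_g/χ²_i for each
residue against its individual fit. Residues above the exclusion cutoff
(default 2.0; configurable) are flagged, removed, and the fit rerun once.
`fixed_dw` clamps per-residue shift differences for weakly dispersing
curves. Model comparison (general vs fast/Luz–Meiboom) uses
`aic_compare()` with AIC = χ² + 2k for known point errors; AICc is
available by flag. Parameter uncertainties come from seeded Monte-Carlo
refits of noise-perturbed datasets (`mc_parameter_errors()`).

## Spin-lock (R1ρ) dispersion: two-site fast exchange

R₂eff values derived from R1ρ via R₂ = (R1ρ − R₁cos²θ)/sin²θ,
θ = arctan(ω_SL/ω_off), are fitted with

R₂eff = R₂⁰ + φ_ex k_ex / (ω_SL² + ω_off² + k_ex²),  φ_ex = p_a p_b Δω².

ω_SL and ω_off are accepted in Hz and converted to angular units, since the
denominator adds them to k_ex². For ¹⁵N sites R₂⁰ is fixed to κ·η_xy (the
RCZZ-calibrated intrinsic rate); for ¹³C sites R₂⁰ is a free parameter and
R₁ is fixed from its own experiment. Because the model is linear in φ_ex
(and R₂⁰) at fixed k_ex, those parameters are profiled out analytically and
k_ex is optimised in one dimension on a log grid — this makes the global
shared-k_ex fit across mixed ¹⁵N/¹³C site sets fast and deterministic.
Sites whose fitted dispersion amplitude across the measured effective-field
window is below twice the median point error are flagged as unidentifiable
(φ_ex pinned at 0 where negative). An alignment pre-filter
(`filter_alignment()`, |ω_off|/ω_SL ≤ 0.4 by default) reproduces the
on-resonance acceptance criterion.

## Rotational diffusion and model-free analysis

`estimate_tc_isotropic()` inverts per-residue R₂/R₁ ratios with the rigid
(S² = 1, τ_i = 0) isotropic spectral density by root finding on
τ_c ∈ [0.2, 60] ns, after excluding residues with NOE < 0.65 (fast internal
motion) and residues whose ratio deviates more than 1.5 SD from the
10 %-trimmed mean (exchange); thresholds are arguments. `fit_axial_tensor()`
extends this to an axially symmetric tensor: (τ_c, D∥/D⊥, axis) are fitted
to the ratios with the three-Lorentzian axial spectral density, multi-start
over axis orientations, against an isotropic null model compared by AIC.
The axis is reported in the upper hemisphere (v ≡ −v); with fewer than 8
usable residues or a degenerate vector distribution the isotropic model is
returned with a warning. N–H vectors come from a PDB file
(`read_nh_vectors()`, first model by default); residues without an amide
proton are skipped, never rebuilt.

`fit_modelfree()` fits the standard five parameterisations per residue —
(1) S²; (2) S², τ_i; (3) S², R_ex; (4) S², τ_i, R_ex; (5) extended
Sf², Ss², τ_s with S² = Sf²Ss² — and selects by a conservative complexity
ladder: the simplest tier whose χ² passes the α = 0.05 critical value for
its residual degrees of freedom is accepted; ties within a tier break by
AIC; if no model passes, the best three-parameter fit is returned with
`selected = FALSE`. The fits exploit the structure of the problem: R_ex
enters R₂ linearly and is profiled in closed form; the remaining searches
are nested 1-D optimisations over bounded transformed parameters (S² ∈
[0,1], τ_i < τ_c). Known single-field identifiability limits apply: R_ex
and τ_i are partially confounded with three observables at one field, and a
residue with *both* slow internal motion (extended spectral density) and
exchange cannot be fully resolved — the ladder then absorbs part of R_ex
into model-4/5 parameters. R_ex values are reported at the measurement
field with no B₀² rescaling. `scale_tc_viscosity()` rescales a 293 K
hydrodynamic τ_c by the water-viscosity ratio (0.653/1.002 mPa·s for
313 K/293 K by default).

## Synthetic data and what the tests show

`make_profile()` builds seeded ground-truth profiles whose defaults encode
the study conditions the pipeline is validated against:

- `free_rrm1_like` (120 residues, τ_c = 6.5 ns, isotropic): rigid core
  (S² ∈ [0.85, 0.95], τ_i ∈ [10, 50] ps), flexible termini described by the
  extended model (Sf² ∈ [0.75, 0.9], S² ∈ [0.3, 0.7], τ_s ∈ [0.5, 2] ns), a
  β4-like exchange group (k_ex drawn in [800, 1000] s⁻¹, p_b = 1 %) and a
  C-terminal helix-coil group (k_ex ∈ [750, 950] s⁻¹, p_b = 0.3 %), shift
  differences 1.5–4 ppm;
- `bound_rrm1_like` (τ_c = 11.8 ns, D∥/D⊥ = 1.26 axial): quenched termini
  and a fast interface group (k_ex = 7000 s⁻¹, p_b = 3 %, Δω 0.5–2 ppm);
- `uniform_rigid`: S² = 0.9 everywhere, no exchange.

Generators emit every observable the readers consume: rate tables, CPMG
curves (optionally as constant-time intensity pairs; default ν_CP grids are
16 constant-time-compatible values spanning 25–750 Hz at 750 MHz and
31.25–750 Hz at 900 MHz, with T = 80/64 ms), spin-lock curves, and
RCZZ/η_xy/R₁ intensity tables. Noise is independent Gaussian per point
(fractional for rates, absolute for NOE and R₂eff) — no baseline artifacts,
peak overlap, or temperature drift; passing recovery tests therefore
demonstrates estimator correctness under the stated error model, not
robustness to spectral pathologies.

Problem sizes used by the recovery tests (chosen to emulate the study
designs at full fidelity while keeping each experiment to a few seconds):
4-residue two-field global CPMG sets at σ = 0.4 s⁻¹ over 20 seeds;
11-site joint ¹⁵N/¹³C spin-lock sets (3 % noise, 20 seeds); 120-residue
model-free maps over 20 seeds; 50-vector tensor fits (1 % noise, 20 seeds).
Recovery is asserted on seed-ensemble means; single noisy datasets of this
size genuinely cannot pin k_ex to 10 % (the χ² surface is flat over a
factor ~2 at σ = 0.4 s⁻¹ and p_b = 0.3 %), and the per-seed spread the
tests tolerate reflects that, matching the ± uncertainties such fits carry
in practice.

## Oracle tolerances

The closed forms are validated against independent Bloch–McConnell
propagators (a complex 2×2 pulse-train propagation for CPMG; the
slowest-decaying eigenmode of the 6×6 spin-lock matrix for R1ρ) on a grid
of regimes. Detection in the CPMG oracle follows the spectroscopy: for
resolved resonances (|Δω| > 2 k_ex, slow exchange) the major-state peak is
monitored; otherwise the coalesced total magnetisation. Measured maximum
deviations (p_a = 0.97, 750 MHz):

| regime (k_ex, s⁻¹) | Δω = 0.5 ppm | 2 ppm | 4 ppm |
|---|---|---|---|
| slow (200) | 0.4 % | 0.8 % | 0.6 % |
| intermediate (2000) | 0.1 % | 0.3 % | 0.2 % |
| fast (20000) | <0.1 % | <0.1 % | <0.1 % |

tested at 2 %. The fast-exchange R1ρ expression is compared over its
validity domain (k_ex ≥ 3000 s⁻¹, Δω ≤ 1 ppm, ω_eff/2π = 200–3000 Hz),
where deviations stay below 0.3 % (tested at 3 %); outside the fast regime
the expression is not applicable and is not used by the fitters.

## Interfaces

Tables are TSV with header-driven columns (units documented in the
readers); configuration is a single YAML file round-tripped by
`read_config()`/`write_config()`, with every filter threshold and fit
option reachable from it. The package's function surface — generators,
readers, fitters, `tidy()`/`glance()` accessors and `autoplot()`/
`plot_modelfree()` figures — is the intended interface for scripted
pipelines; no shell entry point is shipped.

## Known limitations

- Two-site exchange only; no three-site or unequal-R₂ general models, no
  Arrhenius (temperature-dependent) global fitting.
- Off-resonance R1ρ outside the fast regime is out of scope.
- CSA is treated as axially symmetric (η = 0); no quadrupolar or
  remote-dipole mechanisms; ¹³C is an effective two-spin pair.
- Single-field model-free fitting with its stated identifiability limits;
  no multi-field simultaneous fits and no rhombic diffusion tensors.
- Interleaving/temperature-drift corrections are assumed done upstream;
  inputs are peak heights.
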