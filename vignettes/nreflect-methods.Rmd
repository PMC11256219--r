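---
title: "Modelling floating protein-lipid membranes with nreflect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling floating protein-lipid membranes with nreflect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nreflect)
```

## The measurement and the model

Specular neutron reflectometry (NR) measures the reflectivity $R(Q_z)$ of an
interface as a function of momentum transfer $Q_z = 4\pi\sin\theta/\lambda$.
$R(Q_z)$ is determined by the depth profile of the coherent scattering length
density (SLD, $\rho(z)$, units of $10^{-6}\,\mathrm{\AA}^{-2}$), so fitting a
parameterised $\rho(z)$ to measured curves resolves the out-of-plane
structure of a layered interface with sub-nanometre sensitivity.

`nreflect` models one specific and fairly elaborate interface: a
self-assembled *floating* protein-lipid membrane held above a
carboxyl-terminated oligoethyleneglycol self-assembled monolayer
(COOH-OEG-SAM) on a gold-coated silicon substrate, immersed in aqueous
buffer. The neutron beam enters through the silicon block (inverted
solid-liquid geometry), so the slab stack runs

> Si | SiO$_2$/permalloy mix | permalloy | gold | SAM |
> [water interlayer | inner protein | inner heads | tails | outer heads |
> peripheral protein] | bulk solvent

with the bracketed part present only after membrane deposition. Every layer
is described by its thickness, its interfacial roughness, and the volume
fractions of the components occupying it, with water filling the unoccupied
remainder; the component fractions of a layer may not exceed 100%. SLDs of
composite layers are volume-fraction-weighted means (`layer_sld()`), which
is what couples one structural model to its four isotopic-contrast
realisations.

### Contrast variation and co-refinement

Measuring the same structure in several H$_2$O/D$_2$O mixtures (100% D$_2$O;
gold-matched water, AuMW, 75% v/v D$_2$O; protein-matched water, PrMW, 42%
v/v D$_2$O; 100% H$_2$O) gives curves that weight the same unknowns
differently. The package fits all of them *simultaneously*: one shared set
of under-layer parameters (substrate through SAM), one membrane model per
solution condition, and per-dataset scale/background nuisance parameters.
Bare-surface datasets measured before deposition join the same fit and pin
down the under-layers. The objective is
$\chi^2 = \sum_\mathrm{datasets}\sum_i \left((R_{\mathrm{model},i} - R_i)/\mathrm{d}R_i\right)^2$,
and each dataset is always evaluated on its own $Q$ grid — grids are never
interpolated onto each other.

### Labile-hydrogen exchange

Materials with exchangeable hydrogens (protein, lipid headgroups, the SAM
carboxyls) carry separate H$_2$O and D$_2$O endpoint SLDs, interpolated
linearly in the solvent D$_2$O volume fraction. This assumes complete,
instantaneous exchange — the standard assumption. The default SLD table
(`default_materials()`) uses conventional literature values (Si 2.07,
SiO$_2$ 3.47, permalloy 8.5, Au 4.5, SAM 0.3/0.6, lipid heads 1.85/1.92,
lipid tails $-0.4$, hydrogenous protein 1.9/3.2); every number is
user-overridable because reasonable laboratories differ on several of them.
Water endpoints are $-0.56$ and $+6.36$, the standard measured-density
values. Absorption (imaginary SLD) is neglected throughout: it is
negligible for these isotopes at cold-neutron wavelengths.

## The reflectivity kernel

`abeles_reflectivity()` implements the Abelès optical transfer-matrix
recursion for a slab stack (compiled code; media are non-absorbing, so each
normal wavevector is purely real or purely imaginary and the hot loop
avoids complex transcendentals). Two roughness treatments are provided:

* **Névot–Croce** damping of the interfacial Fresnel coefficients — fast
  and accurate while every roughness is small relative to the adjacent
  layer thicknesses;
* **microslicing** — the erf-broadened SLD profile is discretised into thin
  uniform sub-slabs (default 1 Å) of zero roughness. Each slice takes the
  *exact mean* of the profile over its extent (via the antiderivative of
  the normal CDF), and runs of slices lying within `merge_tol`
  (default 0.005 × 10⁻⁶ Å⁻²) of a common mean are merged into single
  uniform slabs. Merging is exact on plateaus and introduces $O(\mathrm{tol})$
  error on gradients; it cuts the slab count several-fold.

Microslicing is the reference path and is selected automatically
(`engine = "auto"`) whenever any roughness reaches one third of an adjacent
thickness. That regime is not hypothetical here: the strongly fluctuating
EDTA state has a bilayer roughness of ~68 Å against 8–30 Å membrane layers,
far outside Névot–Croce validity. The two treatments agree to better than
$10^{-3}$ relative in the small-roughness regime (σ ≈ 2 Å against 40–60 Å
layers, fine slicing), which the test suite checks against the closed-form
Fresnel curve and a brute-force convolution oracle.

Instrument resolution is applied as a Gaussian convolution in $Q$ with
FWHM $= (dQ/Q)\,Q$ — the time-of-flight convention, $\sigma =$ FWHM/2.355 —
at the 3.5% typical of white-beam reflectometers. The forward model
(`reflectivity_smeared()`) evaluates the kernel exactly at 21 quadrature
nodes spanning $\pm 3.5\sigma$ per data point; `smear_gaussian()` offers the
same convolution for already-sampled curves.

## Volume-fraction profiles

`component_profile()` renders the structure as per-component occupancy
versus depth on a 1 Å grid: each layer contributes an erf-edged boxcar
(edge width = the interface roughness), adjacent layers share interfaces
exactly so occupancy telescopes, and water is defined as the unoccupied
volume — the fractions therefore sum to one at every grid point by
construction, which the tests assert across randomised structures.
`sld_profile()` contracts this profile with the per-component SLDs at a
chosen contrast and is identically the profile the microslicing path
discretises.

The headline derived quantity is `membrane_to_sam_distance()` — the
thickness of the pure-water interlayer between the SAM and the inner
headgroups, the quantity tuned by the solution's divalent/monovalent cation
balance (≈11 Å in 2 mM Ca²⁺, ≈26 Å with 200 mM Na⁺ added, ≈132 Å in EDTA).

## Fitting and uncertainty

The optimisation follows the genetic + least-squares workflow standard in
reflectometry software: a rand/1/bin differential-evolution global stage
(`fit_global()`; population 15 × n by default, F = 0.8, CR = 0.9, bounded)
followed by a bounded quasi-Newton polish (`fit_local()`, which never
accepts an increase in $\chi^2$). Every stochastic stage takes an explicit
integer seed and is reproducible.

Uncertainty is quantified by Delayed-Rejection Adaptive Metropolis MCMC
(`run_dram()`) on $\exp(-\chi^2/2)$ with uniform priors on the parameter
bounds. The proposal covariance adapts every 100 steps to the running chain
covariance (scaled $2.4^2/d$); a rejected first-stage proposal triggers a
second-stage proposal scaled down by 1/5 with the standard
delayed-rejection acceptance ratio. The first 25% of each chain is
discarded as burn-in (configurable). Parameter uncertainties are *shortest
65% percentile intervals* — the narrowest contiguous window of sorted
posterior draws holding 65% of them (leftmost on ties) — and curve/profile
uncertainties come from resampling draws from the chain (1000 by default),
recomputing reflectivities and profiles per draw, and taking pointwise
shortest intervals; the reported best-fit line is the *mean of the sampled
curves*, not the curve at the posterior mean.

Numerical details worth knowing: the initial proposal standard deviation is
2% of each bound range (`init_scale`); a chain that never moves raises an
error with guidance rather than returning silently; chains are persisted as
plain TSV by the pipeline.

## The synthetic-data generator

The measured beamline curves behind the resolved structures have no
machine-readable deposition, so the package carries a first-class
generator that emulates the two time-of-flight reflectometers used
(`instrument_spec()`): SURF (0.5–7 Å wavelengths; 0.35°/0.65°/1.5°) and
INTER (1–16 Å; 0.7°/2.3°), both at $dQ/Q$ = 3.5%, reduced onto 150
log-spaced bins over 0.009–0.3 Å⁻¹ — a typical reduction output.

Counting statistics are modelled as
$N_\mathrm{eff}(Q) = A\,(Q/Q_0)^{-p}$ with $A = 10^6$, $p = 2$,
$Q_0 = 0.003\,\mathrm{\AA}^{-1}$, and
$\mathrm{d}R = R/\sqrt{N_\mathrm{eff}}$, $R_\mathrm{obs} \sim
\mathcal{N}(R_\mathrm{model}, \mathrm{d}R)$. These values put the relative
error near 0.3% on the total-reflection plateau and near 10% at the high-$Q$
end, matching figure-quality beamline data; they are declared stand-ins (the
true run statistics are unpublished) and are configurable. By construction
$E[\chi^2] = N$ at the generating truth, which the tests verify over 100
seeds.

Ground-truth structures are the published ones: the calcium-state membrane
(SAM 25 Å at 92% coverage; interlayer 11 Å; heads 8 Å with 42% lipid / 24%
protein; tails 30 Å with 61% lipid / 24% protein; peripheral protein
50.5 Å at 13%; bilayer roughness 7 Å, peripheral 16.5 Å) and its
salt-shifted variants (interlayer/roughness 26/16 Å with added NaCl, 132/68
Å in EDTA). Two generator choices are the package's own: the under-layer
thicknesses (SiO₂/permalloy mix 12 Å, permalloy 120 Å, gold 90 Å, roughness
3–5 Å — realistic sputtered-film values; the published tables do not list
them), and the EDTA-state peripheral roughness, which is raised to the
bilayer value of 68 Å since the height fluctuation of a floating membrane
at 130 Å affects the whole stack. The inner-protein layer is retained as an
optional layer defaulting to zero thickness: in the resolved structure the
protein asymmetry is carried entirely by the peripheral layer. Inner and
outer headgroups are constrained symmetric by default (the resolved values
are identical); asymmetry is available behind `symmetric_heads = FALSE`.

`make_condition_series()` reproduces the full 14-dataset measurement design
(bare surface in two contrasts, then four contrasts per salt condition);
`recovery_harness()` wraps simulate → fit → (optionally) DRAM across
replicates and tabulates bias, RMSE and interval coverage — the package's
calibration surface.

### What passing the synthetic round-trips does and does not show

The generator shares the forward model with the fit, so round-trip tests
validate the inference machinery (identifiability of the co-refinement,
optimiser competence, interval calibration) under exactly-specified
conditions. They do not probe model misspecification as real data would:
in-plane inhomogeneity, imperfect backgrounds, reduction artefacts and
wavelength-dependent resolution are all absent. Conclusions about real
membranes still require measured curves.

## Problem sizes and fit settings used by the shipped checks

The acceptance computations use the full 150-point, 6- or 4-dataset
problems with default noise, differential evolution at population 16–20 for
20–25 generations plus a local polish; these recover the calcium-state
headline parameters (tails thickness, interlayer, SAM coverage, tails lipid
fraction) within the published 65% interval widths, and the salt-condition
membrane-to-SAM distances of 26 Å and 132 Å likewise. Statistical
calibration runs on deliberately smaller problems (two contrasts, 50-point
grids, Névot–Croce engine, two free parameters, ~1000-step chains, ≥20
replicates) where the analytic posterior or the nominal 65% coverage is the
oracle. DRAM chains in examples are short (hundreds to thousands of steps);
production analyses should use longer chains and inspect the traces
(`autoplot()` on a posterior).

## QCM-D support calculations

The companion quartz-crystal-microbalance analysis needs two closed forms.
The shear-wave penetration depth
$\delta = \sqrt{\eta/(\pi\,\rho\,f_0\,n)}$ sets the depth sensitivity of a
QCM-D sensor at overtone $n$ — with water at 38 °C
($\eta = 0.681$ mPa·s, $\rho = 992.6$ kg·m⁻³; standard-table values, the
package default) and $f_0 = 5$ MHz this gives ≈120/94/79 nm for overtones
3/5/7, comfortably spanning the membrane-to-surface distances above. The
Sauerbrey relation $\Delta f_n = -m_A/C$ ($C = 17.7$ ng·cm⁻²·Hz⁻¹ at 5 MHz)
converts areal mass to overtone-normalised frequency shift; ~478 ng·cm⁻²
(a typical lipid bilayer) gives ≈ −27 Hz. Full viscoelastic (Voigt-type)
modelling of dissipation traces is out of scope.

## Known limitations

* Slab models average in-plane: lateral structure appears only through
  effective volume fractions and roughness.
* Névot–Croce results are silently wrong at large σ/thickness; prefer
  `engine = "auto"` (or `"microslice"`) unless speed matters and the
  regime is known to be safe.
* The noise model is a two-parameter power law, not a virtual instrument:
  no gravity, detector efficiency, or reduction pipeline.
* Uniform priors on bounds make the posterior sensitive to deliberately
  tight bounds; bounds should be physical, not decorative.
* The DRAM sampler is single-chain; multimodal posteriors need external
  diagnostics (run several seeds and compare).

```{r example, eval = FALSE}
# A compact end-to-end run (reduced sizes; see README for the full example)
series <- make_condition_series(seed = 1,
                                instrument = instrument_spec("INTER",
                                                             n_bins = 60))
vary <- tibble::tibble(name = "membranes.Ca.interlayer_thickness",
                       lower = 2, upper = 30)
pr <- fit_problem(dplyr::filter(series$data, condition %in% "Ca"),
                  series$under, series$membranes["Ca"], vary = vary)
fit <- fit_corefine(pr, seed = 2, generations = 20)
post <- run_dram(fit$problem, n_steps = 2000, seed = 3)
tidy(post)
```
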