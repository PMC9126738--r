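---
title: "Fitting A/ci curves by limitation-state enumeration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting A/ci curves by limitation-state enumeration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatphys)
```

## The model

`wheatphys` analyses leaf CO2-response (A/ci) curves with the
Farquhar–von Caemmerer–Berry (FvCB) model of C3 photosynthesis. Net
assimilation is the minimum of up to three limitation branches evaluated at
the CO2 partial pressure at the carboxylation site:

* **Rubisco-limited (C):** `A = Vcmax (c - G*) / (c + Km) - Rd`, with
  `Km = Kc (1 + O/Ko)`;
* **RuBP-regeneration-limited (J):** `A = J (c - G*) / (4c + 8G*) - Rd`;
* **TPU-limited (P):** `A = 3 Tp - Rd`, constant in `c`.

All CO2 quantities are partial pressures in Pa, O2 in kPa, rates in
µmol m⁻² s⁻¹. `G*` is the photorespiratory compensation point, `Rd` day
respiration, `Vcmax` the maximum carboxylation rate, `J` the electron
transport rate and `Tp` the triose-phosphate utilization rate.

Two conventions in the J and P branches are genuinely open choices and are
fixed here as documented constants. The electron stoichiometry uses the
NADPH-limited denominator `4c + 8G*`; the ATP-limited alternative
`4.5c + 10.5G*` is available via `j_stoich = "atp"` in `fvcb_params()`. The
TPU branch is the simplest admissible form `3Tp - Rd`, with no
glycolate-export (alpha) term; where TPU limitation is expressed in wheat
flag leaves this form describes the high-CO2 plateau well, and adding an
alpha term would make `Tp` unidentifiable on typical 16-point curves.

Kinetic constants are temperature-corrected with the Arrhenius relation
`k(T) = k25 exp[Ea (T - 25) / (R 298.15 (T + 273.15))]`, evaluated at the
curve's mean leaf temperature; fitted rates are reported both at leaf
temperature and normalized back to 25 °C by the inverse factor. `Tp` is
reported unnormalized (no activation energy is assumed for it). Two named
constant sets ship with the package: a wheat-derived in vivo set (the
default, `wheat_constants()`; its `source_label` marks it as a
reconstruction from the published wheat temperature-response literature)
and a tobacco-derived set (`tobacco_constants()`) as a widely used
fallback. Every fit records which set produced it.

### Mesophyll conductance

Three parameterizations are supported: `gm_mode = "infinite"` (the default;
`gm` is set to 1e6 µmol m⁻² s⁻¹ Pa⁻¹ so the chloroplast sees `ci`
directly), a fixed finite value (5.5 µmol m⁻² s⁻¹ Pa⁻¹ is the conventional
wheat figure), and a fitted `gm`. Under finite `gm` each hyperbolic branch
is solved analytically through the drawdown quadratic obtained by
substituting `cc = ci - A/gm` (the Ethier-type formulation), not by
fixed-point iteration; this is exact and deterministic. Rates fitted with
infinite `gm` are *apparent* rates: refitting a finite-`gm` truth under
infinite `gm` systematically yields `Vcmax` at or below the true value, a
property verified on every run of the acceptance script.

## The fitting procedure

Limitation states must appear in the order C → J → P along the ci axis.
The fitter enumerates **every** contiguous, order-respecting assignment of
sorted observations to a non-empty subset of states, with at least 2
observations per present state (`min_per_state`, the minimum that
identifies a slope-like parameter with `Kc`, `Ko`, `G*` held fixed) and
`n ≥ parameters + 1` overall, so single-state fits need three points.

For a given assignment the objective is the plain sum of squared residuals
of the assigned branch models with shared `Rd`. Inadmissible fits —
assignments whose own fitted model does not make the assigned branch the
pointwise minimum at every observation (tolerance 1e-6 µmol m⁻² s⁻¹) — are
rejected outright rather than penalized. Under infinite `gm` every branch
is linear in its parameter and in `Rd`, so the per-assignment optimum is
computed in closed form by linear least squares; this is an exact global
minimum and makes the exhaustive search cheap (a 16-point C/J/P enumeration
is 108 assignments). Under finite or fitted `gm` the problem is nonlinear
and a deterministic multi-start Nelder–Mead search is used, seeded from the
infinite-`gm` solution and a fixed grid spanning the physiological ranges
(Vcmax 20–400, J 40–600, Tp 3–40, Rd 0–5 µmol m⁻² s⁻¹, gm 0.5–50
µmol m⁻² s⁻¹ Pa⁻¹). Identical inputs always give identical results.

The lowest-cost admissible assignment wins; ties within 1e-8 go to fewer
states, then to fits with positive `Rd`, then to enumeration order.
Negative fitted `Rd` is flagged (`rd_positive`), not rejected. Finally,
boundary observations whose two adjoining branch rates differ by less than
`tol_colimit` (default 0.5 µmol m⁻² s⁻¹; the co-limited "swinging points")
are reassigned to the adjacent state and refitted, keeping the best
admissible result — a monotone, usually idle refinement, since every
reassignment is itself a member of the enumerated family.

Panel mode — used for screens where not every line expresses TPU
limitation — is the same engine restricted to `states = c("C", "J")`.

The closed-form transition points follow from equating branches:
`ci_cJ = (J Km - 8 G* Vcmax) / (4 Vcmax - J)` and
`ci_JP = G* (J + 24 Tp) / (J - 12 Tp)` (absent when non-physical or when
`J ≤ 12 Tp`); the observed compensation point on the Rubisco branch is
`Gamma = (G* Vcmax + Rd Km) / (Vcmax - Rd)`.

A fluorescence diagnostic (`phi_psii_diagnostic()`) locates the ci at which
Phi_PSII stops rising (first 3-point window with slope below 0.002 Pa⁻¹)
and reports its distance from the fitted `ci_cJ`; it never alters the fit.

## Derived traits

Stomatal limitation uses the Farquhar–Sharkey convention:
`Ls = (A0 - Aop)/A0` with `A0` the fitted model evaluated at `ci = ca` of
the operating log. The operating point defaults to the steady-state record
logged immediately before the CO2 ramp (the first acquisition), and is
configurable to any row; which side of the ramp to use is an open
convention and pre-ramp is chosen here as the less perturbed state.
`iwue()` is `A/gs` (µmol CO2 per mol H2O; `gs` strictly in mol m⁻² s⁻¹),
`j_v_ratio()` requires both rates at a common reference temperature,
`per_nitrogen()` is an exact elementwise division by `Narea`, and
`yield_components()` implements `GM2 = (GY/TGW) × 1000` and
`biomass = GY/HI`. `operating_rates()` extracts A at the 500 and 1800
µmol m⁻² s⁻¹ PAR set-points of a light-response table with ±10% matching.

## The statistics stage

`tukey_filter()` removes values beyond 1.5 IQR from the quartiles, with
quartiles by linear interpolation between order statistics (R's type 7);
Tukey's hinges differ slightly and the interpolation convention is
documented rather than assumed. `compare_two_lines()` runs the
Shapiro–Wilk / F-test / t-test cascade: a pooled two-sided t-test when the
F-test does not reject variance homogeneity at 0.05, Welch otherwise, with
degenerate (zero-variance) groups flagged and given `p = NA`.
`adjusted_genotype_means()` fits `trait ~ genotype + covariate` per
environment as a fixed-effect model, keeps a covariate only when its
coefficient is significant at 0.05, and returns genotype least-squares
means; the random year/block/replication machinery of multi-environment
trial analysis is deliberately out of scope and every output says so.
`correlation_matrix()` gives pairwise-complete Pearson r with two-sided p
from the t distribution, raw by default (Holm adjustment behind a flag),
with `r = NA` for pairs with fewer than 3 complete observations.

## What the generators emulate — and what they do not

`generate_aci_curve()` reproduces the measurement protocols of the two
instrument series: the 16-point sequence 43, 35, 27, 20, 15, 5 then 43–95
Pa, and the 11-point sequence 40, 30, 20, 10, 7 then 40–120 Pa, both at
PAR 1500 and 25 °C. For each step, ci is solved self-consistently from the
diffusion supply `A = gc (ca - ci)` with a logistic stomatal decline
(`gs_logistic()`; defaults 0.46 → 0.26 mol m⁻² s⁻¹ around 60 Pa, chosen
once so that the operating ci at 43 Pa ambient falls near 28–31 Pa and the
highest step reaches ci ≈ 65–70 Pa, the magnitudes flag leaves actually
show). Noise is additive homoscedastic Gaussian on A (default protocol
noise 0; the stochastic studies use 0.5 µmol m⁻² s⁻¹); Phi_PSII is emitted
proportional to the electron transport actually used. The generator does
not emulate instrument drift, leaks, match offsets, heteroscedastic noise
at low flow, or leaf patchiness — so passing round trips demonstrate
correctness of the estimator, not robustness to every artefact of real
logs.

`generate_panel()` draws per-trait genotype effects for 80 lines plus one
check from a bivariate normal shared across environments with per-trait
cross-environment correlation (defaults: 0.6 for agronomic traits, 0 for
photosynthetic ones — the qualitative field-vs-glasshouse pattern the
package is designed to analyse), adds replicate noise (4 replicates per
environment), and computes GM2 and biomass from the identities so internal
consistency is exact. `generate_variant_table()` plants SNP sites at a
chosen density and forces the second sample to match the first with the
region's IBS probability; near-inbred material is emulated with a 2% het
rate. A synthetic panel has no linkage, population structure or shared
ancestry beyond the planted profile.

## Identity-by-state binning

Sites pass the variant filter when their missing-call fraction is strictly
below 0.10 and minor allele frequency strictly above 0.05 (strict, to
mirror "<10%" and ">5%" filter statements; the boundary sites are
excluded). A site is IBS when both calls are non-missing and identical
(het matches only het) — the near-inbred default; an allele-sharing
0/0.5/1 scoring is available with `mode = "allele"`. Bins are half-open
5 Mbp windows on 0-based coordinates, terminal short bins kept, chromosome
lengths from VCF contig headers (else the maximum observed position), and
empty bins report `fraction = NA`. `chromosome_summary()` reports the
percentage of non-empty bins above/below the 0.90/0.20 similarity
thresholds.

## Numerical choices and problem sizes

Tolerances: branch-rate admissibility 1e-6 µmol m⁻² s⁻¹; co-limitation
0.5 µmol m⁻² s⁻¹ (configurable; no published value exists for it);
cost ties 1e-8; transition closed forms agree with root finding to well
below 1e-6 Pa. Degenerate inputs are handled explicitly: pure-TPU
assignments are rank-deficient (Tp and Rd confounded) and flagged invalid;
`Vcmax ≤ Rd` has no compensation point; curves need at least 4 points.

The validation studies run at sizes chosen to characterise the estimator
well while remaining quick to reproduce: 50 small curves for the
brute-force assignment oracle, 200 noisy replicates for stochastic
recovery, 1000 random parameter sets for the closed-form checks, 100
curves for the apparent-Vcmax property, 1000 fixtures for the statistics
oracles. The 16-point, three-state enumeration is 108 assignments and fits
in ~60 ms.

## Known limitations

No peaked (deactivation) temperature response; C3 only; no bootstrap or
Bayesian uncertainty on fitted parameters; no co-fitting of
fluorescence-derived J; the light-response module only extracts set-point
rates; adjusted means are fixed-effect only; IBS binning assumes biallelic
sites and performs no imputation or phasing.
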