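---
title: "Allosteric kinetics of membrane-bound pyrophosphatases: models, fitting and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allosteric kinetics of membrane-bound pyrophosphatases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppasekin)
```

## The problem

Membrane-bound inorganic pyrophosphatases (mPPases) couple the hydrolysis
of pyrophosphate (PPi) to H⁺ or Na⁺ pumping. Two well-studied
representatives are a plant vacuolar H⁺-PPase (here labelled AVP1 in the
examples) and an archaeal Na⁺-PPase (MVP). Their hydrolytic activity is
assayed on microsomal membranes as µmol PPi·min⁻¹·mg⁻¹ protein (U/mg),
titrating substrate in the presence of 100 mM KCl (both enzymes require
K⁺) and 0–100 mM added NaCl. Three analysis steps recur in this kind of
study and are what this package implements:

1. **Speciation.** The true substrate is not total PPi but the
   magnesium complex Mg₂PPi. Given the totals of PPi, Mg, K and Na and the
   pH, the equilibrium concentration of Mg₂PPi must be computed from the
   stepwise dissociation constants of the PPi complexes.
2. **Rate laws.** Saturation curves are sigmoidal. They are described
   empirically by the Hill equation and mechanistically by a two-state
   concerted (MWC-type) allosteric law.
3. **Weighted fitting.** Replicate rates (3–5 independent experiments per
   point) are averaged, each mean point is weighted by the reciprocal of
   its replicate variance, and the rate law is fitted by weighted
   nonlinear least squares with asymptotic standard errors.

A synthetic-data generator reproduces the two experimental designs so that
the whole pipeline can be exercised and calibrated without access to raw
assay data.

## Speciation model

At fixed pH (the assay is buffered at pH 7.2, so [H⁺] is an input, not an
unknown) and with K⁺ and Na⁺ in ≥100-fold excess over PPi (their free
concentrations are taken equal to their totals), the system reduces to two
unknowns: free PPi and free Mg²⁺. Every complex concentration follows from
mass action, e.g. [Mg₂PPi] = [Mg]²[PPi] / (K_MgPPi · K_Mg2PPi) for the
stepwise constants. Free PPi is then available in closed form given free
Mg, and the remaining Mg mass balance is a strictly increasing function of
free Mg on [0, total Mg]; `speciate()` solves it by safeguarded Newton
iteration with a bisection fallback (default relative tolerance 1e-10,
200-iteration cap, typed solver error on failure) and verifies both mass
balances on return. Uniqueness follows from monotonicity.

The dissociation constants themselves are conditional constants at assay
ionic strength; no activity-coefficient model (Davies/Debye–Hückel) is
applied, and no temperature correction. The shipped defaults
(`ppi_constants()`, mirrored in `inst/extdata/ppi_complex_constants.tsv`)
are a stand-in compiled from standard values for PPi protonation (pKa
8.94, 6.13) and its Mg/K/Na complexes; they are deliberately easy to
override (`read_constants()`), and analysis results embed the constants
actually used. Protonation entries may be given as pKa; the conversion is
`kd_mM = 10^(3 - pKa)`.

One property worth stating precisely: [Mg₂PPi] increases with total Mg and
decreases with total Na (which sequesters PPi as NaPPi), but it is *not*
globally monotone in total PPi at fixed Mg — once PPi exceeds the Mg pool,
additional ligand chelates Mg²⁺ and the Mg₂PPi concentration falls. This
is the same excess-PPi regime in which the enzymes show apparent substrate
inhibition, and it is why monotonicity in total PPi is only asserted (and
only holds) while Mg remains in excess.

## Rate laws

The empirical description is the Hill equation,

$$v = \frac{V_m\,S^{n_H}}{K_{0.5}^{n_H} + S^{n_H}},$$

with the standard reading of the "empirical Hill equation" since no
explicit functional form accompanies that phrase in common usage notes;
`n_H = 1` is the Michaelian limit.

The mechanistic description is a two-state concerted model for a
homodimer: active R and inactive T conformers in equilibrium
L = [T]/[R]; substrate (Mg₂PPi) binds only to R, at two equivalent
catalytic sites, with dissociation constant K_R; and bound substrate also
displaces the conformational equilibrium toward R, represented by dividing
L by (1 + S/K_R)². With u = 1 + S/K_R the saturation function is

$$\hat{Y} = \frac{(S/K_R)(1 + S/K_R)}{(1+S/K_R)^2 + L/(1+S/K_R)^2}
         = \frac{u^4 - u^3}{u^4 + L},$$

and `mwc_saturation()` evaluates the right-hand form, which avoids the
nested quotient; the two forms agree to 1e-12 over the tested parameter
space. The rate is `v = vm * Yhat` — the proportionality constant between
v/Vm and Ŷ is fixed at 1 so that Vm is the true asymptote, which is how
Vm is tabulated in practice. L = 0 reduces exactly to Michaelis–Menten
with Km = K_R. The derivative numerator in u is u²(u⁴ + 4Lu − 3L), strictly
positive for u ≥ 1, so Ŷ is strictly increasing in S, and it is strictly
decreasing in L at fixed S > 0, bounded in [0, 1).

Units: substrate is handled in mM everywhere; K_R is accepted and reported
in µM (the scale on which R-state constants are usually quoted), with the
conversion confined to `mwc_rate()` and the fit-report boundary.

`effective_hill()` connects the two descriptions: it computes
log(81)/log(S₉₀/S₁₀) from the 10% and 90% saturation points of the
allosteric curve (root-finding on the strictly monotone Ŷ), giving the
apparent cooperativity implied by a given L. It is 1 at L = 0 and grows
with L; for example the low-salt H⁺-PPase parameters (L = 17, K_R = 84 µM)
imply n_eff ≈ 1.6, and the much larger L ≈ 615 of the Na⁺-PPase implies
n_eff ≈ 2.6 — the qualitative ordering seen in the corresponding Hill
coefficients.

## Aggregation, weighting and fitting

`aggregate_replicates()` reduces replicates to mean, unbiased sample
variance (n − 1 denominator) and count per substrate level. The default
weight is 1/(replicate variance). "1/variance" is ambiguous between the
replicate variance and the variance of the mean; the replicate-variance
reading is the default and `weights = "sem"` switches to the variance of
the mean (the two differ only by the factor n, so point estimates are
identical when replicate counts are balanced). Degenerate cases are never
silent: zero variances are replaced by the smallest positive variance in
the dataset with a typed warning, and single-replicate levels are an error
unless unit weights are requested.

`fit_model()` minimises the weighted residual sum of squares with bounded
Levenberg–Marquardt least squares (trust-region family), restarted from a
small data-driven grid: vm₀ = max mean rate, k₀ = substrate at half-max,
n_H ∈ {1, 2, 3, 5} or L ∈ {0, 10, 10³, 10⁵}. The best converged start wins
and ties go to the earlier start, making fits deterministic. Bounds keep
parameters on their natural scale (vm ≤ 10× max rate, K ≤ 10× max S,
n_H ∈ [0.5, 8], L ∈ [0, 10⁷]) rather than transforming them, so reported
values are directly comparable to published tables. Cost tolerance is
1e-10 with at most 500 iterations. Standard errors use the conventional
curvature estimate cov = s²(JᵀWJ)⁻¹ with s² = WRSS/(N − p) and a central
finite-difference Jacobian at the optimum; this makes both the estimates
and the standard errors invariant to rescaling all variances by a common
factor.

Apparent substrate inhibition above ~0.2–0.25 mM PPi cannot be described
by either saturation law, so `truncate_for_substrate_inhibition()` (or the
`truncate_max_s` argument) excludes the affected points before fitting and
records the threshold in the result. Published thresholds for the H⁺-PPase
differ between 0.2 mM and 0.175 mM depending on where they are quoted;
both are simply accepted as user inputs and the package does not privilege
either.

## Synthetic data: what it emulates and what it does not

`make_design()` reproduces the two layouts: matched-Mg titrations
(total Mg = 2 × total PPi per point, so the mixture is effectively a
Mg₂PPi stock) and fixed-Mg titrations (MgCl₂ at 1 or 2.5 mM with PPi up to
0.25 mM, guaranteeing free Mg²⁺ excess). Every point carries the basal
Na⁺ = 4 × PPi contributed by the tetrasodium PPi salt, plus the added NaCl
level, and 100 mM KCl at pH 7.2.

The default matched-Mg PPi grid (8 points, 0.1–1.25 mM total PPi) was
chosen once so that the speciated Mg₂PPi abscissa spans roughly
0.01–0.55 mM under the default constants — the range over which the
published saturation curves run from near-zero to near-plateau. Since only
the Mg₂PPi axis of such figures is public, the totals grid is necessarily
a package choice, and it is exposed as the `ppi_totals` argument.

`simulate_assay()` draws replicate rates as Gaussian noise around the
generating law with SD = CV × rate + floor. The defaults — 4 replicates
(midpoint of the 3–5 used experimentally), CV = 8%, floor = 0.005 U/mg —
were fixed to match figure-scale error bars and are configuration, not
test, values. Negative draws are redrawn rather than clipped, keeping the
mean unbiased at the cost of slight variance shrinkage when the true rate
is within a few SD of zero. Each (point, replicate) pair has its own
substream seeded from the point's ionic identity, so runs are bit-identical
under a fixed seed and subsetting a design does not change the draws of
shared points. The generator does not model day/batch effects,
heteroscedasticity beyond CV + floor, or the pumping (fluorescence-quench)
readout — so passing tests demonstrate correct *recovery under the assumed
noise model*, not robustness to structured experimental error.

## Pipeline conventions

`run_analysis()` groups records by enzyme, design mode, Mg level (fixed-Mg
mode) and NaCl level, computes the abscissa, aggregates, truncates, fits
the requested laws and summarises. The abscissa convention follows the
experimental logic: matched-Mg conditions are fitted against speciated
Mg₂PPi, fixed-Mg conditions default to total PPi (the axis on which such
titrations are plotted), with `abscissa = "speciated"` available as an
explicit override. Failed conditions are flagged and logged, not fatal.
Salt sensitivity is expressed as
`percent_decrease = 100 (1 - Vm_treated / Vm_0mM)` and reported both raw
and rounded to the nearest ten percentage points, the granularity at which
such numbers are usually quoted; fold changes (e.g. K⁺ activation) use
`treated/reference`. Display tables show estimate ± SE with the SE at two
significant figures; machine-readable output keeps full precision.

## Worked example

```{r example, eval = FALSE}
des <- make_design("matched_mg")
truth <- list(`0` = mwc_params(0.51, 17, 84),
              `50` = mwc_params(0.40, 50, 64),
              `100` = mwc_params(0.24, 106, 69))
recs <- simulate_assay(des, synthetic_config(truth, enzyme = "AVP1", seed = 11))
res <- run_analysis(recs, analysis_config())
format_parameter_table(res$parameter_table)
res$sensitivity
```

## Numerical choices and limitations

* **Problem sizes.** The shipped tests and the acceptance script use the
  study-scale designs directly: 8 substrate points × 4 replicates × 3 salt
  levels × 2 enzymes, with 20 simulation seeds for the recovery study and
  10,000 replicates for the noise-calibration check.
* **K_R/L trade-off.** At large L the allosteric curve approaches a
  threshold shape governed by the combination K_R·L^(1/4) more tightly
  than by K_R alone, so single-dataset K_R estimates are noticeably less
  precise than Vm (medians around 20–40% relative error at 8% assay CV,
  versus ≤10% for Vm). Published standard errors for such constants show
  the same pattern. L itself is recovered within a factor of ~2 (median)
  for true L between 10 and 1000; far outside that range (L ~ 10³–10⁴) the
  data contain little information about L beyond "large".
* **Weights from 4 replicates are noisy.** Sample variances with 3 degrees
  of freedom scatter over an order of magnitude, so 1/variance weighting
  adds variance to the estimates relative to unit weights on homoscedastic
  data. It is retained as the default because it is the convention of the
  studies this package mirrors.
* **Degenerate inputs.** Zero totals, zero-variance levels,
  single-replicate levels, empty designs and underdetermined fits all have
  typed errors or logged fallbacks; nothing is silently imputed.
* **Out of scope.** Non-exclusive T-state binding (MWC c ≠ 0), more than
  two catalytic sites, ionic-strength corrections, Ca²⁺ chelation,
  Bayesian/bootstrap uncertainty, model-selection statistics, global fits
  across salt levels, and fitting the substrate-inhibited region.
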