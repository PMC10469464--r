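---
title: "Methods: chemical activity-based trophic magnification of PFAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical activity-based trophic magnification of PFAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfastmf)
```

## The problem

Trophic magnification factors (TMFs) summarize whether a contaminant's
thermodynamic potential increases up a food web: the TMF is $e^m$ for the
slope $m$ of a regression of $\ln(\text{value})$ on trophic position (TP).
For legacy lipophilic pollutants the "value" is a lipid-normalized
concentration. Perfluoroalkyl acids (PFAS) break that convention: they sorb
to serum-type protein (albumin) and membrane phospholipids, barely at all
to storage lipids. Comparing wet-weight or lipid-normalized concentrations
across organisms whose protein and lipid content differ — and trend with
trophic position — conflates composition with biomagnification.

This package places concentrations on a thermodynamically comparable scale
before the regression, in six ways: apparent chemical activity, and
concentrations normalized to total protein, albumin, polar lipid, total
lipid, or left as wet weight (the baseline being critiqued).

## The model

**Sorptive capacity.** A sample is modeled as five phases with mass
fractions $\phi_{NL}, \phi_{PL}, \phi_{ALB}, \phi_{SP}, \phi_W$ (neutral
lipid, polar lipid, albumin, structural protein, water). With phase–water
distribution coefficients $D_{XW} = 10^{\log D_{XW}}$, the capacity of the
mixture relative to water is

$$\mathrm{cap} = \phi_{NL} D_{NLW} + \phi_{PL} D_{PLW} +
  \phi_{ALB} D_{ALBW} + \phi_{SP} D_{SPW} + \phi_W .$$

Residual mass (carbohydrate, ash) is excluded from the sum, not lumped into
water: the model enumerates exactly five phases. The fraction of chemical
mass in phase $i$ is $\phi_i D_i / \mathrm{cap}$, which sums to one by
construction (`mass_distribution()`).

**Apparent activity.** A wet-weight concentration $C_{ww}$ (ng/g) is
converted to mol/m$^3$ assuming tissue density $\rho$ (default 1 g/cm$^3$,
configurable; the choice cancels in any TMF because it multiplies every
sample identically), then

$$a = \frac{F \cdot C}{S_W \cdot \mathrm{cap}},$$

with $S_W$ the water solubility and $F$ the fugacity ratio. The exact
arrangement — $F$ times the dissolved-phase saturation ratio — follows from
the definition of activity for solids ($F \cdot C/S$) combined with the
water-relative capacity above. "Apparent" records two acknowledged
approximations: $S_W$ is used at its measurement temperature and the
$D_{XW}$ at theirs; no temperature correction is attempted because
predictive temperature relationships are not available for these phases.

**Fugacity ratio.** For a chemical solid at body temperature $T$,
$F = \exp(-\Delta S_{fus}/R \cdot (T_m/T - 1))$; $F = 1$ for
$T_m \le T$. $\Delta S_{fus}/R$ defaults to Walden's rule, 6.79, and is a
configurable parameter since calorimetric entropies are rarely available
for PFAS. Between the body temperatures used here (291 K for
poikilotherms, 313 K for birds) $|\ln F|$ changes by at most
$6.79\,T_m(1/291 - 1/313)$, under 1 log-unit for $T_m \le 500$ K — a
minor term, and one that cancels entirely in any single-species
comparison.

**QSPR for missing coefficients.** Long-chain homologues typically lack
measured $\log D_{XW}$. Missing values are predicted from ordinary
least-squares lines of measured $\log D$ on molar volume, fitted
separately per analyte class (PFCA vs PFSA) and phase. Plain OLS, no
weighting; measured values always take precedence; extrapolation beyond
the fitted molar-volume range warns but proceeds, since the interesting
long chains are exactly the ones outside the measured range. The fit
records its point count, residual sd ($n-2$ degrees of freedom, zero when
$n = 2$), and range.

**Censored regression.** Concentrations below the method limit of
quantification (MLOQ) are left-censored. Every TMF is estimated by
maximizing the censored Gaussian likelihood on the natural-log scale:
density terms for detects, $\Phi((\ln L_i - \mu_i)/\sigma)$ for
nondetects, $\mu_i = b_0 + m\,x_i$. Crucially, each sample's MLOQ is
transformed by *exactly the same per-sample constant* as its measurement
(activity conversion or fraction division), so censoring thresholds remain
consistent on the transformed scale.

**Trophic position.** Either supplied directly or derived from
$\delta^{15}N$ as $TP = TP_{base} + (\delta^{15}N -
\delta^{15}N_{base})/\Delta$ with enrichment $\Delta = 2.88$‰ per level by
default (a food-web-specific estimate treated as an input; deriving it is
out of scope). An explicit TP column takes precedence over
$\delta^{15}N$.

**Detection gate.** TMFs are computed only for analytes detected in more
than 60% of samples — a strict inequality, so 60.0% exactly is excluded.

## Why the schemes can agree, and when they cannot

Every scheme multiplies a sample's concentration by a positive per-sample
constant, so on the log scale the schemes differ by per-sample offsets. If
composition (and body temperature) were identical across samples, those
offsets would be constant and every scheme would give the *same* slope —
the scheme-equivalence identity, which the acceptance suite verifies to
1e-9 on such a dataset. Real food webs violate the premise: albumin and
lipid fractions trend upward with trophic position, so wet-weight TMFs
absorb the composition trend and overestimate biomagnification relative to
protein-normalized or activity-based TMFs. The generator's default
configuration reproduces this ordering (wet > total protein), and the
acceptance suite asserts its direction.

## The synthetic world

`generate_foodweb()` states a food web, it does not tune one:

* **n = 74 samples**, trophic positions evenly spaced over 1–4 with
  Gaussian jitter (sd 0.15), floored at 1. The sample size matches the
  regression degrees of freedom ($F_{1,72}$) of the terrestrial food-web
  study this design emulates.
* **Composition trends** (fractions per TP, defaults): albumin +0.96%,
  neutral lipid +0.93%, polar lipid +0.41%, structural protein +0.14%
  (total protein ≈ +1.1% minus albumin), water flat. Intercepts are chosen
  once so that fractions over TP 1–4 stay inside observed ranges (albumin
  ≈1.5–4.3%, neutral lipid ≈1.1–3.9%, polar lipid ≈0.5–1.7%, structural
  protein ≈1.2–1.8%, water 70%). Fractions are clipped to [0, 1] with the
  clip count reported, and a composition model that cannot produce valid
  samples is rejected at configuration time.
* **Body temperature** 291 K below TP 2.5 (invertebrate prey), 313 K above
  (birds).
* **Analyte truth**: activity-scale TMF, baseline activity at TP 0
  (default 1e-8, the order of magnitude implied by ng/g-level tissue
  concentrations over mol/m$^3$-scale solubilities and capacities of
  10$^2$–10$^3$), and log-scale residual sd 0.6 (slope standard errors at
  n = 74 then land near 0.1, typical of field TMF regressions). Activities
  are drawn log-normally around the true line and inverted through the
  activity equation per sample, so the generator exercises the exact
  inverse of the estimation path (round-trip exact to 1e-10).
* **Censoring**: the MLOQ is the empirical quantile of the drawn
  concentrations at the configured target (default 30%), so realized
  censoring matches the target by construction; an explicit per-analyte
  MLOQ can be supplied instead. Censored rows report the MLOQ as their
  value.
* **Bundled chemical table**: `chemicals_synthetic.csv` is a synthetic
  stand-in (realistic magnitudes and trends, not literature values):
  log $D_{ALBW}$ ≈ 3.6–4.8 rising with molar volume, polar-lipid affinity
  rising faster so it overtakes albumin for long chains, negligible
  neutral-lipid affinity. Shorter homologues carry "measured" values;
  longer ones are QSPR-predicted.

What a green test on this world establishes: the estimator recovers known
truth under the model's own assumptions (log-normal noise, linear
composition trends, a shared MLOQ per analyte). What it does not
establish: robustness to species-level composition error, non-lognormal
residuals, region-structured concentrations, or analytical bias between
laboratories — none of which the generator emulates (per-sample
composition noise exists as an option but is off by default; spatial
structure is deliberately absent).

## Numerical choices

* The censored MLE starts from OLS with censored values at their limits,
  optimizes $(b_0, m, \log\sigma)$ by BFGS with an analytic gradient, then
  Newton-polishes until the gradient is below 1e-11 so that algebraic
  identities (scheme equivalence) hold to machine precision rather than
  optimizer tolerance. $\sigma$ is floored at 1e-8; exactly collinear,
  uncensored data shortcut to the OLS line with $\sigma$ at the floor.
* Standard errors come from the observed information (numerically
  differentiated Hessian of the polished optimum); p-values are two-sided
  Wald by default with a likelihood-ratio alternative. 95% CIs are
  $e^{m \pm 1.96\,se}$.
* ROS uses Hirsch–Stedinger plotting positions with Weibull-type spacing,
  ties in limits processed together, imputation on the log scale from the
  OLS line of detects against normal quantiles. It refuses > 80% censoring
  and all-censored inputs. ROS (rather than a censored MLE or
  Kaplan–Meier mean) is the summary estimator implemented; which variant
  produced any given published table is generally unstated, so the choice
  is documented rather than asserted.
* In recovery experiments the relative bias of $\ln TMF$ is undefined at
  true TMF = 1 ($\ln TMF = 0$); the absolute bias of $\ln TMF$ is used for
  that analyte, on the same 0.05 scale. Coverage checks allow a 1e-9
  tolerance so the degenerate zero-noise CI (width zero at the exact
  slope) counts as covering its own truth.
* Samples non-normalizable under a scheme ($\phi = 0$) are dropped for
  that scheme only, warned about, and counted in the result record.
* `logd_sensitivity()` substitutes a coefficient globally (all samples at
  once) and reports percent change and CI overlap against a designated
  reference value, the appropriate default being a value measured at an
  environmentally relevant body temperature.

## Open design points, resolved

* QSPR fits accept any point set per class/phase and record its size and
  range; whether literature sources should be pooled or fit separately is
  left to the caller's table, not guessed.
* The pipeline supports TMFs on mass or molar scales; TMFs are invariant
  to the choice because molar conversion is a per-analyte constant.
* A `group` column is carried through the schemas; per-group fits are a
  straightforward subset operation left to the caller rather than a
  pipeline switch.

## Limitations

Distribution coefficients are used at their measurement temperatures; the
activity is "apparent", not absolute. The five-phase model ignores
speciation within tissues and assumes equilibrium partitioning. The
bundled property table is synthetic: any real analysis must supply
literature or measured properties via `read_chemicals()`.
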