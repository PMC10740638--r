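---
title: "Isobolographic analysis of antinociceptive drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isobolographic analysis of antinociceptive drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobolr)
```

## The problem

Two centrally acting analgesics given together may achieve their effect at a
much lower total dose than either alone — synergy — or merely add, or
interfere.  The classical way to decide is isobolographic analysis: estimate
each drug's ED50 in a behavioral assay, derive the total mixture dose that
*would* give the half-maximal effect if the drugs only added (Loewe
additivity), and ask whether the experimentally fitted mixture ED50 falls
significantly below that additive expectation.  `isobolr` implements this
chain for hot-plate antinociception data, together with the group-comparison
statistics used for chronic-pain (spinal nerve ligation, SNL) time courses,
and a seeded generator of synthetic datasets with the same structure.

## From latencies to %MPE

A hot-plate trial records the latency to a nocifensive response (paw licking
or jumping), with the animal removed at a fixed cutoff (35 s by default) to
avoid injury.  Latencies are normalized per animal to the percent maximum
possible effect,

$$\%MPE = 100\,\frac{\text{observed} - \text{control}}{\text{cutoff} - \text{control}},$$

where "control" is that animal's pre-dose baseline.  The transform is affine
in the observed latency, exactly 0 at baseline and exactly 100 at the cutoff.
Three conventions matter and are deliberate:

* **Negative %MPE is retained.**  An observed latency below baseline gives a
  negative score; the definition imposes no floor, and clamping at zero
  inflates low-dose means and biases ED50 upward.  `clamp_negative = TRUE`
  is available for comparison with analyses that did clamp.
* **Censored trials enter as 100%.**  A latency at the cutoff is a censored
  observation; it is scored exactly 100 and flagged.  A likelihood-based
  censoring model is out of scope — at the doses where censoring is common
  the curve is near its ceiling and the bias is small.
* **Time collapse.**  Latencies are recorded 5–120 min post-dose;
  dose–response fitting needs one number per animal × dose.  The default rule
  takes the 15-min reading (the time at which per-dose means are
  conventionally reported for this assay); a per-animal peak rule is the
  documented alternative.  Which rule a given historical analysis used is
  often unstated, so the rule is recorded in every fit object.

## ED50 estimation

Collapsed observations are fit to the Hill model
$E(D) = E_0 + (E_{max}-E_0)\,D^n/(D^n + ED_{50}^n)$ by least squares.  By
default $E_{max}=100$ and $E_0=0$ are fixed — %MPE is already normalized to
its ceiling — leaving $(ED_{50}, n)$ free; a 4-parameter fit is available.
Numerical choices:

* The fit runs on $\log_{10}$ dose with $\log$-parameterized $ED_{50}$ and
  slope, which enforces positivity without constrained optimization.
* Nelder–Mead from 5 log-spaced $ED_{50}$ starts across the dose range
  (relative tolerance $10^{-8}$ on the residual sum of squares, ≤ 500
  iterations); the best residual wins, ties broken toward the median log
  dose.  A single-free-parameter fit uses Brent's method instead.
* Standard errors are Gauss–Newton: $\hat\sigma^2 (J'J)^{-1}$ with $J$ the
  Jacobian of predictions in the internal parameterization.  Delta-method
  intervals are built on $\log_{10} ED_{50}$ with $t$ quantiles and
  exponentiated, so they respect positivity; a case-resampling bootstrap
  (animals within dose) gives a percentile alternative.
* A fit is flagged **not converged** — and refused by every downstream
  isobole computation — when the optimizer fails, the fitted $ED_{50}$ falls
  outside $[\min(D)/100,\ 100\max(D)]$, the response shows no variation, or
  the slope leaves $[10^{-3}, 100]$ (a step-function degeneracy).  At least
  3 distinct positive doses are required by design.

## The additive benchmark and the interaction index

For a fixed-ratio mixture with molar fractions $\rho_1$ (drug A) and
$\rho_2$ (drug B), Loewe additivity gives the theoretical additive point

$$ED_{50,add} = \frac{ED_{50,A}}{\rho_1 + R\,\rho_2},\qquad
  R = \frac{ED_{50,A}}{ED_{50,B}},$$

the total mixture dose on the straight line joining the two single-drug
ED50s on the isobologram.  The formula is symmetric under swapping the
components with their fractions, reduces to the harmonic mean
$2AB/(A+B)$ for the equimolar design, and is always bounded by the two
component ED50s.

Uncertainty is propagated by the delta method with the components treated as
independent (they come from separate cohorts of animals — an assumption,
stated here because it cannot be checked from the fits):

$$\mathrm{Var}(Z_{add}) = \Big(\frac{\rho_1}{D^2}\Big)^2 \mathrm{Var}(A)
 + \Big(\frac{\rho_2 A^2}{B^2 D^2}\Big)^2 \mathrm{Var}(B),
 \qquad D = \rho_1 + \tfrac{A}{B}\rho_2.$$

Propagation is on the natural dose scale by default because isobolograms
plot natural-scale error bars; a log-scale option and a Monte-Carlo
propagation (paired normal draws, seeded) are provided, and the two routes
agree within a few percent at study-scale uncertainties.

The decision rule operationalizes "the mixture point lies below the additive
line": with $t = (ED_{50,add} - ED_{50,mix})/\sqrt{SE_{add}^2 + SE_{mix}^2}$
and Welch–Satterthwaite degrees of freedom (a fixed-df option exists for
strict textbook replication), the mixture is *synergistic* when
$ED_{50,mix} < ED_{50,add}$ with $p < \alpha$, *antagonistic* when
significantly above, otherwise *additive*.  The interaction index
$\gamma = ED_{50,mix}/ED_{50,add}$ is always reported — a visual
below-the-line criterion alone is not decidable, so the package couples the
index to the significance test.  $\alpha$ defaults to 0.05, two-sided
throughout.

## SNL time-course statistics

The SNL model produces thermal hyperalgesia (shorter withdrawal latency to
radiant heat) and mechanical allodynia (lower force threshold).  The
radiant-heat cutoff is three times the animal's own baseline latency;
measurements above it are truncated and flagged, and the truncation is
idempotent.  Sessions run baseline → 7 days post-surgery → treatment days
3/7/10/14.

Analysis defaults: per endpoint and session, a one-way ANOVA across groups
followed by Dunnett many-to-one comparisons against a named control group
(the session-wise one-way layout matches the star-per-session convention of
behavioral time-course figures; a repeated-measures model is out of scope).
Dunnett adjusted p-values come from the multivariate-$t$ distribution of the
comparison statistics (correlation $\lambda_i\lambda_j$ with
$\lambda_i = \sqrt{(1/n_0)/(1/n_i + 1/n_0)}$), evaluated by Genz–Bretz
Monte-Carlo integration with a fixed default seed (10⁵ points, absolute
tolerance 10⁻⁴), so results are reproducible; adjusted p-values are clamped
to be at least the raw p-values and monotone in $|t|$.  Within groups, each
post-baseline session is compared with baseline by a paired two-sided
$t$-test on animal-matched differences.  All seeded internals restore the
caller's RNG state, so embedding these calls in a user simulation never
perturbs it.

## What the generator simulates — and what it does not

`simulate_hot_plate()` inverts the %MPE definition: per animal, a baseline
latency is drawn from a truncated normal (mean 10 s, SD 1.5 s on (3, 30) s —
chosen so the %MPE denominator 35 − control stays well-conditioned); the
true effect is $\text{kernel}(t)\times\text{Hill}(D)$ with a log-normal-shaped
time kernel peaking at 15 min and returning to ~0 by 120 min; observed
latency is $\text{control} + (\text{cutoff}-\text{control})(\%MPE_{true} +
\varepsilon)/100$ with $\varepsilon \sim N(0, 12)$ in %MPE units, floored at
0.5 s (a physical reaction-time floor) and censored at the cutoff.  The
noise SD of 12 was chosen so per-dose SEMs at $n = 10$ fall in the 3–10
range typical of this assay.  Default true ED50s are 7.8 μmol/kg for the
donepezil-like reference (its established value in this assay) and
17 μmol/kg for the agonist-like drug (no reference value exists; this is a
package calibration default, flagged as such).  Default Hill slope 1.5 is a
typical mid-range value for centrally acting analgesics.  The mixture arm's
true ED50 is $\gamma \times ED_{50,add}$ computed from the true component
values; its dose ladder should bracket that truth (the default 0.6–4.8
μmol/kg ladder suits $\gamma \approx 0.1$; calibration studies at
$\gamma = 1$ use the 3–30 ladder).

`simulate_snl()` draws value = true group × session mean + a per-animal
offset (between SD) + measurement noise (within SD), with thermal values
truncated by the 3×-baseline rule.  Default trajectories: thermal
26.1 → 14.7 s after ligation with treated recovery to 22.5 s by day 14;
mechanical 49.2 → 25.9 g recovering to 42.2 g; sham groups flat; n = 6 per
group; SDs chosen so simulated SEMs match the 1.3–3.0 range such studies
report.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: pharmacokinetic between-animal variation
in time-to-peak (the kernel is shared), tolerance across repeated dosing,
dropout, non-normal or heteroscedastic noise, and any correlation between an
animal's baseline and its drug response.  Tests on these simulations verify
the *statistical machinery*, not the biology.

## Problem sizes and verification

The test suite verifies the algebra exhaustively (randomized property tests
for the additive-dose identities and the %MPE contract), the fitter against
an independent 400 × 400 grid-search oracle on 20 seeded datasets, parameter
recovery and 95%-interval coverage over 500 replicates per true ED50
(1, 8, 16 μmol/kg; 4-dose ladders, n = 10/dose), the synergy classifier's
error rates over 500 pipeline replicates per condition (false-synergy ≤ 8%
at true γ = 1; detection ≥ 90% at γ = 0.1), Dunnett against both `multcomp`
and a direct Monte-Carlo simulation, and the ANOVA's size under a global
null over 1000 replicates.  Replicate-heavy simulations use the single
15-min reading (statistically identical to the full grid after the fixed@15
collapse) to keep the suite fast.  Zero-noise round trips recover every true
parameter to well under 0.5%.

## Known limitations

* Censored observations enter the least squares as exactly 100%; at designs
  where most top-dose animals are censored the ED50 is mildly biased
  downward.
* The delta-method SE of $ED_{50,add}$ ignores any correlation between the
  two component fits; with shared vehicle cohorts it would be optimistic.
* The classifier's false-synergy rate runs slightly above the nominal
  α/2-per-side level at small n (finite-sample SEs); the acceptance bound of
  8% reflects that.
* Dose units are μmol/kg everywhere.  Historical reports of this assay
  sometimes print μg/kg and μmol/kg inconsistently for the same series; the
  readers enforce unit-suffixed column names precisely to keep such
  ambiguity out of the data path.
* The repeated-measures structure of the SNL design (same animals across
  sessions) is used only by the paired baseline contrasts, not by the
  session-wise ANOVA.
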