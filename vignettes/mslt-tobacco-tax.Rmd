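---
title: "Modelling annual tobacco tax increases with proportional multistate life tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling annual tobacco tax increases with proportional multistate life tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msltax)
```

## The model

`msltax` simulates a closed national cohort — everyone alive in a baseline
year (2011 by default), stratified by sex, single year of age 0–110, and two
ethnicities (a majority and a high-smoking, high-mortality minority) — to
extinction, under a business-as-usual (BAU) scenario and under a policy of
repeated annual tobacco excise increases. The comparison yields incremental
quality-adjusted life-years (QALYs), net health-system costs, and changes in
ethnic mortality inequality.

The causal chain has four links:

1. **Smoking-state projection.** Each cohort cell carries a distribution over
   smoking states: never, current, twenty single-year ex-smoker bins indexed
   by years since quitting, and a "former" pool for quitters of 20+ years who
   carry no excess risk. Each simulated year, cohort members reaching age 20
   initiate at a geometrically declining rate, current smokers quit at banded
   net cessation rates (ages 20–34, 35–54, 55+), ex-bins advance by one year,
   and the cell's composition is re-weighted by survival under
   status-specific all-cause mortality before renormalising to 1. In a year
   with a tax rise, current prevalence in each elasticity age band is
   multiplied by `1 + elasticity × increase` (a 10% rise with elasticity
   −0.38 is a 3.8% relative reduction; −0.10 gives 1.0%), and the displaced
   smokers enter the newest ex-bin. The minority elasticity is the majority
   value scaled by 1.2. The quitting effect applies in the year of the rise
   only. Elasticities act on ages 15 and over — the lower edge of the
   youngest elasticity band; the model population includes children, but no
   published elasticity covers them.

2. **Relative risks and population impact fractions.** Ex-smoker relative
   risks decay exponentially toward 1,
   `rr(t) = 1 + (rr_current − 1) e^{−γt}`, hitting exactly 1 at 20 years
   since quitting. The decay rate γ is a per-disease-group parameter
   (defaults: cardiovascular `ln 2 / 3` per year, cancers and respiratory
   `ln 2 / 10`); the published coefficients behind this attenuation are not
   reproduced here, so γ is configurable and only the qualitative behaviour —
   fast cardiovascular recovery, slow cancer recovery, no excess risk after
   20 years — is fixed. For each disease, stratum, and year the population
   impact fraction links the two smoking scenarios:
   `PIF = 1 − Σ p'ₛ RRₛ / Σ pₛ RRₛ`, summing over all smoking states.
   Intervention incidence is BAU incidence times `1 − PIF`. PIFs scale
   incidence only — never case fatality. For the three diseases where
   smoking is protective (RR < 1) the PIF is negative and incidence rises.

3. **The multistate life table.** The main life table advances each cohort
   cell by annual cycles with total mortality = residual mortality +
   modelled-disease deaths. Sixteen disease life tables run in parallel;
   each tracks the prevalent proportion `p` of the living cell through the
   illness–death flows `p' = p + i(1 − p) − (f + r)p`, with incidence `i`
   (PIF-scaled), case fatality `f`, and remission `r` (non-zero only for
   cancers and the acute lower respiratory infection, whose survivors fully
   remit within the year; remitted cases rejoin the susceptible pool).
   Disease deaths enter the main table as `p × f`. Residual mortality is
   all-cause mortality minus baseline disease deaths (prevalence × case
   fatality); a negative residual anywhere is a hard error naming the
   stratum. Person-years use the half-cycle correction
   `(alive_start + alive_end)/2`; age 110 is absorbing.

4. **Valuation.** QALYs weight person-years by
   `1 − (pyld_other + Σ_d DR_d p_d)`, where `pyld_other` is baseline
   per-capita morbidity net of the modelled diseases' share and `DR_d` is
   the disability rate per prevalent case. Costs per year are
   `alive × baseline + Σ_d (first-year × incident + prevalent × occupancy +
   last-6-months × dying-of-d)`. Net cost adds the one-off law cost to the
   intervention arm; US$ figures divide NZ$ by the 2011 purchasing-power
   parity factor 1.486. (The source costing describes this factor as
   "1.486 US$ to 1 NZ$", which read literally would mean multiplication,
   but its own printed NZ$/US$ pairs are consistent only with division; the
   package follows the arithmetic and flags the wording here rather than
   silently resolving it.)

### Trends

Rates move by annual proportional changes (APC) until 2026 and are flat
thereafter (a scenario switch extends them indefinitely). Residual mortality
declines at 2.25%/yr for the minority and 1.75%/yr for the majority. COPD
incidence and case fatality each decline at 1%/yr — an even split of the
observed ~2%/yr COPD mortality decline, applied uniformly across strata.
Because disease deaths are modelled explicitly, the all-cause trend emerges
endogenously as the death-weighted sum of disease trends and the residual
trend.

## One consistent epidemiological convention

The generator, the coherence check, and the engine all use the
open-population illness–death recursion `p' = p + i(1 − p) − (f + r)p` for
disease prevalence. Under this convention a constant-rate disease with no
remission converges to the classic steady state `i/(i + f)`, which
`check_coherence()` exploits: it forward-simulates each disease's rates over
the age range and reports the maximum absolute gap to the supplied
prevalence surface (generated bundles achieve 0 by construction, and
anything above 0.005 fails the bundle).

Two alternatives were considered and rejected for the disease tables. A
closed bookkeeping in which disease deaths shrink the table's denominator
adds an `f p²` term that drags high-prevalence, high-fatality cells (e.g.
coronary disease at 85+) more than 10% away from the input surfaces within a
decade, breaking internal validation on perfectly coherent inputs. An
absorbing "cured" compartment for remission behaves the same way and
additionally distorts the acute respiratory disease, whose survivors are
genuinely re-susceptible. In the chosen convention remitted cases return to
the susceptible pool; the only substantive consequence is that re-incidence
is possible, which is epidemiologically correct for the acute infection and
a second-order effect for cancers at the rates used.

`validate_internal()` implements the zero-trend consistency check: with all
trends zeroed, the model's disease-specific mortality risks per age group a
decade into the run are compared with the input-implied occupancy × case
fatality, flagging relative gaps above 10%. Both sides are computed as
annual risks against the start-of-year population, since comparing a risk
with a per-person-year rate would inflate the gap by `1/(1 − q/2)` — about
12% at the oldest ages on mortality alone.

## The synthetic study conditions

The generator builds a fully self-consistent toy population with the
statistical structure of the modelled country, so every stage is testable
without any download. Its defaults are the study conditions, not tuning
knobs:

* 44,000 people (a 1/100 scale of a 4.4-million population; all outputs are
  per-capita invariant, so scale only affects absolute totals), minority
  share 15%.
* Current-smoker prevalence: majority adult peak 16% with uptake over ages
  15–25 and decline after 60; minority prevalence is 33/14 times the
  majority curve — the ratio checked at ages 25–44 in the tests.
* Minority all-cause mortality twice the majority's.
* Sixteen tobacco-related diseases — coronary heart disease, stroke, COPD,
  lower respiratory tract infection, and twelve cancers, with smoking
  protective against endometrial cancer, melanoma, and thyroid cancer.
  Incidence follows scaled logistic curves of age with disease-specific
  onset; case fatality rises with age; prevalence is derived from the rates
  by the coherence recursion. Two cancers are female-only (cervical,
  endometrial), handled as zero male incidence.
* Cancer remission rates are plausible constants bounded by the complement
  of case fatality (the source analysis anchored remission to five-year
  relative survival through an external fitting tool that is out of scope
  here); the acute respiratory infection remits at `1 − case fatality`.
* Costs and morbidity rise with age; baseline total morbidity is
  constructed as a base curve plus the modelled diseases' disability share,
  which guarantees a non-negative background utility decrement.
* Initiation, cessation, trend, and elasticity defaults are the published
  policy parameters (e.g. net cessation 0.0414/yr for majority men aged
  20–34; initiation decline 3.39%/yr for the same group; elasticities
  −0.38/−0.29/−0.19/−0.10 with the +20% minority scalar).
* The one-off law cost (NZ$3.54 M with SD 1.05 M at full population scale)
  is scaled by the population scale factor so that per-capita economics are
  preserved at desk scale.
* A seed-dependent log-normal jitter (5% SD) perturbs curve levels so
  different seeds give genuinely different bundles while every invariant
  holds; identical seeds give bit-identical bundles.

What the generator does **not** emulate: real rate magnitudes for any
country, cohort replacement (births), comorbidity interactions,
cigarettes-per-day intensity effects, and secondhand-smoke spillovers.
Passing tests therefore demonstrate internal correctness and qualitative
behaviour — dominance orderings, inequality direction, timing of gains —
not calibration to any jurisdiction.

## Uncertainty analysis

Monte Carlo draws perturb every uncertain parameter with moment-matched
marginals: normal, log-normal, beta, or gamma, with mean equal to the point
estimate and SD from the tiered rule — 5% for well-measured disease rates,
10% for morbidity, disability, costs, and relative risks, 20% for
initiation, cessation, and elasticities; trends get an absolute 0.5
percentage-point SD, the tax increment an absolute 1 percentage-point SD,
the minority elasticity scalar an absolute 0.10 SD (truncated at zero, so
the scalar invariant survives sampling), and the law cost its gamma
distribution. Parameters sharing a correlation family are comonotone: one
uniform quantile per family per draw is pushed through each member's
marginal, giving rank correlation 1 within the family (all twelve cessation
cells, the four elasticity bands, each disease's rate set) and independence
across families — the coupling mechanism is a package choice, since only
the correlation value is documented in the source. After each draw the
bundle's all-cause mortality is rebuilt as stored residual + perturbed
disease deaths, which keeps the residual-mortality invariant non-negative
by construction.

Sampling the prevalence alongside incidence and case fatality with one
shared quantile preserves approximate coherence within a draw; the small
residual incoherence a draw introduces is part of the uncertainty being
propagated, not an error.

Outputs are summarised as means, medians, and 2.5–97.5 percentile
uncertainty intervals. Tests use 50–200 draws with common random numbers
across SD scalings (halving/doubling SDs then scales interval widths by
≈0.5/≈2 with far less Monte Carlo noise than independent draws would);
4,000 draws is the full-run default. The tax increment is drawn once per
run, not per year — the uncertainty is read as uncertainty about the policy
magnitude rather than annual noise.

## Inequality metrics

Mortality rates by single age are age-standardized with the WHO World
Standard weights (bundled in code; weights are renormalized over whichever
band is requested, so 45–64, 65–84, 85+, and all-45+ use one standard).
From a pair of standardized rates the package reports the standardized rate
difference (SRD), ratio (SRR), and percentage changes between scenarios
computed on unrounded values, with the relative-inequality change expressed
on the excess SRR (`SRR − 1`). In Monte Carlo runs the percentage changes
are computed per draw and then summarised.

## Numerical choices and edge cases

* Annual cycles; all flows within a cycle are computed simultaneously from
  the start-of-year state.
* Discounting uses the end-of-year convention: year `t` (1-based) is
  discounted by `(1+ρ)^{−t}`, so a constant unit stream over `n` years has
  present value `(1 − (1+ρ)^{−n})/ρ`. The main analysis uses 0%, variants
  3%.
* The smoking-state survival re-weighting scales status-specific mortality
  so its composition-weighted mean equals the cell's all-cause rate. Because
  the scaling depends on the cell's composition, the two scenarios' scalings
  differ microscopically; current prevalence under tax can exceed BAU by up
  to ~1e−8 in near-extinct cells (prevalence < 1e−6 at ages near 100). The
  dominance invariant is therefore asserted at 1e−6.
* Trend-scaled rates are clamped to [0, 1]; a tax shock that would produce
  negative prevalence (extreme elasticity × increase) is an error, not a
  clamp; initiation outside [0, 1] after trend application is an error.
* Utility weights below 0 and negative residual mortality are hard errors —
  both indicate incoherent inputs rather than conditions to repair silently.
* The terminal age 110 is absorbing: the oldest active cohort dies during
  its age-110 year and contributes a half-year of person-time.
* All randomness flows from explicit seeds: the generator's seed fixes the
  bundle bit-for-bit, and a draw plan's seed fixes the entire Monte Carlo
  quantile matrix up front.

## Problem sizes

The package's own test and example runs use the scaled default bundle
(44,000 people, 4 strata × 111 ages, 16 diseases, horizons of 40–111
years) and 8–200 Monte Carlo draws; a full comparison runs in well under a
second, an uncertainty analysis at 200 draws in a few minutes. These sizes
were chosen so the whole pipeline — generation, projection, two life-table
runs, and reporting — exercises every code path at interactive speed; the
engine's cost is independent of the population count, so full-scale
populations change nothing but the absolute totals.

## Known limitations

Beyond the generator's non-goals above: the model is compartmental, not a
microsimulation; disease processes are independent (no comorbidity
interactions); price elasticities are held constant even at much higher
cumulative price levels; the illicit market, tax revenue, and nicotine
substitution products are out of scope; and equity analyses substitute the
majority's background mortality and morbidity for the minority's rather
than modelling the social processes behind the gap.
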