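---
title: "Modelling the cost-effectiveness of dedicated pediatric operating rooms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of dedicated pediatric operating rooms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pedorcea)
```

## The question and the model

Many referral hospitals in low- and middle-income countries run pediatric
surgery inside shared adult operating theatres. Installing dedicated
pediatric operating rooms (ORs) raises surgical throughput, and the policy
question is whether the installation and running costs are justified by the
health gained. `pedorcea` models this as a two-arm decision tree over one
year of service at a single referral hospital:

* **Standard of care**: the pre-installation service treats a fraction of
  the annual surgical demand (226 of 343 cases, 66%, in the default
  configuration). The untreated remainder suffer the *natural course* of
  their disease: with probability $p^{dx}_{death}$ they die, otherwise they
  live to the average life expectancy under an untreated disability weight
  $dw^{dx}_{untreated}$.
* **Dedicated pediatric ORs**: the full annual demand is treated. A treated
  child dies before discharge with probability $p_{DBD}$ (taken from the
  registry's observed in-hospital mortality); a survivor is successfully
  treated with probability $p_{ST}$ and then either fully cured or, with
  probability $p^{dx}_{res}$, left with residual morbidity; treatment
  failure reverts to the natural course.

Health is measured in discounted disability-adjusted life years (DALYs).
For a child operated at age $a$ with remaining life $L = LE - a$ (life
expectancy $LE$ = 54 y by default), future healthy years are discounted
continuously at annual rate $r$:

$$Y(L) = \frac{1 - e^{-rL}}{r}, \qquad Y(L) \to L \text{ as } r \to 0 .$$

Death loses $Y(L)$; a disabled state of weight $dw$ loses $dw \cdot Y(L)$.
No age weighting is applied, disability is constant over the remaining
lifetime, and residual morbidity can be portrayed per diagnosis either as
years lived with disability (`lifelong_disability`, the default) or as a
death within the year (`death_within_year`), both present in the catalog
schema. YLL and YLD streams are discounted identically.

Costs take an all-healthcare-payor perspective in 2021 USD: charity
installation capital (durable equipment annualized straight-line over each
item's lifespan, shipping/installation, overhead), Ministry-of-Health
operating costs (presence- and share-weighted personnel salaries plus
per-case perioperative costs and hospital bed-days at a WHO-CHOICE-style
day rate), and families' out-of-pocket spending. The incremental
cost-effectiveness ratio is

$$\mathrm{ICER} = \frac{C_{OR} - C_{SoC}}{E_{SoC} - E_{OR}}
  \quad [\$ \text{ per DALY averted}],$$

classified against a willingness-to-pay threshold of half the GDP per
capita ($1,043 by default), strict at the boundary; dominance follows
standard CEA conventions (no negative ICERs are reported).

## The synthetic registry

No patient-level data ship with the package. `generate_registry()` draws a
synthetic perioperative registry with the published marginal structure of
the study service: 1,068 cases over 3.2 years, mean age 3.84 y (SD 4.61),
79.2% male, elective/emergency mix 806/242 with the residual unclassified
cases folded into elective, urgency-specific in-hospital mortality 2/806
and 16/242, and a case mix of ~65% general pediatric surgery and ~14%
congenital anomalies, the small remainder split over six further synthetic
groups. Ages are gamma-distributed truncated to $[0, 18)$; because the SD
exceeds the mean no symmetric non-negative law fits, and the gamma
parameters are solved numerically so the *truncated* moments match the
targets. Out-of-pocket spend is gamma with mean \$9{,}800/117 per case
(shape 2, a moderately right-skewed spend distribution typical of
self-reported medical expenditure).

The generator reproduces marginal structure only: it has no within-patient
correlation between age, diagnosis, urgency and death beyond the modelled
urgency-mortality link, no seasonality, and no case-complexity drift over
time. Tests passing on synthetic registries therefore validate the
*pipeline arithmetic* on realistically shaped inputs, not any clinical
association in real data.

## Calibration

Per-diagnosis untreated death probabilities and disability weights come
from sources that are not publicly reproducible, so the shipped catalog is
an explicit placeholder and `calibrate_catalog()` anchors the model to the
published arm-level DALY totals (840 standard-of-care, 302 intervention).
Writing $d_t$ and $d_u$ for the expected burden of a treated and an
untreated case, the two arm equations are linear:

$$n_{or} \, d_t = E_{OR}, \qquad
  n_{soc} \, d_t + (n_{or} - n_{soc}) \, d_u = E_{SoC},$$

giving $d_t = 302/343 \approx 0.880$ and $d_u \approx 5.479$ DALYs per
case at the default volumes. Two scalars then carry the catalog onto these
burdens: $\alpha$ scales each entry's composite untreated severity
$s_u = p_{death} + (1 - p_{death}) dw_{untreated}$ (applied to the death
probability and proportionally to both disability weights, so
$s_u' = \alpha s_u$ holds exactly), and $\beta$ scales the residual
probability of the success branch so the registry-mean treated burden is
$d_t$. Both are closed-form; targets that would push any probability or
weight outside $[0,1]$, or a treated target below the floor implied by
perioperative mortality, raise a calibration error. Only the composite
severities are identified by the two targets — the split between untreated
death and untreated disability within $s_u$ retains the placeholder
proportions, which is why derived quantities that depend on that split
(notably lives saved, hence cost per life saved) are reported but not
calibrated.

DALYs are computed per record from each record's own age; the arm totals
are expectations over the registry's empirical case mix, which makes arm
evaluation identical to the exhaustive leaf-enumeration of the tree (a
property the test suite checks to $10^{-9}$) and calibration recovery
exact on the calibration registry. An explicit treated-subset mode
(seeded draw or case order) is available for registry-sized demand sets.

## Cost configuration

The default configuration reproduces the six published annual components:

| component | $/year | payor |
|---|---|---|
| durable equipment (annualized) | 57,435 | charity |
| shipping and installation | 30,293 | charity |
| overhead | 7,018 | charity |
| incremental personnel | 21,943 | MoH |
| perioperative variable costs | 51,037 | MoH |
| out-of-pocket | 9,800 | patient |

The six components sum to \$177,526, one dollar under the published
rounded total. Salary rows and the split of the perioperative total across
disposables, medications, utilities and bed-days (day rate \$26.17, mean
stay 5 days) are synthetic back-computations from the aggregates at the
base incremental caseload of 117; the aggregates, not the splits, are the
constrained quantities. The overhead line sits with the charity payor, so
the charity subtotal is \$94,746 with overhead and \$87,728
(equipment + shipping) as installation capital proper — both groupings are
recoverable from the ledger. The comparator arm's annual cost is carried
as the published total (\$117,514) rather than rebuilt from components:
its composition is not itemized publicly, and an additive reconstruction
from the per-case variable rates would need a (nonsensical) negative fixed
base. The incremental ICER is unaffected by that choice. Annualization is
straight-line without interest or salvage; GBP originals of the two
converted capital figures are carried in the configuration for
traceability but never re-converted, since the published USD values imply
inconsistent conversion factors and are taken as authoritative.

## Sensitivity analyses

`tornado()` sweeps one parameter at a time through `icer_with()`, the
re-evaluation engine that recomputes the full model under overrides. The
comparator volume share is swept over 0–90% and the discount rate over
0–6%; perioperative mortality over the observed elective–emergency span
(0.25%–6.6%); the remaining cost and demographic inputs over ±20%. The
ICER is strictly increasing in both the comparator share and the discount
rate, and the discount sweep brackets the base case — the directional
pattern the model must reproduce. Exact endpoint values depend on
non-public inputs and are not calibration targets.

`run_psa()` (also available as `simulate()` on the fitted model)
propagates parameter uncertainty over Monte Carlo batches. Each batch
simulates a new year of service: an annual caseload is drawn uniform on
250–400 and that many cases are resampled with replacement from the model
registry, supplying the year's empirical case mix and ages; the decision
volumes remain at the observed annual throughputs (226/343), which are
historical facts rather than uncertain parameters — the caseload draw
represents year-to-year variation in who presents, not in the service's
capacity. (A `scale_volumes = TRUE` option ties the intervention volume to
the draw instead.) Distribution families follow the study's uncertainty
table: betas for probabilities and disability weights, gammas for costs,
and an empirical resampling law for per-case medication costs, represented
by a deterministic gamma-quantile grid whose batch value is the mean of a
simulated year of per-case draws. Every family is moment-matched so its
mean is the base-case value, with range-to-variance mapping
$\sigma = (high - low)/3.92$ (the range read as a central 95% interval);
±0.2 absolute ranges are used for probabilities without an empirical
range, ±20% relative for costs and disability weights. The headline
simulation ICER is the ratio of mean incremental cost to mean DALYs
averted (the standard CEA estimator; the mean of per-batch ratios is also
reported, and is upward-shifted by ratio noise). Uncertainty intervals are
percentile bootstraps over 100 resampled means of the per-batch ICERs. The
whole analysis, bootstrap included, is a pure function of one seed, and a
fully degenerate parameter set reproduces the base case exactly (in that
limit the base registry itself is the realized caseload).

## Numerical choices and limitations

* Zero-discount limits are handled exactly (`discounted_years(L, 0)`
  returns `L`, not a 0/0).
* Presentation rounding is half-away-from-zero to the dollar and applied
  only at print time; all internal arithmetic is unrounded.
* The truncated-gamma age fit is solved by Nelder–Mead on the log
  parameters to relative tolerance $10^{-14}$; sampling uses the inverse
  CDF restricted to the truncation interval.
* Beta fits reject variances the support cannot carry; degenerate
  (zero-width) ranges collapse to constants in every family.
* Problem sizes are chosen so the full pipeline is quick on a laptop: the
  default registry has 1,068 records, the probabilistic analysis 100
  batches with 100 bootstrap resamples, property tests draw $10^4$
  samples. The complete test suite runs in a few seconds.
* One year of service, no Markov extension, no indirect costs
  (transportation, lost wages), no preoperative diagnostics, and no
  acceptability curves or value-of-information measures: all outside the
  model's scope.
* The model assumes the same case mix with and without the dedicated ORs;
  if the true incremental cases are more complex, the modelled benefit is
  conservative.
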