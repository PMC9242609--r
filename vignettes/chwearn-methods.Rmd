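---
title: "Methods: projecting and auditing CHW incentive earnings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting and auditing CHW incentive earnings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chwearn)
```

## The model and its assumptions

`chwearn` projects the expected monthly earnings of a community health
worker (CHW) from a catalog of fixed rupee incentives. Each incentive is the
product of four terms: a monthly beneficiary incidence, the probability the
CHW completes her required actions, the probability the household completes
the required behaviors *given* the CHW action, and the incentive amount.
Crossing perfect/actual CHW modes with perfect/actual household modes gives
four scenarios (PP, PA, AP, AA) whose totals decompose into a design gap
(PP − PA), a lost opportunity (PA − AA) and an implementation gap
(observed payments − AA, positive meaning overpayment).

Assumptions the engine makes, and why:

- **Independence across required actions/behaviors.** When an incentive
  needs several actions or behaviors, their rates multiply. The source
  material maps actions and behaviors per incentive but states no
  combination rule; the product is the minimal assumption, it is isolated in
  `effective_rate()` so tests can probe it, and the four-scenario ordering
  AA ≤ {AP, PA} ≤ PP holds under it for any rates in [0, 1].
- **Conditional behavior rates.** Household behavior rates are always
  interpreted as conditional on CHW contact. The unconditional population
  rate is never used: a woman who delivers at a facility without any CHW
  contact generates no claim, so using population rates would overstate
  claimable earnings. The synthetic generator draws such background behavior
  explicitly (and the claimability tests assert it never pays).
- **Annual→monthly conversion is division by 12**, with no seasonality:
  per-1,000 annual rates give `rate × (population/1000) / 12` events per
  month. Pregnancy incidence is proxied by live-birth incidence (the crude
  birth rate), as the published worked chain does.
- **Deterministic averages.** The engine projects state-average earnings for
  an average catchment of 1,000; per-CHW heterogeneity lives only in the
  synthetic-data module, and no confidence intervals are attached to model
  outputs (none exist in the source analysis).

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| catchment population | persons | 1,000 | stated average CHW catchment; a sweep utility (`catchment_sweep()`) exposes the linearity/invariance structure |
| crude birth rate | events/1,000/yr | 27.28 | chosen so the published chain is exact: 27.28/12 = 2.2733/month (printed 2.3) and 2.2733 × 300 = 682 |
| incentive amounts | INR | catalog | only the amounts printed in the main analysis are verbatim (300 institutional delivery, 300 ANC series, 100 first-year immunization, 100 recordkeeping); the rest are `placeholder_amount = TRUE` fixtures |
| action / behavior rates | probability | rate-set CSV | the three worked-chain rates (0.6, 0.66, 0.75) and two series completion rates (0.264, 0.511) are published; the rest synthetic |
| INR per USD | rate | 71.7 | presentation only; the published INR/USD pairs imply slightly different rates in different places, so it is a config parameter |

## Numerical choices

**Rounding.** Money is double-precision rupees; rounding to whole rupees
happens only at presentation. Two engine modes exist:

- `FULL_PRECISION` (default): no intermediate rounding.
- `PAPER_ROUNDING`: reproduces the published worked chains for regression
  testing. Those chains round the *rate-adjusted* incidence of
  population-scaled incentives to one decimal before multiplying by the
  amount (2.2733 × 0.6 × 0.66 → 0.9 → INR 270), but use the *unrounded*
  incidence when no rate is applied (2.2733 × 300 = 682, not 2.3 × 300 =
  690) and never round the fixed routine chain (1 × 0.75 × 100 = 75). The
  mode therefore applies one-decimal rounding only to population-scaled
  incentives with a combined scenario rate below 1. This is the only
  definition consistent with all three published worked values at once.
  One published value (perfect-CHW/actual-household institutional delivery,
  INR 457) is inconsistent with its own printed inputs (2.2733 × 0.66 × 300
  = 450.1) and is deliberately not a regression target.

**Relaxation fitting.** The "paid despite partial completion" mechanism is
formalised as a threshold k on the series completion count, paying the full
lump sum when count ≥ k; per-component partial amounts are not modeled
because the observed mechanism is full payment for partial work. The fitted
threshold minimises the absolute rupee discrepancy against the observed mean
monthly payment; ties break toward the *largest* k, i.e. the explanation
closest to the designed rule. Expected payment is non-increasing in k (a
survival function), bounded by incidence × amount; both are property-tested.

**Degenerate inputs.** Empty catalogs project to zero. Empty key lists have
effective rate 1 in both modes. A conditioning stratum with no contacted
beneficiaries yields an omitted rate with a warning, never 0/0. Validation
errors carry classed conditions (`chwearn_validation_error`,
`chwearn_contract_error`, `chwearn_config_error`) and the CLI maps them to
exit status 2 versus 1 for runtime failures.

## What the synthetic generator emulates — and what it does not

`generate_microdata()` produces linked household + CHW microdata with the
structure the analysis assumes: per-CHW catchments of ~1,000 people;
beneficiary counts per CHW-month drawn Poisson with mean equal to the
analytic incidence (the source analysis is deterministic-average only, so the
count family is a modelling choice; tests assert only on means); Bernoulli
contact indicators at the action rates; behaviors conditional on contact,
with nonzero background behavior without contact (never claimable — the
default background rate is half the conditional rate, a deliberate fixture
choice since only the existence of background behavior is documented);
series completion counts from per-incentive distributions whose
P(count ≥ full threshold) equals the corresponding completion rate in the
rate set, keeping generator and engine mutually consistent; payment records
under strict or partial-completion rules; and a questionnaire of N = 1,502
respondents at the documented proportions (claim experience 0.72/0.55/0.65/
0.47/0.26/0.26, recency 0.34/0.31/0.35, and the awareness pattern 1.00 aware
/ 0.30 exact / modal wrong answer 600 at 0.68, generated nested so that
exact ⇒ aware holds by construction).

It does **not** mimic the real surveys' sampling design (no clusters or
weights — estimation is unweighted by design), attaches no correlation
structure across questionnaire items, and its completion-count distributions
are synthetic: the real ones derive from unpublished supplementary rates.
A green recovery test therefore establishes that the estimators and engine
are mutually consistent and unbiased under the stated structure — not that
the bundled rates reproduce any real population.

Series incentives carry exactly one *completion key* (enforced by the
catalog validator): a single behavior key when completion is a household
behavior conditional on contact (ANC, immunization), or the single action
key when the series is the CHW's own visits (PNC). This convention is what
makes the analytic rate, the generator and `estimate_rates()` agree, and the
law-of-large-numbers test (simulated strict-rule mean payments → AA
projection) span all three modules.

## Design choices where the design was open

- **Catalog schema** is bespoke versioned JSON (with a flat CSV import):
  nested series specifications fit JSON naturally and no machine format is
  prescribed anywhere.
- **Headline totals as fixtures.** The grand totals (PP 5,867 / PA 3,000 /
  AA 1,325 / observed 2,580 INR/month) and the observed per-category
  payments (941/789/376/387, with family planning 87 as the residual
  closing 2,580) are bundled as fixtures and verified through the gap
  identities, because the per-incentive rates they summarise are not
  published. The package's own fixture catalog produces *qualitatively*
  matching totals (family planning designed as the top category yet ~3% of
  observed payments) but is not tuned to reproduce them.
- **Share bases are explicit.** Category shares are computed against either
  the potential (PP) base or the observed-payments base, because both are
  used in different sentences of the source analysis; `gap_report()` returns
  both.
- **Test sizes.** The parameter-recovery acceptance run uses 20,000
  CHW-months (floor: 5,000) so its 2% projection-versus-simulation tolerance
  sits at roughly four Monte-Carlo standard errors; the threshold-recovery
  run uses 100 replicates of 600 CHW-months, where adjacent-threshold
  expected payments differ by >5 standard errors. Both choices were made
  from the variance arithmetic before running the tests, not tuned
  afterwards.
- **Pipeline configuration is JSON** (not YAML): it keeps the dependency
  footprint to packages the analysis already needs.

## Known limitations

- Placeholder amounts and synthetic rates mean absolute fixture totals are
  illustrative; only the published worked chains, identities, shares and
  recovery properties are asserted.
- The relaxation model fits each series incentive independently and assumes
  the completion-count distribution is known; jointly fitting distribution
  and threshold from payments alone is not identifiable and is out of scope.
- No uncertainty quantification on projections; binomial intervals appear
  only in survey descriptives (Wilson, with an exact fallback for n < 30 or
  boundary counts — a presentation choice, as the source reports none).
- The under-5 population share enters as a single fixture number; no
  population projection is performed.
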