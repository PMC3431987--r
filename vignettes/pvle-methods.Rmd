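---
title: "Estimating productivity costs of premature mortality with pvle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating productivity costs of premature mortality with pvle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvle)
```

## The problem

When a disease kills people before the end of their working lives,
society loses the goods and services they would have produced. Economic
evaluations taken from the societal perspective need that loss in money
terms, next to direct medical costs. `pvle` implements the two standard
valuations: the **human capital approach**, which counts all potential
future earnings foregone, and the **friction cost method**, which counts
only the loss until the vacated job is refilled.

## The human-capital model

For a person of sex $j$ dying at age $s$, remaining life expectancy
$e(s,j)$ fixes an earning horizon. The paid-work loss is

$$\mathrm{PVLE}^{paid}_{s,j} \;=\; \sum_{k=0}^{n-1}
  \frac{l_{s+k,j}\, W_{s+k,j}}{(1+r)^k},$$

with $l$ the labor force participation rate, $W$ the annual wage and $r$
the social discount rate; the unpaid household-work loss is

$$\mathrm{PVLE}^{hh}_{s,j} \;=\; \sum_{k=0}^{n-1}
  \frac{(1-l_{s+k,j})\, h_{s+k,j}\, w_{s+k,j}}{(1+r)^k},$$

valuing the $h$ annual hours of household work of the fraction of the
year of life spent outside the labor force at an hourly rate $w$. Both
sums run over the same horizon and use the same discount rate; the first
year is undiscounted (exponent $k=0$ at the starting age). Participation
is defined to be zero from age 76 on, so paid earnings stop there
regardless of survival.

Assumptions worth keeping in mind: full employment over the horizon
(everyone in the labor force works full time — the `parttime_factor`
control implements a proportionate downward adjustment), wages as the
measure of marginal product, and the usual equity caveat that age- and
sex-specific wages value some deaths more than others.

### Inputs and their units

All stratified inputs are dense per-age, per-sex schedules over ages
18–75 (`age_sex_series`): remaining life expectancy (years),
participation (proportion in $[0,1]$), annual wages (currency/year),
hourly wages (currency/hour, needed only for the opportunity-cost
household valuation), and annual household-work hours (hours/year,
bounded by 8760). Source statistics reported in age brackets are
expanded with `expand_brackets()`: bounds are inclusive on both ends, so
a 20–24 bracket covers ages 20, 21, 22, 23 and 24, and a value reported
for one sex only is replicated to the other with a provenance note.
Wages can be put on a common price year with the annual CPI index ratio
(`adjust_cpi()`); sub-annual CPI timing is deliberately not modelled.

The scalar inputs are the country's social discount rate (taken as
given; its derivation is a separate literature) and a free-text currency
label with a price year. Validation (`validate_dataset()`) is
report-based — each violation is one row naming component, age and sex —
with an opt-in strict mode, because real statistical inputs often carry
benign anomalies one wants to see rather than crash on. A decreasing
life-expectancy check is reported at warning severity only, since real
tables can violate it at bracket boundaries.

## Numerical conventions

Several conventions are left open by the printed equations; each is
pinned to a default in `pvle_control()` and exposed as a switch:

* **Horizon rounding** (`horizon`): life expectancy is rarely an integer.
  The default interprets the horizon as $n = \mathrm{round}(e)$ whole
  years (round half-to-even, R's `round()`), so total earning years equal
  rounded remaining life expectancy; `"prorate"` instead keeps
  $\lfloor e\rfloor$ full years plus a final year weighted by the
  fraction. The two differ by at most half a year's earnings.
* **Representative ages** (`pvle_group_table()`): results are reported
  for 5-year, 10-year or broad (18–34, 35–64, 65+) age groups, each bin
  evaluated at the floor of its midpoint (18–34 → 26, 35–64 → 49). The
  open-ended bin uses the midpoint with 75, the last input age (65+ →
  70), overridable via `open_bin_age`. The 10-year bins are 18–24,
  25–34, …, 65–74, 75+, aligning decade boundaries with the broad
  scheme's cut points.
* **Discounting**: annual, first year undiscounted, no mid-year
  correction — the exponent is taken literally.
* **Household work past 75** (`household_beyond_75`): paid participation
  is zeroed at 76+, but household production need not stop; by default
  it continues through the horizon with hours and hourly wage carried at
  their age-75 values.
* **Friction replacement-cost weighting** (`weight_replacement`): the
  friction loss is $l \cdot (W \cdot m/12 + C)$ with friction period $m$
  months and replacement cost $C$ — both terms weighted by
  participation, since a death outside the labor force vacates no job.
  Setting the switch charges $C$ unconditionally. No discounting is
  applied within the (short) friction period.
* **Discounting of future deaths** (`discount_deaths`): when a mortality
  schedule spreads deaths over future years, each death's loss is
  discounted back to baseline by default, making the burden table a
  present value at baseline; switching it off values deaths at their
  time of death.

Degenerate inputs behave predictably: a rounded horizon of zero gives a
PVLE of 0 with `horizon_end_age = start_age - 1`; zero participation
annihilates both the paid PVLE and the friction loss; a missing
household table makes household operations fail with a clear error
rather than silently returning 0, mirroring the fact that time-use data
exist only for some countries.

## Burden integration

`lifetime_productivity_cost()` takes a mortality schedule — expected
(fractional) deaths by year offset, age at death and sex, the natural
output of a deterministic Markov cohort model — and computes

$$cost(\text{sex}, \text{bin}) = \sum_{(t,a)\,\in\,\text{bin}}
  d_{t,a} \cdot loss(a) \cdot (1+r)^{-t},$$

with $loss$ either the human-capital PVLE or the friction loss, always
evaluated at the **age at death**. `cost_share()` turns a productivity
and an exogenous direct-cost total into the productivity share of total
lifetime costs; direct medical costs are never computed here — they are
an input from the disease model. `hc_friction_ratio()` reports the
per-bin ratio of the two methods, with an `Inf` sentinel where the
friction cost is zero.

## What the synthetic generators emulate — and what they do not

`generate_country_dataset()` produces internally consistent, stylized
country inputs: life expectancy declining ~0.95 years per year of age
(higher for females and advanced profiles), participation rising
logistically to the mid-20s, declining after the late 50s and near zero
past 65, a flat Gaussian wage hump (peak/trough ratio ≈ 1.2, peak age 48
by default), male/female wage ratio 1.25 and participation gap 0.15,
and higher female household hours. Defaults are 40,000 currency
units/year wages and a 3% discount rate for the advanced profile, and
12,000 and 8% for the emerging one — the rates sit inside the published
country ranges (roughly 2–9% advanced, 4–14% emerging). The wage
profile is deliberately flat so that the canonical age ordering of PVLE
(youngest group highest) holds across that whole discount range, a
property of realistic inputs that a steeply humped profile can destroy
at high discount rates; this was fixed as a generator convention up
front. Identical seeds give bit-identical datasets, and generation
leaves the caller's RNG stream untouched.

`simulate_cohort_mortality()` is a minimal three-state (current smoker /
former smoker / dead) expected-value Markov chain with a Gompertz
baseline hazard, a smoker relative risk, a one-off quit attempt at
baseline and linearly decaying former-smoker excess risk. It is a
labelled synthetic stand-in producing output of the right *shape* for
burden integration — it makes no claim to real smoking epidemiology, and
morbidity states (lung cancer, CHD, COPD) are intentionally absent. An
optional stochastic mode draws binomial deaths for property testing.

Consequently, passing tests demonstrate the *computational* contract —
equations, conventions, conservation, orderings — on data with realistic
structure; they do not validate any country's actual PVLE levels, which
depend entirely on the real life-table, participation and wage inputs
supplied by the user.

## Problem sizes and tolerances

The test suite checks the closed-form annuity equivalence on a grid of
120 constant-input combinations at 1e-9 relative tolerance; straight-loop
oracle equivalence on 200 random synthetic datasets (1e-9); pattern
suites on three seeds per development level; and cohort conservation at
1e-9 over a 60-year horizon. The acceptance script simulates a
1,000-smoker cohort entering at age 30 over 40 years. These sizes keep a
full run in well under a minute while exercising every code path; the
equivalences are exact up to floating-point accumulation, so larger
sizes add nothing.

## Known limitations

Morbidity-related productivity losses (absenteeism, presenteeism) are
out of scope, as are consumption offsets ("production minus
consumption" netting), market exchange-rate conversion between
currencies, vacancy-chain refinements of the friction method
(occupation-specific friction periods, surplus labor, employed-to-
employed transitions), and any real-data retrieval. The friction method
here is the rough three-month approximation commonly used in
sensitivity analyses. Household-work valuation inherits the gender wage
differentials of the paid labor market; the replacement-cost valuation
is provided precisely so users can quantify that sensitivity.
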