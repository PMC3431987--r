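# pvle — productivity costs of premature mortality

`pvle` estimates the indirect (productivity) cost of premature death for
health-economic evaluations from the societal perspective. It is aimed at
researchers who need to attach a monetary value to mortality streams coming
out of disease models — e.g. a Markov cohort model of smoking cessation —
using country-specific demographic and labor-market inputs.

## The model

The core quantity is the **present value of lifetime earnings** (PVLE)
under the human capital approach. For a person of sex *j* dying at age
*s*, with remaining life expectancy *e(s, j)* defining an earning horizon
of *n* = round(*e*) years:

```
PVLE_paid(s, j)      = Σ_{k=0}^{n-1}  l(s+k, j) · W(s+k, j) / (1 + r)^k
PVLE_household(s, j) = Σ_{k=0}^{n-1} (1 − l(s+k, j)) · h(s+k, j) · w(s+k, j) / (1 + r)^k
```

where `l` is the labor force participation rate (defined as 0 from age 76
on), `W` the annual wage, `h` annual hours of unpaid household work, `w`
the hourly wage used to value them (the person's own market wage under the
*opportunity cost* valuation, or a flat hired-substitute wage under the
*replacement cost* valuation), and `r` the country's social discount rate.
Inputs are age- and sex-stratified schedules over ages 18–75; bracketed
source data (e.g. 5-year groups) are expanded so each single age carries
its bracket's value.

Around this core the package provides:

* a validated per-country input data model with CSV/JSON readers and
  writers and CPI adjustment (`country_dataset()`, `read_dataset()`,
  `validate_dataset()`, `adjust_cpi()`);
* age-group result tables under 5-year, 10-year or broad (18–34, 35–64,
  65+) groupings, each bin evaluated at its midpoint representative age
  (`pvle_group_table()`);
* the **friction cost** sensitivity method — participation-weighted wage
  loss over a friction period (default 3 months) plus employer
  hiring/training costs (`friction_loss_per_death()`);
* **burden integration**: combining an age/sex/year mortality schedule
  with per-death losses into discounted lifetime cost tables, cost shares
  and human-capital vs friction ratios (`lifetime_productivity_cost()`,
  `cost_share()`, `hc_friction_ratio()`);
* synthetic data: a country-dataset generator and a deterministic
  three-state Markov cohort smoking-mortality simulator, so the whole
  pipeline runs with no external data (`generate_country_dataset()`,
  `simulate_cohort_mortality()`);
* a CLI (`pvle_cli()`, wrapper scripts in `inst/cli/` and `scripts/`).

## Worked example

```r
library(pvle)
ds <- generate_country_dataset(fixture_profile("advanced", seed = 1))
pvle_total(ds, "male", 40, include_household = TRUE)
#> PVLE (male, start age 40, horizon to age 79, r = 0.030):
#>   paid           692419.26 SYN
#>   household      187717.59 SYN
#>   total          880136.86 SYN

pvle_group_table(ds, "broad")
#>    country    sex age_group representative_age   paid household  total currency
#>  SYN-ADV-1   male     18-34                 26 940350         0 940350      SYN
#>  SYN-ADV-1   male     35-64                 49 433724         0 433724      SYN
#>  SYN-ADV-1   male       65+                 70   1854         0   1854      SYN
#>  SYN-ADV-1 female     18-34                 26 630945         0 630945      SYN
#>  SYN-ADV-1 female     35-64                 49 291015         0 291015      SYN
#>  SYN-ADV-1 female       65+                 70   1244         0   1244      SYN
```

A 40-year-old man in this synthetic advanced economy represents about
692,000 currency units of discounted future paid earnings (and a further
188,000 of household production valued at his market wage). The broad
table shows the two regularities the method produces on any realistic
input: estimates are largest for the youngest group (most earning years
ahead) and larger for men (higher participation and wages in the input
schedules). Deaths past the working ages are worth little under paid-work
PVLE, which is why the companion friction method matters mainly below 65.

The same pipeline from the shell:

```sh
Rscript scripts/pvle fixtures country --profile advanced --seed 1 --out demo_ds
Rscript scripts/pvle fixtures cohort --entry-age 30 --seed 1 --arm smoker --out demo_sched.csv
Rscript scripts/pvle burden --dataset demo_ds --mortality demo_sched.csv --method hc --out demo_burden.csv
```

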