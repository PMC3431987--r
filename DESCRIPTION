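Package: pvle
Title: Productivity Costs of Premature Mortality via the Present Value of
    Lifetime Earnings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates productivity costs of premature mortality with the
    human capital approach: the present value of lifetime earnings (PVLE)
    for paid and unpaid household work, computed from age- and sex-specific
    remaining life expectancy, labor force participation, wage and time-use
    schedules, with country-specific social discount rates. Includes a
    friction-cost sensitivity method (friction-period wage loss plus
    employer replacement costs), integration of age/sex-specific mortality
    schedules into lifetime cost tables and direct-vs-indirect cost shares,
    a synthetic country-dataset generator plus a deterministic Markov
    cohort smoking-mortality simulator for fully offline testing, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
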