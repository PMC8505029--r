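# raschkit

Headless psychometric analysis of person-by-item score matrices for
school assessment specialists, test developers, and measurement
researchers: classical test theory (CTT) item analysis with a
customizable flagging system, dichotomous Rasch and partial credit
model (PCM) calibration by marginal maximum likelihood, Wright-map and
Thurstonian-threshold diagnostics, many-facets differential item
functioning (DIF), fixed-anchor equating of linked test forms, one-way
ANOVA on person ability, and inter-rater intraclass correlations
(ICC).  Every analysis produces tidy tibbles, a fixed 13-sheet results
workbook, and a deterministic narrated markdown report.

## The model

For a dichotomous item the Rasch model gives the probability that
person *n* with ability θ<sub>n</sub> (logits) answers item *i* with
difficulty δ<sub>i</sub> correctly:

P(X<sub>ni</sub> = 1) = e^{D(θ<sub>n</sub> − δ<sub>i</sub>)} / (1 + e^{D(θ<sub>n</sub> − δ<sub>i</sub>)})

with D = 1 on the logit metric (D = 1.702 closely matches the
normal-ogive curve).  At θ = δ the success probability is exactly 0.5
— the zone where an item is optimally informative for a learner.  The
partial credit model extends this to ordered scores 0..m<sub>i</sub>
through step difficulties δ<sub>ij</sub>: the odds of completing step
*j* versus stopping at *j−1* are again logistic in θ − δ<sub>ij</sub>.
Raw score is a sufficient statistic for θ, so equal scores on the same
items always yield equal ability estimates.

Item parameters are estimated by marginal maximum likelihood (EM with
normal-population quadrature) under a user-chosen identification
constraint (latent mean fixed at 0, or mean item difficulty fixed at
0).  The facets extension adds a group main effect G<sub>g</sub> and a
sum-to-zero group-by-item interaction D<sub>gi</sub> whose magnitude
is the DIF measure; fixed-anchor equating re-fits a second form with
the link items frozen at reference-form values, with the invariance
statistic z<sub>i</sub> = (δ<sub>i</sub> − δ′<sub>i</sub>)/√(se² + se′²)
and equating error ε = √(Σd<sub>i</sub>²/(L−1))/√L.

## Worked example

```r
library(raschkit)

sim <- sim_responses(sim_design(n_items = 20, n_persons = 500, seed = 42))
an  <- rasch_analysis(sim$responses, construct = "Numeracy", focal_group = "Grade 4")

an$reliability$alpha        # 0.755  ("acceptable")
glance(an$fit)
#   deviance n_iterations converged latent_mean latent_sd n_persons n_items
#     10912.           19 TRUE                0     0.966       500      20
head(tidy(an$fit), 3)
#   item_id  step delta    se
#   I0001       1 -1.81 0.126
#   I0002       1 -1.73 0.123
#   I0003       1 -1.56 0.119
range(an$abilities$se_theta)   # 0.522 ... 1.855
an$wright$targeting$verdict    # "persons and item thresholds are matched well"

write_results_workbook(an, "numeracy.wb")   # 13 fixed sheets
render_report(an, "numeracy_report.md")     # narrated technical report
autoplot(an)                                # Wright map
```

The deviance (−2 log marginal likelihood) summarizes global fit; the
item table carries one row per step difficulty with its standard
error; the person standard errors quantify score precision across the
ability range, and the targeting verdict compares the person
distribution with the item thresholds on the shared logit scale.

Grouped data (first CSV column = group) flow through `fit_facets()` →
`dif_table()`, linked forms through `fit_rasch()` on each form →
`equate_forms()`, ability group comparisons through `oneway_anova()`,
and rater tables through `icc()`.  A thin command-line front end with
the same capabilities ships in `inst/cli/raschkit.R`.

## Package layout

- `R/` — implementation (containers and IO, simulation, CTT, MML
  fitting, abilities, diagnostics, facets DIF, equating, group
  statistics, reporting, tidy/plot methods)
- `tests/testthat/` — unit, property, and end-to-end suites with
  independent oracles (brute-force grid integration, hand sums of
  squares, closed forms)
- `vignettes/measurement-methods.Rmd` — the methods vignette: models,
  estimation, numerical choices, and limitations
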