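---
title: "Measurement methods in raschkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement methods in raschkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschkit)
```

raschkit analyses person-by-item integer score matrices with the
dichotomous Rasch model and its partial credit extension.  This
vignette records the models, the estimation machinery, the numerical
choices, and the design decisions that were genuinely open — the
things a maintainer or a skeptical reviewer would want written down.

## Models

For a dichotomous item, the probability of success is logistic in the
difference between person ability $\theta_n$ and item difficulty
$\delta_i$, both in logits:
$P(X_{ni}=1) = \mathrm{e}^{D(\theta_n-\delta_i)} / (1 +
\mathrm{e}^{D(\theta_n-\delta_i)})$.  Estimation always runs at
$D = 1$; the classical constant $D = 1.702$, which minimizes the
maximum discrepancy between the logistic curve and the standard
normal ogive, is kept as a display-time conversion only
(`fit_config(scaling_D = )`).  This keeps all internal quantities on
one metric and matches how the constant is actually used in practice.

For an item scored $0..m_i$, the partial credit model assigns each
pair of adjacent categories its own step difficulty $\delta_{ij}$:
$P(X = x) \propto \exp\!\big(x\theta - \sum_{j \le x}
\delta_{ij}\big)$, so the conditional probability of completing step
$j$ given reaching category $j-1$ or $j$ is logistic in
$\theta - \delta_{ij}$, and $m_i = 1$ reproduces the dichotomous
model exactly.  Raw score is a sufficient statistic for $\theta$:
persons with equal scores on the same administered items always
receive equal ability estimates.

Missing cells are treated as *not administered*: excluded from the
likelihood and from pairwise classical statistics, never scored as
wrong.  This is the semantics multi-form equating requires (a Form B
student never saw most Form A items), and it is applied uniformly.

## Marginal maximum likelihood estimation

Item parameters are estimated by MML-EM.  Ability is integrated out
under a normal population $N(\mu, \sigma^2)$ represented by 21
equally spaced quadrature nodes at $\mu \pm 5\sigma$ with weights
proportional to the normal density, renormalized.  The nodes ride on
the current $(\mu, \sigma)$, so the relative resolution of the grid
does not degrade when the estimated population is narrow — on tiny
degenerate data sets $\hat\sigma$ can be far from 1, and a fixed
absolute grid would mis-integrate there.  A lower bound of 0.05 on
$\hat\sigma$ keeps the quadrature well-posed on degenerate inputs.

- **E-step**: posterior node weights per person from the current
  parameters.
- **M-step (items)**: per-item Newton updates of the step
  difficulties from expected category counts, with step-halving so
  the expected complete-data log-likelihood never decreases.  The
  gradient and Hessian come from the identity
  $\partial \log P(x)/\partial\delta_j = -\mathbb{1}(j \le x) +
  P(X \ge j)$.
- **M-step (population)**: candidate $(\mu,\sigma)$ from posterior
  moments, accepted through a backtracking line search on the EM
  objective (the node positions move with the parameters, making
  this a generalized EM; the safeguard preserves the monotone
  deviance guarantee that the test suite asserts at $10^{-6}$ per
  step).

Identification follows the user's constraint: *cases* fixes $\mu = 0$
and estimates $\sigma$ with difficulties free; *items* fixes the
grand mean of all step difficulties at 0 (applied by recentring and
compensating through $\mu$, which leaves the likelihood unchanged)
and estimates both $\mu$ and $\sigma$.  Convergence is declared when
the deviance change and the largest parameter change both fall below
`convergence_tol` (default $10^{-4}$); hitting `max_iterations`
(default 500) returns the fit with `converged = FALSE` and a warning
rather than an error, so long or degenerate runs still yield
inspectable output.

The deviance reported is $-2\log$ marginal likelihood under the
quadrature representation.  `deviance_by_grid()` re-evaluates it by
brute-force integration on a 10&nbsp;000-point grid; the suite requires
agreement within $10^{-3}$ on toy data, which pins down the quadrature
error directly.

Items with no observed score variation are excluded from calibration
and reported in `notes`; interior categories that never occur are
collapsed onto the observed ordered categories with a note.  Both
choices favour loud bookkeeping over silent failure.

## Person abilities

`estimate_abilities()` offers maximum likelihood (MLE) and Warm's
weighted likelihood (WLE).  The MLE solves
$\sum_i (x_i - E[X_i\,|\,\theta]) = 0$ over administered items; its
standard error is the inverse square root of the test information
$\sum_i \mathrm{Var}(X_i\,|\,\theta)$, which for dichotomous items is
the familiar $[\sum p(1-p)]^{-1/2}$.  Zero and perfect raw scores
have no finite MLE, so they receive a half-point score correction
(0.3 score points, solved against the expected-score curve) and an
`EXTREME` flag — every person gets a finite ability and standard
error, which downstream narration (the min/max SE summary) relies
on.  WLE adds the $J/2I$ penalty to the score function and needs no
correction.  The 0.3 half-point choice is a convention; any value in
(0, 0.5) gives the same qualitative behaviour, and it is echoed in
the Settings sheet.

Item standard errors follow the Fisher step-information sum
$[\sum_n S_j(\theta_n)(1-S_j(\theta_n))]^{-1/2}$ with
$S_j = P(X \ge j)$, evaluated at the estimated abilities — the
classical $[\sum_n P_n(1-P_n)]^{-1/2}$ for dichotomous items.

## Classical test theory

Item-rest correlations are Pearson correlations with the rest score
(total minus the focal item), pairwise complete.  Confidence
intervals use the Fisher $z$ transform with standard error
$1/\sqrt{n-3}$ — the method is recorded in the Settings sheet because
bootstrap intervals would be an equally defensible choice.
Attenuation-corrected coefficients use the biserial correction
$r_b = r_{pb}\sqrt{p(1-p)}/\phi(z_p)$ for dichotomous items and its
polyserial generalization $r\,s_x / \sum_k \phi(\tau_k)$ (two-step,
thresholds from cumulative proportions) for polytomous ones; the
two-step form was chosen over full maximum likelihood for robustness
on small samples, and it reduces exactly to the biserial form at two
categories.  Cronbach's alpha uses complete cases (a pairwise
covariance alpha is deliberately not offered — determinism of the
published statistic) and is banded at 0.50/0.60/0.70/0.80/0.90.

Flag semantics are strict inequalities: an item-rest correlation
exactly at the threshold is *not* flagged (`LOW_R` fires strictly
below the cut, default 0.10).  Flags are unions — `LOW_R`,
`NEGATIVE_R`, `CI_BELOW_ZERO`, `ALPHA_GAIN`, `ZERO_VARIANCE` can
co-occur.

## Diagnostics

Thurstonian thresholds $\gamma_{ij}$ solve $P(X \ge j\,|\,\theta) =
0.5$ by bisection to $10^{-8}$; cumulative probabilities are strictly
monotone, so these are always ordered within an item even when the
step difficulties are disordered, and they carry the
`I-<item>-<category>` labels used on Wright maps and in the
developmental report.  The orderedness table computes, per
item-category, the point-biserial of category membership against
estimated ability and the mean ability of members; an item is flagged
when either sequence fails to increase strictly with the category
(ties count as disordered — conservative flagging).  The point-
biserial is taken against estimated $\theta$, not the rest score,
matching how category functioning is interpreted on the latent
metric.

Person misfit uses the outfit mean square (mean squared standardized
residual over administered items) with default bounds (0.7, 1.3):
Guttman-deterministic patterns fall below, erratic patterns above.
The bounds are exposed in `flag_config()` because no single interval
suits every test length; with few items the statistic is noisy and
flags should be read as screening, not verdicts.

The Wright map is emitted as data (person histogram bins plus
labelled thresholds on one logit axis; counts conserve N) rather than
an image, and a targeting summary compares the person mean with the
threshold mean, driving the narrated recommendation (e.g. larger
standard errors at the top of the ability range suggest adding harder
items).

## Facets DIF

The facets model makes the effective difficulty of item $i$ for group
$g$ equal to $\delta_i + G_g + D_{gi}$.  One design question was
genuinely open: whether each group should get its own latent ability
distribution.  With free group means, a per-group difficulty constant
is absorbed by the group's ability mean, which makes $G_g$
unidentifiable; raschkit therefore estimates a *single* common
$N(\mu,\sigma^2)$ population, letting $G_g$ (sum-to-zero over
groups) carry the group-level effect and $D_{gi}$ — sum-to-zero over
groups per item *and* over items per group — carry pure DIF.  These
constraints are applied exactly at every M-step exit, so the reported
effects satisfy them to $10^{-8}$.  With two groups the interactions
are mirrored, $D_{1i} = -D_{2i}$, and a positive $D_{gi}$ means the
item is harder for group $g$.

Flags are dual and independent: `STATISTICAL` when
$|D_{gi}|/\mathrm{se}(D_{gi})$ exceeds the two-sided normal critical
value at `dif_alpha` (default 0.05), `PRACTICAL` when the
between-group gap (for two groups, $2|D_{gi}|$) reaches
`dif_practical_logits` (default 0.5 logits — a conventional
magnitude for "worth investigating", surfaced as a config default
rather than hidden).  No multiple-testing correction is applied by
default: flags are per-item screening devices, and at 20 items and
$\alpha = 0.05$ one expects a false statistical flag per analysis,
which is why the practical flag exists.  Interaction standard errors
use the Fisher information of the group-item shift at the estimated
abilities, combined through the sum-to-zero centring.

## Equating

Two independently calibrated forms are compared on their link items,
matched by exact case-sensitive label.  Form B link difficulties are
first shifted by a single constant so the link means agree — this
enforces the zero-sum identity $\sum_i (\delta_i - \delta'_i) = 0$
and absorbs any pure origin difference between calibrations.  On the
aligned differences, $z_i = (\delta_i - \delta'_i)/
\sqrt{se_i^2 + se_i'^2}$ flags potentially non-invariant links
(reported, never auto-dropped; an optional purification loop was
considered and rejected as a default because silently dropping links
changes the scale), and the equating error is $\varepsilon =
\sqrt{\sum d_i^2/(L-1)}\,/\sqrt{L}$.

The reported scale comes from a separate fixed-anchor refit: Form B
is re-estimated with the link items frozen at their Form A values, no
centring constraint, and the Form B population mean and SD free —
identification flows entirely through the anchors, which is what
places Form B persons and its unique items on the Form A metric.
Anchor rows in the output are bit-equal to their input values.
Diagnostics from the independent calibrations and the scale from the
anchored refit are deliberately different computations: the former
answers "may I equate?", the latter "what are the equated values?".

## Group statistics

The ANOVA on ability is the classical fixed-effects one-way
decomposition (via `aov`), with a Shapiro–Wilk check on residuals
that is reported but never gates the analysis, estimated marginal
means (via `emmeans`), and Tukey HSD pairwise comparisons from the
studentized range distribution; with two groups the Tukey-adjusted p
equals the pooled t-test p ($q = \sqrt2\,t$).  The grouping table is
joined positionally with a strict length check, because the persons
sheet and grouping file carry no shared key.

Intraclass correlations are computed from the one- or two-way ANOVA
mean squares in the Shrout–Fleiss/McGraw–Wong forms, with F-based
confidence limits (Satterthwaite degrees of freedom for the two-way
agreement case).  Defaults are two-way random, agreement, single
unit, 95% CI — the most conservative of the common choices — and all
four options are switchable.  Complete tables are required; there is
no principled single imputation for missing ratings, so the function
refuses rather than guesses.

## Synthetic data

`sim_design()` encodes the study conditions the generators emulate:
abilities $N(0,1)$, item locations equally spaced on $(-2, 2)$ —
a well-targeted test in which persons and items line up on the
Wright map — with the I-by-N grid (items 20–80, persons 50 upward)
used for scale testing.  Polytomous step difficulties spread
$\pm 0.5$ logits around the item location.  DIF is injected
symmetrically ($\pm$`dif_size`/2 per group) so the sum-to-zero
decomposition recovers $\pm$`dif_size`/2 without confounding the
group main effect.  Linked forms share their `n_link` hardest
reference-form items under identical labels and true difficulties,
with an optionally shifted Form B population — the situation
fixed-anchor equating exists to resolve.  Rater tables follow a
one-way random-effects model with variance components chosen so the
population single-rater ICC equals the target.

What the generators do *not* emulate: multidimensionality, guessing,
item drift other than the injected DIF, dependence between items
beyond the latent trait, and non-normal ability populations.  Tests
passing on these fixtures demonstrate correctness of the estimation
machinery under the model's own assumptions, not robustness to their
violation.

## Problem sizes and numerical choices

The test suite runs its recovery studies at the sizes the methods are
documented for: difficulty recovery at 20 items × 2000 persons
(RMSE < 0.12), DIF recovery at 5000 persons, equating at 2000 per
form, ICC at 2000 × 3; oracle comparisons (grid integration, hand
sums of squares, closed forms) run on deliberately tiny inputs where
brute force is exact.  Bisection tolerance for thresholds is
$10^{-8}$; sum-to-zero constraints hold to $10^{-8}$; EM monotonicity
is asserted at $10^{-6}$ per step.  Ties in orderedness count as
disordered; flag inequalities are strict at their thresholds.

## Known limitations

- One grouping facet only; no rater-facet chains or three-way
  interactions.
- Single-pair equating; no chained equating across more than two
  forms, and no equipercentile/mean-sigma/Stocking–Lord alternatives.
- No 2PL/3PL/4PL or rating-scale models — the package is built
  around the sufficiency and common-scale properties of the Rasch
  family.
- The workbook is a sheet-per-CSV directory bundle with fixed sheet
  names and order; any spreadsheet program can import the sheets, but
  it is not a single binary file.
- Person misfit bounds and the practical-DIF magnitude are
  conventions exposed as configuration, not estimated quantities.
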