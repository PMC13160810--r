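---
title: "Prioritizing survey-derived requirements with Kano, AHP, TRIZ and TOPSIS"
author: "needsmcda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing survey-derived requirements with Kano, AHP, TRIZ and TOPSIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needsmcda)
```

## The problem

Design studies of public-service facilities — the bundled worked example
concerns community health emergency stations for older adults — routinely
collect three kinds of evidence: paired Kano questionnaires telling *what
kind* of requirement each candidate feature is, expert pairwise judgments
telling *how much* each requirement matters, and Likert ratings of
concrete design alternatives telling *which scheme* best serves the
weighted requirements. `needsmcda` implements that chain as one tested
pipeline: Kano classification → reliability/validity checks → AHP
weighting with consistency diagnostics → advisory contradiction analysis
→ TOPSIS ranking.

## Kano classification

Each respondent answers every indicator twice on the 5-level scale
*like / must_be / neutral / live_with / dislike*: once assuming the
feature is present (functional form), once assuming it is absent
(dysfunctional form). The pair indexes a 5×5 evaluation table with six
outcomes: Attractive (A), One-dimensional (O), Must-be (M), Indifferent
(I), Reverse (R) and Questionable (Q). The table itself is a modelling
choice, so it ships as an overridable CSV; the default is the
conventional one — (like, dislike) → O, like against a middle answer →
A, a middle answer against dislike → M, the two agreeing extremes → Q,
any pair in which absence is strictly preferred to presence → R, and the
nine middle cells → I (cell counts 1/2/3/3/7/9 for O/Q/A/M/R/I).

Per indicator, `kano_tabulate()` reports the category fractions and the
Better–Worse coefficients

$$\mathrm{Better} = \frac{A+O}{A+O+M+I}, \qquad
  \mathrm{Worse} = -\frac{O+M}{A+O+M+I},$$

with R and Q excluded from the denominator as is standard. The final
demand type is the most frequent of A, O, M, I (`kano_assign()`); R and Q
are reported but never win. Ties are broken by a configurable precedence
defaulting to **M > O > A > I**: in a safety-critical facility a
requirement that could plausibly be must-be should be treated as must-be.
Because only relative frequencies are compared, assignment is invariant
to renormalizing a row by any positive constant — which matters because
the bundled aggregate rows do not sum to 100% and are renormalized on
load.

Three bundled rows (B1, B2, D1) carry reported category labels that *no*
max-frequency rule can reproduce from their own percentages (argmax gives
I, I, A where M, O, M are reported), and the reported Better–Worse
columns are likewise inconsistent with the standard formulas (some rows
exceed 100%). The package does not guess at an unrecoverable rule: it
computes the standard quantities and writes each disagreement to the
pipeline's divergence log.

## Reliability and validity

`psychometric_report()` bundles the three questionnaire checks usually
reported alongside a Kano study: Cronbach's
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$,
the Kaiser–Meyer–Olkin measure
$\mathrm{KMO} = \sum_{i \ne j} r_{ij}^2 \big/ \bigl(\sum_{i \ne j} r_{ij}^2 +
\sum_{i \ne j} q_{ij}^2\bigr)$
with partial correlations $q_{ij}$ from the scaled inverse correlation
matrix, and Bartlett's sphericity statistic
$\chi^2 = -(n - 1 - \tfrac{2p+5}{6})\ln\det R$ on $p(p-1)/2$ degrees of
freedom. All variances use the $n-1$ convention; the item count is always
taken from the data, never from a constant. The raw item-level responses
behind the worked example were not published, so its reported α = 0.910,
KMO = 0.912 and χ² values are not recomputable; correctness rests instead
on closed forms (two-item α, the Spearman–Brown limit, equicorrelated
KMO), exact constructions whose sample correlation matrix is the identity,
null-calibration simulations, and equivalence with independent
regression-residual oracles.

## AHP weighting

Local priorities come from Saaty pairwise ratio matrices. The default
estimator is the dominant eigenvector by power iteration (uniform start,
convergence when successive sum-normalized iterates differ by less than
1e-12 in max-norm, capped at 10,000 iterations, λ_max from the Rayleigh
quotient); the row-geometric-mean estimator is available and agrees to
well under 1e-3 L1 on near-consistent matrices. Consistency is
CI = (λ_max − n)/(n − 1) and CR = CI/RI with Saaty's classic RI table
shipped as a data file; CR = 0 for n ≤ 2, and orders outside the table
raise a configuration error rather than extrapolating. The order n is
always taken from the matrix.

Reciprocity (a_ij·a_ji = 1, unit diagonal) is definitional for AHP, yet
published judgment grids — including the bundled ones — sometimes violate
it. The constructor therefore accepts any positive square grid,
`validate_reciprocity()` reports the defective cells, and the default
pipeline mode `repair_upper` rebuilds the lower triangle from the upper
before weighting (strict mode errors instead). Repair is idempotent and
every repair is logged as a divergence.

Global weights multiply each indicator's local weight by its criterion
weight and renormalize to sum to 1, ranking by descending weight with
stable input-order ties. The bundled example's reported "comprehensive
weights" are *not* products of its reported layer weights (its criterion
values even exceed 1), so the package computes the product-and-normalize
synthesis and records the disagreement rather than reproducing the
reported column.

## TRIZ stage

The contradiction stage is deliberately advisory: it annotates the report
with inventive-principle suggestions and never alters weights or
rankings. Technical contradictions (improve parameter X, worsen Y) are
resolved through a loadable contradiction-matrix file; physical
contradictions (one parameter wanted in two states) have no matrix cell
and carry their principle sets directly, as the worked example does.
Principle order is preserved because it may encode priority. The bundled
parameter numbering follows the source material, which is nonstandard
(it cites an id above 39), so the files assert only the worked example
and claim no correspondence with the classical 39×39 matrix.

## TOPSIS ranking

Mean 7-point scores (expert and user raters pooled with equal weight — no
group weighting is part of the design) form the evaluation matrix F. The
steps are columnwise vector normalization
$R_{ij} = f_{ij} / \sqrt{\sum_i f_{ij}^2}$, weighting
$u_{ij} = W_j R_{ij}$, ideal formation (columnwise max/min for benefit
indicators, reversed for cost; all indicators in the worked example are
benefit), Euclidean distances $S_i^{\pm}$ to the ideals, and relative
closeness

$$C_i = \frac{S_i^-}{S_i^+ + S_i^-} \in [0, 1].$$

This is the only closeness form consistent with "larger is closer to the
ideal"; for any two-alternative all-benefit problem it forces
$C_1 + C_2 = 1$ exactly, which the test-suite verifies at machine
precision on random instances. When $S_i^+ + S_i^- = 0$ (identical
alternatives) $C_i$ is set to 0.5 and flagged. The worked example's
reported closeness pair (0.894, 0.167) violates both the formula and the
two-alternative identity, so it is bundled only as a reference to diff
against: the pipeline computes C = (0.882, 0.118) from the published
score matrix and logs the difference.

Which weight vector fed the worked example's ranking is ambiguous — its
hierarchy has 16 indicator labels but its evaluation matrix 15, and its
combined-weight column sums to 2.268. The bundled configuration therefore
uses that column renormalized to sum to 1, passed explicitly and echoed
in the report; ordinary runs default to the renormalized global AHP
weights whenever their labels match the evaluation indicators.

## Synthetic data and what the tests show

Every stage has a generator with planted ground truth, pure in
(arguments, seed):

* **Kano responses** — a mixture: with probability 1 − ε the answer pair
  is drawn uniformly from the cells of the planted category, with
  probability ε uniformly from all 25 cells. The zero-noise limit is
  exact by construction; the simplest model with that property. The
  default role split mirrors the surveyed composition (241/351 older
  adults), though roles carry no analytic weight.
* **Pairwise matrices** — a_ij = (w_i/w_j)·exp(e_ij) with antisymmetric
  Gaussian log-perturbations, preserving positivity and reciprocity by
  construction; optional snapping to the discrete 1/9…9 scale. σ = 0
  gives a perfectly consistent matrix whose priority vector is w.
* **Likert scores** — truth + Gaussian noise, rounded and clipped to
  1–7, so a mean-recovery oracle exists while scores stay on scale.
* **Factor items** — x = λf + √(1−λ²)e, giving population inter-item
  correlation λ² and hence a Spearman–Brown target for α and a null
  (λ = 0) calibration for Bartlett.

These emulate clean versions of the study conditions; they deliberately
omit demographic effects on responses, missing data, within-rater
correlation and acquiescence bias. Passing recovery tests therefore shows
the estimators are correct, not that real questionnaires are this
well-behaved.

Suite sizes (chosen to probe the asymptotics the closed forms describe
while keeping the default run quick): Bartlett null calibration 500
replicates of n = 200, p = 10; planted-Kano recovery 100 seeds of 200
respondents × 19 indicators at ε = 0.1; AHP σ-monotonicity 200 seeds per
σ ∈ {0.05, 0.15, 0.3} at n = 5; α vs Spearman–Brown at n = 2000, k = 10;
oracle equivalence on 50 random item matrices to 1e-8.

## Numerical choices and degenerate inputs

Fraction strings (`"1/3"`) are parsed wherever judgments appear; CSV I/O
is UTF-8 with RFC-4180 quoting, and matrices are written at 17
significant digits so write-then-read round-trips exactly. Reports round
to 3 decimals for weights and closeness and 1 decimal for Likert means,
with full precision kept internally; two runs with identical inputs and
seed produce byte-identical reports. Degenerate cases are explicit
errors, never silent repairs: indicators answered only with R/Q, all-zero
evaluation columns, singular correlation matrices (reported with a
condition-number diagnostic), λ_max below n, and matrix orders outside
the RI table.

## Limitations

The package computes with published aggregates where raw data were not
deposited, so several reported values of the worked example are
documented divergences rather than regression targets; the divergence log
is the honest boundary between what the methods reproduce and what the
source printed. No group aggregation of multiple judges' matrices, no
fuzzy-AHP, no factor extraction beyond the adequacy statistics, and no
automated identification of contradictions from requirement text.
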