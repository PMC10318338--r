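---
title: "Additive MCDA with pairwise preference elicitation and probabilistic sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive MCDA with pairwise preference elicitation and probabilistic sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mcdaid)
```

## The decision model

`mcdaid` implements the additive multi-attribute value model used throughout
applied multi-criteria decision analysis (MCDA).  A decision problem has a
set of *alternatives* (here: types of quality-improvement intervention), a
set of *criteria* each measured on an ordered scale of qualitative
performance levels (worst first), and a *performance matrix* assigning each
alternative a level on each criterion.  Two scoring rules are supported:

* **Unweighted**: the levels of an $L$-point scale are coded $1 \dots L$
  and summed over criteria.  This is the "equal importance" model used when
  no preference data exist.
* **Weighted**: every level of every criterion carries a *part-worth*
  $S_{ij}$ (percent), with the worst level worth 0 and the best level worth
  the criterion's weight $W_i$; the total value of alternative $j$ is the
  additive model
  $$V_j = \sum_{i=1}^{n} S_{ij}, \qquad
    \sum_i W_i = 100,$$
  where $S_{ij}$ is the part-worth of the level alternative $j$ attains on
  criterion $i$ (so $V_j$ lies between 0 and 100).

The bundled case study ranks four medication-optimisation intervention
types for English NHS hospitals over ten implementation criteria selected
from the Consolidated Framework for Implementation Research, with weights
elicited from a national survey of 356 quality improvers:

```{r}
fit <- mcda(medopt_matrix(), medopt_criteria(), medopt_values())
fit
```

### Numerical conventions

* Published part-worth tables are printed to one decimal.  Totals over such
  tables are accumulated in integer tenths, so the reported weighted totals
  are exact decimal sums, not floating-point approximations.  Value systems
  that are not one-decimal (e.g. fitted or aggregated ones) are summed in
  ordinary double precision.
* Ranking is dense and tie-aware: equal scores (within a configurable
  tolerance, default exact equality) share a rank rendered "Joint
  *k*-th", and the next distinct score takes the next consecutive rank.
  This reproduces rank layouts such as First / Second / Joint third / Joint
  third over four alternatives.
* Red/amber/green rendering is defined only for three-level scales (rank 0
  is red, 1 amber, 2 green); every other operation accepts arbitrary
  $L \ge 2$.

### Fixture authority

The case-study tables disagree with each other in three printed cells
(`medopt_discrepancies()` lists them).  The package follows the numeric
score table, because its columns sum exactly to the published totals; the
qualitative grid and the published level-weight table are preserved
verbatim as the `"qualitative"` matrix and `"survey"` value variants, and
`validate_files()` emits exactly two documented warnings when validating
the packaged fixtures — one for the matrix-label drift, one for the
level-value drift.

## Pairwise trade-off elicitation

Criterion weights are elicited in the style of the PAPRIKA family of
methods: respondents repeatedly choose between two hypothetical
alternatives that differ on exactly two criteria, with neither dominating
the other, and every unasked comparison that the answers imply by
transitivity is resolved automatically.

Internally every question compares two *swing quantities* — the value
difference between two levels of one criterion against the value
difference between two levels of another.  For $n$ criteria with $L$
levels there are $\binom{n}{2}\binom{L}{2}^2$ undominated question pairs
(9 for two 3-level criteria; 405 for the case-study design of ten 3-level
criteria).

* **Adaptive question choice.**  `next_question()` returns the unresolved
  pair whose possible strict answers would resolve, by transitivity, the
  largest expected number of other unresolved pairs (the expectation is
  the mean of the two strict outcomes; ties break by enumeration order, so
  sessions are deterministic given the answers).  In practice a noiseless
  respondent on the case-study design answers roughly 120–190 of the 405
  pairs explicitly.
* **Transitive closure.**  Strict preference and indifference are closed
  under transitivity over the swing quantities, together with the
  within-criterion dominance relations (a wider level swing strictly
  contains a narrower one).  Cyclic judgement sets are rejected with a
  witness cycle rather than repaired.  Because the adaptive loop only ever
  asks unresolved questions, a simulated session can never produce a
  transitive cycle — respondent noise surfaces as *wrong but coherent*
  answers, exactly as in an adaptive survey.

### Solving for part-worths

After (or during) a session the respondent's part-worths are any value
vector whose swing quantities respect the elicited order.  Two
deterministic solution rules are implemented, both constrained by: worst
level worth 0; strictly positive level steps; every strict preference held
with margin at least `epsilon` (default $10^{-3}$ on the 0–100 scale, a
pure feasibility floor — fitted orderings are invariant to its scale);
indifferences held with zero margin; and the all-best profile normalised
to 100.

* `method = "maxmin"` maximises the smallest strict margin and then
  minimises total part-worth mass as a tie-break (a small
  ridge-regularised quadratic program).  This rule is simple but sits on a
  face of the feasible polytope, and the tie-break does not constrain the
  best-level values at all once the normalisation is fixed, so criterion
  weights from single respondents can be arbitrary within the ordinal
  constraints.
* `method = "center"` (the default) refines the max-min solution to the
  *analytic centre* of the constraint polytope: it maximises the sum of
  logarithmic barriers over all strict margins and step positivities, with
  indifference classes enforced by a quadratic penalty ($\lambda = 10^4$;
  observed equality residuals are below $10^{-3}$, two orders of magnitude
  under the smallest strict gaps, so ties and strict preferences remain
  cleanly separable at a 0.01 tolerance).  Being central rather than
  extreme, this estimate tracks the generating values far better in
  simulation: a noiseless 50-respondent cohort dispersed around the
  case-study weight table is recovered to within well under one weight
  point per criterion.

If a judgement set is transitively consistent but *additively* infeasible
(possible under choice noise: e.g. preferring criterion A's lower and
upper swings to B's while preferring B's full swing to A's), the solver
falls back to an extended log barrier that is finite everywhere and flags
the fit with `feasible = FALSE`; `on_infeasible = "error"` turns this into
an inconsistency error instead.

Group aggregation is the arithmetic mean of level part-worths across
respondents, so group weights are mean best-level values and still sum
to 100.  The published description of the case study reports mean
preference values, which is what motivated this choice; re-normalised
medians would be a straightforward alternative but are not implemented.

## Probabilistic sensitivity analysis

Uncertainty is propagated by Monte Carlo simulation (default 1000
iterations) under three scenarios:

* **Scores** — every non-zero weighted contribution $c$ is replaced by a
  gamma draw with mean $c$ and standard deviation $cv \cdot c$
  (shape $1/cv^2$, scale $c\,cv^2$); zero contributions stay zero.  The
  parameterisation is mean-preserving and scale-free; the default
  $cv = 0.1$ produces interval widths of the same order as the published
  case-study intervals and is a calibration knob, not an estimate.
* **Weights** — criterion weights are redrawn from a Dirichlet
  distribution with parameters $\alpha_i = \kappa W_i / 100$, which
  matches the elicited means exactly and leaves the spread to the
  concentration $\kappa$ (default 100, likewise a documented knob: the
  case study states only that observed means parameterised the
  distribution).  Each criterion's level values are rescaled
  proportionally to its drawn weight, and the perturbation is applied to
  weighted contributions so that all three scenarios live on one scale.
* **Both** — the weight draw is applied first and the gamma perturbation
  is applied to the rescaled contributions.

Each iteration recomputes all total scores; the report gives expected
values, equal-tailed 2.5–97.5 percentile intervals (the case study prints
"95% CI" without stating a method), and first-rank acceptability with
within-iteration ties broken uniformly at random.  Results are
bit-for-bit reproducible given a seed.  By linearity of expectation the
weights-only expected totals equal the deterministic totals, and at the
default settings all three scenarios preserve the deterministic rank
order of the case study:

```{r}
p <- run_psa(fit, scenario = "weights", seed = 42)
p
```

The published per-scenario means and the "chosen 78 times out of 100"
figure depend on variance settings the study does not report, so they are
treated as qualitative rank-order checks only, not as numeric targets.

## What the synthetic generator does (and does not) emulate

`synthetic_respondent()` answers questions from a latent additive value
function through a logistic choice rule with inverse temperature $\beta$
(per unit of value difference on the 0–100 scale): $\beta = \infty$ is a
deterministic truth-teller, $\beta = 0$ a coin flipper.
`generate_cohort()` disperses criterion weights around a centre value
system with a Dirichlet distribution (concentration `kappa_pop`, default
200, chosen to give a few points of between-respondent weight spread —
the real survey reports no respondent-level variance to calibrate
against) while keeping within-criterion level profiles proportional to
the centre.

Passing the simulation tests therefore shows that the elicitation and
aggregation machinery recovers the preference structures this generator
produces; it does not show robustness to features of real survey data the
generator omits — correlated criterion preferences, attention lapses that
are not exchangeable across questions, partial sessions, or systematic
subgroup differences.

## Problem sizes used by the test suite

The closure oracle property is exhausted over all instance sizes up to 3
criteria × 3 levels; fit properties use 3-criterion instances and the
full 10 × 3 case-study design; the cohort-recovery property uses 50
noiseless respondents (about half a minute of compute); PSA properties
use 1000 iterations with a 10 000-iteration moment check.  These sizes
were chosen so the whole suite exercises every code path in well under
two minutes on a single core.

## Known limitations

* Only two-criterion questions are generated (pair order 2).  The
  elicited order therefore constrains, but does not uniquely determine,
  comparisons of full multi-criterion profiles; fitted values resolve
  such comparisons the way the analytic centre does.
* Indifference constraints are enforced by penalty, not exactly; ties are
  reproduced to about $10^{-3}$ on the 0–100 scale.
* The gamma score perturbation is applied to weighted contributions, not
  to raw ordinal scores, and draws are neither truncated nor renormalised
  to keep totals below 100 — extreme draws can exceed the deterministic
  maximum, which matters only at large `cv`.
* Group aggregation assumes identical criteria and level sets across
  respondents; partial-session imputation is out of scope.
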