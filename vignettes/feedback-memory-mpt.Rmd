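---
title: "Modelling memory for veracity feedback with multinomial processing trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling memory for veracity feedback with multinomial processing trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedbackmpt)
```

## The problem

When people study statements together with veracity feedback ("true",
"false", or a non-informative "?") and are later tested on both recognition
("old or new?") and feedback attribution ("was it marked true, false, or
?"), observable attribution accuracy confounds three distinct cognitive
processes: memory for the statement itself, memory for the feedback, and
guessing. A plausibility-by-feedback interaction in raw attribution scores —
plausible statements more often correctly called "true", implausible ones
more often correctly called "false" — can therefore arise from genuine
memory differences or purely from plausibility-consistent guessing.

`feedbackmpt` implements the measurement model that disentangles these
processes: a three-source variant of the two-high-threshold
source-monitoring model (2HTSM), fitted to aggregated response frequencies
by maximum likelihood, together with the surrounding analysis pipeline
(behavioral measures, nested-model tests, order-constrained
reparametrisation, synthetic-data generation, power analysis).

## The model

The design crosses 2 plausibility conditions (plausible, implausible) with 4
statement types (studied with "true", "false" or "?" feedback, or new),
giving 8 processing trees. Each tree emits the four responses
("true", "false", "?", "new"). For a statement studied with "true" feedback:

* with probability $D_{true}$ the statement is recognised as old; then
  * with probability $d_{true}$ the feedback is remembered ("true" response);
  * otherwise ($1-d_{true}$) the participant guesses: with $a_{fb}$ that
    feedback was shown, and within that with $a_{true}$ that it was "true";
    with $1-a_{fb}$ they respond "?";
* with probability $1-D_{true}$ the statement is not recognised; with $b$
  they nevertheless guess "old" and then guess feedback via $g_{fb}$ and
  $g_{true}$; with $1-b$ they respond "new".

The "false"- and "?"-feedback trees are mirror-symmetric (the
feedback-memory branch terminates in "false" / "?"), and the new-statement
tree replaces detection with $D_{new}$ (a correct "new" response). All
parameters are estimated separately per plausibility condition, with the
suffix convention `D_P_true`, `d_I_false`, `g_true_P`, etc.

A category probability is the sum over branches of products of parameters
and complements, e.g. for the "true"-feedback tree

$$P(\text{"true"}) = D d + D(1-d)\,a_{fb}a_{true} + (1-D)\,b\,g_{fb}g_{true}.$$

**Identifiability.** The full 8-tree model has 24 free categories and 24
parameters (saturated). The baseline model equates detection of new
statements and statements studied with "?" feedback within each plausibility
condition ($D_? = D_{new}$), a constraint validated in the 2HTSM
literature. This leaves 22 free parameters and a goodness-of-fit test with
2 df. The constraint is represented explicitly (not hard-coded) so it can be
removed or tested; `identifiability_check()` verifies full column rank of
the probability Jacobian at random interior points. Notably, the
*unconstrained* model is also locally identifiable in the strict Jacobian
sense — the constraint's practical role here is to make the model
non-saturated and hence testable.

```{r}
model <- build_feedback_model()
model
```

## Fitting and inference

Frequencies are aggregated over participants into one table per design cell
(complete pooling), matching the aggregate-fit strategy of the original
analysis; per-participant or hierarchical fitting is out of scope. The
multinomial log-likelihood kernel $\sum_c n_c \log p_c(\theta)$ is maximised
on logit-transformed parameters — boundary-safe and unconstrained — by a
quasi-Newton optimizer (PORT via `nlminb`) with analytic gradients, using 20
seeded uniform random starts by default (simulation workloads use fewer
starts plus warm starts). Convergence tolerance is 1e-9 on the objective.

Goodness of fit uses the likelihood-ratio statistic
$G^2 = 2\sum_c n_c \log(n_c/\hat m_c)$ with the conventions: observed 0
contributes 0; expected 0 with observed > 0 yields an infinite $G^2$. With
15,744 observations the fit test detects tiny deviations, so the recommended
fit-test level is $\alpha = .001$, which still gives power > .99 against
small misfit of $w = .05$ (`power_model_misfit()`).

Nested constraints are tested by $\Delta G^2$ referred to $\chi^2$ with df
equal to the number of independent constraints, at $\alpha = .05$. The
standard battery (`run_test_battery()`):

| Test | Constraints | df |
|------|-------------|----|
| 1 | `D_P_true = D_P_false`, `D_I_true = D_I_false` | 2 |
| 2a | `d_P_true = d_P_false`, `d_I_true = d_I_false` | 2 |
| 2b | `s_P_d = s_I_d` (shrinkage model) | 1 |
| 3 | `a_true_P = a_true_I`, `g_true_P = g_true_I` | 2 |

Both fits of a nested pair share the seed and start count, and the
restricted fit warm-starts from the projection of the unrestricted MLE onto
the constraint set (equality classes take the member mean). This avoids
spurious negative $\Delta G^2$; residual negatives within 1e-6 are clamped
to 0, larger ones trigger a refit with doubled starts and a warning.

**Shrinkage reparametrisation.** To compare the *size* of the
expectation-violation effect between plausibility conditions, the
expectation-consistent feedback-memory parameters (plausible+true,
implausible+false) are rewritten as $d_{cons} = s \cdot d_{incons}$ with
$s \in [0,1]$ (`reparametrise_shrinkage()`). In tree form, a branch factor
$d_{cons}$ becomes $s\,d_{incons}$ and a complement factor splits as
$(1-d_{cons}) = (1-d_{incons}) + d_{incons}(1-s)$, so the rewritten model is
still a proper MPT. The order $d_{incons} \ge d_{cons}$ holds by
construction; smaller $s$ means a larger expectation-violation effect. The
free-parameter count is unchanged, and when the unrestricted MLE satisfies
the order, the shrinkage model fits exactly as well as the baseline with
$\hat s$ equal to the ratio of the $d$ estimates.

**Confidence intervals** are Wald intervals on the probability scale from
the inverse observed information (finite-difference Hessian), clipped to
$[0,1]$ — the convention of standard MPT software. When the information
matrix is singular or an estimate lies within .01 of a boundary, a
profile-likelihood interval is substituted and flagged. $p$-values use the
central $\chi^2$; for the boundary case $s = 1$ this reference is known to
be conservative (the mixture-distribution issue), which we accept to stay
with standard practice.

## Behavioral measures

For each participant and plausibility-by-feedback cell ("true"/"false"
feedback only; "?" trials enter the model frequencies but not these
measures):

* **CSIM** — correct feedback attributions / correct "old" responses;
  undefined when the participant recognised nothing in the cell;
* **SIM** — correct feedback attributions / all 6 targets; always defined,
  but confounded with item memory;
* **Pr** — hit rate minus false-alarm rate over the whole test; participants
  with $Pr \le 0$ (no item memory) are excluded, along with self-reported
  non-serious participation, note taking, and language problems
  (`apply_exclusions()`).

The 2 (plausibility) x 2 (feedback) within-subject ANOVA
(`rm_anova_2x2()`) is computed from difference-score contrasts; for 2-level
factors each effect's F is exactly the squared paired t on its contrast (the
test suite cross-checks against `aov()` with error strata). CSIM analyses
drop participants with an undefined cell listwise; SIM analyses keep
everyone. Two-sided tests throughout; sphericity is not an issue with
2-level factors.

## Synthetic data

`simulate_trials()` draws each trial's response from the branch distribution
of its design-cell tree. The default `design_spec()` reproduces the study
conditions: 328 participants, 6 statements per plausibility-by-condition
cell, hence 48 test trials per participant (36 studied + 12 new, the new
statements split 6 plausible / 6 implausible) and 15,744 observations in
total. All participants share one parameter vector (complete-pooling
generative model), matching the aggregate fitting strategy. Generation is
vectorised per design cell under a single seeded RNG stream; regeneration
with the same seed is bit-identical. Only test-phase responses are
simulated — study-phase timing, buffers and the retention task do not enter
the analysis.

Named scenarios (`make_effect_scenario()`):

* `"study-estimates"` — the aggregate-fit estimates of the plausibility
  study (e.g. `d_I_true = .77` vs `d_I_false = .62`, `g_true_P = .65` vs
  `g_true_I = .36`);
* `"null"` — every battery-tested pair equated (member means), for type-I
  calibration;
* `"expectation-violation-d"` — a planted feedback-memory advantage of
  `delta_d` (default .10, placed symmetrically around the null value) for
  expectation-inconsistent feedback in both conditions, the effect size the
  study was powered for;
* `"guessing-only"` — memory parameters flat across all cells; only the
  "true"-guessing parameters differ by plausibility. This scenario
  reproduces the observable SIM crossover interaction without any memory
  differences — the study's headline point that raw attribution measures
  confound guessing with memory.

What the generator does *not* emulate: participant heterogeneity (real
response vectors are overdispersed relative to a common-theta multinomial),
item effects, and response omissions. Passing recovery and calibration tests
therefore validate the estimation machinery under the model's own
assumptions, not robustness to misspecification on real data.

## Power analysis

* `power_model_misfit()` — analytic noncentral-$\chi^2$ power of the fit
  test against misfit of effect size $w$ ($\lambda = n w^2$).
* `power_delta_g2()` / `required_n_delta_g2()` — simulation-based power of a
  nested test, running the package's own simulate-aggregate-test pipeline
  per replicate (no closed-form $\Delta G^2$ noncentrality is assumed);
  default 1000 replicates for reported estimates (about +-3 percentage
  points), 200 for sample-size searches, with a binomial Monte-Carlo CI.
  Required-N uses a doubling-then-bisection grid and is bit-reproducible
  given the seed and grid settings.
* `required_n_rm_anova()` — analytic noncentral-F sample size for the 2x2
  within-subject interaction. The default convention is
  $\lambda = f^2 N m/(1-\rho)$ with $m = 4$ repeated measures, numerator
  df 1 and denominator df $N-1$; external power programs differ in whether
  the $m/(1-\rho)$ multiplier is applied, so the convention is an explicit
  argument. At $f = .10$, $\rho = .50$, $\alpha = .05$, power .90 this gives
  N = 134.

## Numerical choices and problem sizes

* Optimization tolerance 1e-9 (objective), logit scale, analytic gradients;
  oracle tests require agreement with exhaustive .001-step grid search on
  toy models with up to 3 free parameters.
* Tree normalization is property-tested at 1000 random parameter draws
  (tolerance 1e-10); $G^2$ at model-implied frequencies must vanish below
  1e-6.
* The test suite's simulation studies use 200 replicates for parameter
  recovery and mechanism demonstrations and 1000 replicates for type-I
  calibration of the battery, all at the full study size N = 328; power
  unit tests use smaller designs (N = 60-150, 25-400 replicates) to keep
  the default run fast.
* Degenerate inputs: vertex parameter vectors yield exact one-hot
  distributions; zero observed counts contribute nothing to the likelihood;
  boundary estimates switch to profile intervals; ANOVA contrasts with zero
  variance return F = 0 (or infinite F for a nonzero mean difference).

## Known limitations

* Aggregate (complete-pooling) fitting only; no hierarchical or Bayesian
  MPT variants, no bootstrap CIs.
* Wald CIs can undercover for parameters near boundaries or with little
  information (e.g. feedback memory for "?" trials); the profile fallback
  mitigates but does not remove this.
* The $\chi^2$ reference for order-constrained tests at the $s = 1$ boundary
  is conservative.
* EQN I/O covers the multiTree/MPTinR product-term dialect; equality
  constraints and fixed values are not representable in EQN and must be
  re-applied after reading.
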