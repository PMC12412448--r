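# feedbackmpt

Multinomial-processing-tree (MPT) analysis of memory for veracity feedback.

## What this is for

In veracity-feedback experiments, participants study statements of high or
low plausibility together with feedback ("true", "false", or an
uninformative "?") and are later tested: *was this statement presented?*
and, if "old", *which feedback did it carry?* Raw attribution accuracy in
such designs confounds three processes — memory for the statement, memory
for the feedback, and guessing — so an observed interaction between
plausibility and feedback (plausible statements called "true", implausible
ones called "false") cannot by itself be attributed to memory.

`feedbackmpt` is for researchers in memory/mathematical psychology who want
to separate these processes. It implements:

* the **three-source two-high-threshold source-monitoring model** for the
  2 (plausibility) x 4 (statement type) design: 8 processing trees over the
  responses ("true", "false", "?", "new") with statement-memory parameters
  `D`, feedback-memory parameters `d`, and guessing parameters `b`,
  `a_fb`/`a_true`, `g_fb`/`g_true`, estimated per plausibility condition.
  The baseline model equates `D_? = D_new` within condition (22 free
  parameters, 24 free categories, fit df = 2);
* **maximum-likelihood fitting** of aggregated category frequencies with the
  likelihood-ratio statistic `G^2 = 2 Σ n log(n/m̂)`, multi-start seeded
  optimization on the logit scale with analytic gradients, Wald/profile 95%
  confidence intervals, and numerical identifiability checks;
* **nested-model tests** (`ΔG^2` against `χ²`) including the standard
  battery — Test 1 (statement memory), 2a (feedback memory), 2b (shrinkage
  asymmetry), 3 (plausibility-consistent guessing) — and the
  **order-constrained shrinkage reparametrisation** `d_consistent = s ×
  d_inconsistent` with `s ∈ [0,1]` quantifying the expectation-violation
  effect;
* **behavioral measures**: CSIM (correct attributions among correct "old"
  responses), SIM (among all targets), discrimination index `Pr`,
  exclusion rules, 2x2 within-subject ANOVA and paired follow-up tests;
* a **synthetic-data generator** reproducing the study design (328
  participants x 48 trials; 6 per cell) with named effect scenarios;
* **power analysis**: analytic noncentral-`χ²` power of the fit test against
  misfit `w`, simulation-based power/sample size for `ΔG^2` tests, and
  analytic noncentral-F sample size for the within-subject interaction;
* **EQN file I/O** in the multiTree/MPTinR dialect for interchange with
  other MPT software.

## Worked example

Simulate a cohort at the estimate-based scenario, fit the model, and run the
full analysis:

```r
library(feedbackmpt)

model <- build_feedback_model()
model
#> MPT model: 8 trees, 24 free categories, 22 free parameters (df = 2)
#>   equalities: D_P_new = D_P_q, D_I_new = D_I_q

theta <- make_effect_scenario("study-estimates")
sim <- simulate_trials(model, theta, design_spec(328), seed = 2026)
freq <- aggregate_trials(sim$trials)
sum(freq$count)
#> [1] 15744

battery <- run_test_battery(freq, seed = 2026)
battery
#> Baseline model: G^2(2) = 1.270, p = 0.53 (fit test at alpha = 0.001)
#>   test delta_g_squared delta_df  p_value significant
#> 1    1          18.777        2 8.37e-05        TRUE
#> 2   2a          31.286        2 1.61e-07        TRUE
#> 3   2b           5.765        1 1.63e-02        TRUE
#> 4    3         119.310        2 1.24e-26        TRUE

round(battery$shrinkage_fit$estimates[c("s_P_d", "s_I_d")], 2)
#> s_P_d s_I_d
#>  0.93  0.83

rm_anova_2x2(measure_table(sim$trials), "sim")
#> 2x2 repeated-measures ANOVA on SIM (n = 328 complete, 0 dropped)
#>        effect      F df1 df2       p partial_eta_sq
#>  plausibility  3.387   1 327 0.06660         0.0103
#>      feedback  2.296   1 327 0.13100         0.0070
#>   interaction 10.120   1 327 0.00161         0.0300
```

Reading the output: the baseline model fits (`G^2(2) = 1.27`, not rejected
at the stringent α = .001 used for the fit test). Equating statement-memory
parameters across feedback (Test 1) or feedback-memory parameters (Test 2a)
significantly worsens fit, so both differ by feedback condition; the
shrinkage parameters show the expectation-violation effect on feedback
memory is stronger for implausible (`s_I = .83`) than plausible statements
(`s_P = .93`, Test 2b); and "true"-guessing differs strongly by plausibility
(Test 3). At the level of raw behavior, the SIM ANOVA shows the crossover
interaction, `F(1, 327) = 10.1` — which the model attributes to guessing
plus statement memory, not feedback memory alone. The `"guessing-only"`
scenario demonstrates this confound directly: it produces the SIM
interaction with no memory differences at all.

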