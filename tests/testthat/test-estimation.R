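test_that("expected frequencies are total times category probability", {
  m <- build_feedback_model()
  th <- make_effect_scenario("null"); th[] <- 0.5
  ef <- expected_frequencies(m, th, 600)
  tf <- ef[ef$plausibility == "plausible" & ef$item_type == "true", ]
  expect_equal(tf$count[tf$response == "true"], 225)
  expect_equal(tf$count[tf$response == "false"], 75)
  expect_equal(tf$count[tf$response == "?"], 150)
  expect_equal(tf$count[tf$response == "new"], 150)
  # per-tree totals preserved
  expect_equal(as.numeric(tapply(ef$count, paste(ef$plausibility, ef$item_type),
                                 sum)),
               rep(600, 8))
})

test_that("log-likelihood kernel matches hand arithmetic and conventions", {
  toy <- toy_2par()
  # P(true) = uv = .12, P(false) = u(1-v) = .28, P(new) = .6
  th <- c(u = 0.4, v = 0.3)
  n <- c(3, 2, 5)
  expect_equal(log_likelihood(toy, th, n),
               3 * log(0.12) + 2 * log(0.28) + 5 * log(0.6))
  # doubling counts doubles the kernel
  expect_equal(log_likelihood(toy, th, 2 * n),
               2 * log_likelihood(toy, th, n))
  # observed 0 with p = 0 contributes 0; observed > 0 with p = 0 gives -Inf
  expect_equal(log_likelihood(toy, c(u = 1, v = 0.3), c(3, 2, 0)),
               3 * log(0.3) + 2 * log(0.7))
  expect_equal(log_likelihood(toy, c(u = 1, v = 1), c(3, 2, 5)), -Inf)
})

test_that("noiseless data are recovered and G^2 vanishes at the optimum", {
  m <- build_feedback_model()
  th <- make_effect_scenario("study-estimates")
  ef <- expected_frequencies(m, th, 1e6)
  f <- fit(m, ef, n_starts = 3, seed = 5, ci_level = NA, tol = 1e-12)
  cm <- feedbackmpt:::compile_model(m)
  truth <- setNames(feedbackmpt:::theta_free_from_named(cm, th), cm$free)
  expect_lt(max(abs(f$estimates - truth[names(f$estimates)])), 0.005)
  expect_lt(f$g_squared, 1e-6)
  expect_true(f$converged)
})

test_that("the optimizer dominates random parameter draws", {
  m <- build_feedback_model()
  sim <- simulate_trials(m, make_effect_scenario("study-estimates"),
                         design_spec(100), seed = 31)
  freq <- aggregate_trials(sim$trials)
  f <- fit(m, freq, n_starts = 5, seed = 31, ci_level = NA)
  cm <- feedbackmpt:::compile_model(m)
  n <- feedbackmpt:::freq_vector(m, cm, freq)
  set.seed(32)
  for (i in 1:1000) {
    ll <- feedbackmpt:::ll_kernel(n, feedbackmpt:::cat_probs_free(cm, runif(22)))
    if (ll > f$log_likelihood + 1e-8) fail("random draw beat the optimizer")
  }
  succeed()
})

test_that("fits are deterministic given the seed", {
  m <- build_feedback_model()
  sim <- simulate_trials(m, make_effect_scenario("null"), design_spec(50),
                         seed = 8)
  freq <- aggregate_trials(sim$trials)
  f1 <- fit(m, freq, n_starts = 4, seed = 99, ci_level = NA)
  f2 <- fit(m, freq, n_starts = 4, seed = 99, ci_level = NA)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$g_squared, f2$g_squared)
})

test_that("G^2 is invariant under tree relabeling", {
  m <- build_feedback_model()
  sim <- simulate_trials(m, make_effect_scenario("study-estimates"),
                         design_spec(80), seed = 13)
  freq <- aggregate_trials(sim$trials)
  f1 <- fit(m, freq, n_starts = 5, seed = 3, ci_level = NA)
  # permute the trees (and the frequency rows with them)
  perm <- c(5:8, 1:4)
  m2 <- mpt_model(m$trees[perm],
                  equality_constraints = m$equality_constraints)
  f2 <- fit(m2, freq, n_starts = 5, seed = 3, ci_level = NA)
  expect_equal(f1$g_squared, f2$g_squared, tolerance = 1e-6)
})

test_that("Wald interval widths scale as 1/sqrt(n)", {
  m <- build_feedback_model()
  sim <- simulate_trials(m, make_effect_scenario("study-estimates"),
                         design_spec(328), seed = 17)
  freq <- aggregate_trials(sim$trials)
  f1 <- fit(m, freq, n_starts = 4, seed = 4)
  freq4 <- freq; freq4$count <- 4 * freq4$count
  f4 <- fit(m, freq4, n_starts = 4, seed = 4)
  wald <- f1$ci$method == "wald" & f4$ci$method == "wald"
  w1 <- (f1$ci$upper - f1$ci$lower)[wald]
  w4 <- (f4$ci$upper - f4$ci$lower)[wald]
  expect_gt(sum(wald), 15)
  expect_equal(w4 / w1, rep(0.5, sum(wald)), tolerance = 0.05)
})

test_that("boundary estimates fall back to flagged profile intervals", {
  toy <- toy_2par()
  # all "true" responses among old: v estimated at the boundary 1
  f <- fit(toy, c(60, 0, 40), n_starts = 5, seed = 2)
  est <- f$ci[f$ci$parameter == "v", ]
  expect_gt(est$estimate, 0.99)
  expect_equal(est$method, "profile")
  expect_equal(est$upper, 1)
  expect_lt(est$lower, 1)
})

test_that("non-conformable frequency tables are rejected", {
  m <- build_feedback_model()
  expect_error(fit(m, rep(10, 31), ci_level = NA), "length 32")
  sim <- simulate_trials(m, make_effect_scenario("null"), design_spec(5),
                         seed = 1)
  freq <- aggregate_trials(sim$trials)
  freq <- freq[-1, ]
  expect_error(fit(m, freq, ci_level = NA), "missing cells")
})
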