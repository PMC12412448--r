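test_that("the default design reproduces the study's trial structure", {
  d <- design_spec()
  expect_equal(d$n_participants, 328L)
  expect_equal(d$items_per_cell, 6L)
  sim_d <- simulate_trials(theta = make_effect_scenario("null"),
                           design = design_spec(4), seed = 71)
  tr <- sim_d$trials
  expect_equal(nrow(tr), 4 * 48)
  counts <- table(tr$participant, tr$plausibility, tr$condition)
  expect_true(all(counts == 6))
  # 36 old + 12 new per participant
  expect_equal(sum(tr$participant == 1 & tr$condition != "new"), 36)
  expect_equal(sum(tr$participant == 1 & tr$condition == "new"), 12)
  # feedback response present iff "old"
  expect_true(all(is.na(tr$feedback_response) == (tr$old_response == "new")))
})

test_that("generation is bit-identical under the same seed", {
  th <- make_effect_scenario("study-estimates")
  s1 <- simulate_trials(theta = th, design = design_spec(20), seed = 72)
  s2 <- simulate_trials(theta = th, design = design_spec(20), seed = 72)
  s3 <- simulate_trials(theta = th, design = design_spec(20), seed = 73)
  expect_identical(s1$trials, s2$trials)
  expect_false(identical(s1$trials, s3$trials))
  expect_identical(aggregate_trials(s1$trials), aggregate_trials(s2$trials))
})

test_that("aggregation preserves counts and the round trip to frequencies", {
  sim_d <- simulate_trials(theta = make_effect_scenario("study-estimates"),
                           design = design_spec(328), seed = 74)
  freq <- aggregate_trials(sim_d$trials)
  expect_equal(sum(freq$count), 15744)
  expect_equal(nrow(freq), 32)
  cell_tot <- tapply(freq$count, paste(freq$plausibility, freq$item_type),
                     sum)
  expect_true(all(cell_tot == 328 * 6))
  # every trial is counted exactly once in its cell
  key <- paste(sim_d$trials$plausibility, sim_d$trials$condition)
  expect_equal(sort(unname(table(key))), sort(unname(cell_tot)))
})

test_that("aggregated proportions converge to the tree probabilities", {
  m <- build_feedback_model()
  th <- make_effect_scenario("study-estimates")
  sim_d <- simulate_trials(m, th, design_spec(20000), seed = 75)
  freq <- aggregate_trials(sim_d$trials)
  cp <- category_probabilities(m, th)
  key_f <- paste(freq$plausibility, freq$item_type, freq$response)
  key_p <- paste(cp$plausibility, cp$item_type, cp$response)
  prop <- freq$count[match(key_p, key_f)] / (20000 * 6)
  expect_lt(max(abs(prop - cp$prob)), 0.005)
})

test_that("certainty parameters yield deterministic responses", {
  th <- make_effect_scenario("null")
  th[grep("^D_", names(th))] <- 1
  th[grep("^d_", names(th))] <- 1
  sim_d <- simulate_trials(theta = th, design = design_spec(5), seed = 76)
  tr <- sim_d$trials
  old <- tr$condition != "new"
  expect_true(all(tr$old_response[old] == "old"))
  expect_true(all(tr$feedback_response[old] == tr$condition[old]))
  expect_true(all(tr$old_response[!old] == "new"))
})

test_that("scenario vectors encode the intended effect structure", {
  pe <- make_effect_scenario("study-estimates")
  expect_equal(unname(pe[c("g_true_P", "g_true_I")]), c(0.65, 0.36))
  expect_equal(unname(pe[c("a_true_P", "a_true_I")]), c(0.54, 0.29))
  null <- make_effect_scenario("null")
  expect_equal(unname(null["D_P_true"]), unname(null["D_P_false"]))
  expect_equal(unname(null["d_I_true"]), unname(null["d_I_false"]))
  expect_equal(unname(null["g_true_P"]), unname(null["g_true_I"]))
  ev <- make_effect_scenario("expectation-violation-d", delta_d = 0.10)
  expect_equal(unname(ev["d_P_false"] - ev["d_P_true"]), 0.10)
  expect_equal(unname(ev["d_I_true"] - ev["d_I_false"]), 0.10)
  go <- make_effect_scenario("guessing-only")
  D <- go[grep("^D_", names(go))]
  expect_true(all(D == D[1]))
  expect_equal(unname(go["d_P_true"]), unname(go["d_I_false"]))
  expect_equal(unname(go[c("g_true_P", "g_true_I")]), c(0.65, 0.36))
  expect_error(make_effect_scenario("bogus"))
})

test_that("trial CSV round trip preserves the records", {
  sim_d <- simulate_trials(theta = make_effect_scenario("null"),
                           design = design_spec(3), seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(sim_d$trials, path)
  back <- read_trials_csv(path)
  expect_equal(back, sim_d$trials)
})

test_that("responses depend only on the design cell, not the statement", {
  # statements are exchangeable within a cell: each statement id occurs
  # exactly once per participant, and within-cell per-statement "old" rates
  # agree within binomial noise
  sim_d <- simulate_trials(theta = make_effect_scenario("study-estimates"),
                           design = design_spec(2000), seed = 78)
  tr <- sim_d$trials
  expect_true(all(table(tr$participant, tr$statement) == 1))
  cell <- tr$plausibility == "plausible" & tr$condition == "true"
  rate <- tapply(tr$old_response[cell] == "old", tr$statement[cell], mean)
  expect_equal(length(rate), 6)
  se <- sqrt(0.25 / 2000)
  expect_lt(diff(range(rate)), 8 * se)
})
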