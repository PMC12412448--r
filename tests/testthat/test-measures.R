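test_that("CSIM and SIM implement the definition arithmetic", {
  tr <- make_cell_trials(n_old = 5, n_correct = 4)
  expect_equal(csim(tr, 1, "plausible", "true"), 0.8)
  expect_equal(sim(tr, 1, "plausible", "true"), 4 / 6)
  tr2 <- make_cell_trials(n_old = 6, n_correct = 6)
  expect_equal(csim(tr2, 1, "plausible", "true"), 1)
  tr0 <- make_cell_trials(n_old = 0, n_correct = 0)
  expect_true(is.na(csim(tr0, 1, "plausible", "true")))
  expect_equal(sim(tr0, 1, "plausible", "true"), 0)
})

test_that("Pr is hit rate minus false-alarm rate", {
  sim_d <- simulate_trials(theta = make_effect_scenario("study-estimates"),
                           design = design_spec(1), seed = 61)
  tr <- sim_d$trials
  target <- tr$condition != "new"
  manual <- mean(tr$old_response[target] == "old") -
    mean(tr$old_response[!target] == "old")
  expect_equal(pr_index(tr, 1), manual)
  # perfect discrimination
  tr$old_response <- ifelse(target, "old", "new")
  tr$feedback_response <- ifelse(target, tr$condition, NA)
  expect_equal(pr_index(tr, 1), 1)
  # "old" to everything: no discrimination
  tr$old_response <- "old"
  tr$feedback_response <- "true"
  expect_equal(pr_index(tr, 1), 0)
})

test_that("per-cell integer identities hold on simulated data", {
  sim_d <- simulate_trials(theta = make_effect_scenario("study-estimates"),
                           design = design_spec(40), seed = 62)
  tr <- sim_d$trials
  mt <- measure_table(tr)
  for (tag in c("P_true", "P_false", "I_true", "I_false")) {
    pl <- if (substr(tag, 1, 1) == "P") "plausible" else "implausible"
    fb <- sub("^._", "", tag)
    for (id in mt$participant) {
      sub <- tr[tr$participant == id & tr$plausibility == pl &
                  tr$condition == fb, ]
      n_old <- sum(sub$old_response == "old")
      n_cor <- sum(sub$old_response == "old" & sub$feedback_response == fb)
      s <- mt[mt$participant == id, paste0("sim_", tag)]
      cs <- mt[mt$participant == id, paste0("csim_", tag)]
      expect_equal(s * 6, n_cor)
      if (n_old > 0) expect_equal(cs * n_old, n_cor) else expect_true(is.na(cs))
      if (!is.na(cs)) expect_gte(cs, s)
    }
  }
})

test_that("exclusion rules flag the planted violations", {
  sim_d <- simulate_trials(theta = make_effect_scenario("study-estimates"),
                           design = design_spec(10), seed = 63)
  tr <- sim_d$trials
  # participant 1 answers "old" everywhere: Pr = 0, excluded at the boundary
  idx <- tr$participant == 1
  tr$old_response[idx] <- "old"
  tr$feedback_response[idx] <- "true"
  flags <- data.frame(participant = 1:10, serious = TRUE, took_notes = FALSE,
                      language_ok = TRUE)
  flags$serious[2] <- FALSE
  flags$took_notes[3] <- TRUE
  flags$language_ok[4] <- FALSE
  res <- apply_exclusions(tr, flags)
  log <- res$log[order(res$log$participant), ]
  expect_true(all(c("1", "2", "3", "4") %in% log$participant))
  expect_equal(log$reason[log$participant == "1"], "Pr <= 0")
  expect_equal(log$reason[log$participant == "2"], "not serious")
  expect_equal(log$reason[log$participant == "3"], "took notes")
  expect_equal(log$reason[log$participant == "4"], "language")
  expect_false(1 %in% res$retained)
  # a barely positive Pr is retained
  expect_true(all(vapply(res$retained, function(id) pr_index(tr, id) > 0,
                         logical(1))))
})

test_that("each 2x2 ANOVA effect equals the squared paired t on its contrast", {
  set.seed(64)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    mt <- data.frame(participant = seq_len(n))
    for (tag in c("P_true", "P_false", "I_true", "I_false"))
      mt[[paste0("sim_", tag)]] <- runif(n)
    a <- rm_anova_2x2(mt, "sim")
    Y <- as.matrix(mt[, -1])
    tt_int <- t.test((Y[, 1] - Y[, 2]) - (Y[, 3] - Y[, 4]))
    tt_pl <- t.test((Y[, 1] + Y[, 2]) / 2 - (Y[, 3] + Y[, 4]) / 2)
    tab <- a$table
    expect_equal(tab$F[tab$effect == "interaction"],
                 unname(tt_int$statistic)^2, tolerance = 1e-10)
    expect_equal(tab$F[tab$effect == "plausibility"],
                 unname(tt_pl$statistic)^2, tolerance = 1e-10)
    expect_equal(tab$df2, rep(n - 1, 3))
  }
})

test_that("the ANOVA agrees with aov() error strata on one dataset", {
  set.seed(65)
  n <- 24
  mt <- data.frame(participant = seq_len(n))
  for (tag in c("P_true", "P_false", "I_true", "I_false"))
    mt[[paste0("csim_", tag)]] <- runif(n)
  a <- rm_anova_2x2(mt, "csim")
  long <- reshape(mt, direction = "long",
                  varying = list(names(mt)[-1]), v.names = "y",
                  timevar = "cell", times = names(mt)[-1])
  long$plaus <- factor(substr(long$cell, 6, 6))
  long$fb <- factor(sub("^csim_._", "", long$cell))
  long$id <- factor(long$participant)
  fit_aov <- aov(y ~ plaus * fb + Error(id / (plaus * fb)), data = long)
  sm <- summary(fit_aov)
  f_aov <- c(
    plausibility = sm[["Error: id:plaus"]][[1]]["plaus", "F value"],
    feedback = sm[["Error: id:fb"]][[1]]["fb", "F value"],
    interaction = sm[["Error: id:plaus:fb"]][[1]]["plaus:fb", "F value"])
  expect_equal(unname(f_aov),
               a$table$F[match(names(f_aov), a$table$effect)],
               tolerance = 1e-8)
})

test_that("degenerate ANOVA inputs are handled", {
  mt <- data.frame(participant = 1:10)
  for (tag in c("P_true", "P_false", "I_true", "I_false"))
    mt[[paste0("sim_", tag)]] <- 0.5
  a <- rm_anova_2x2(mt, "sim")
  expect_equal(a$table$F, rep(0, 3))
  expect_equal(a$table$p, rep(1, 3))
  # undefined CSIM cells are dropped listwise
  mt$csim_P_true <- c(NA, runif(9))
  mt$csim_P_false <- runif(10); mt$csim_I_true <- runif(10)
  mt$csim_I_false <- runif(10)
  a2 <- rm_anova_2x2(mt, "csim")
  expect_equal(a2$n, 9)
  expect_equal(a2$n_dropped, 1)
})

test_that("pairwise follow-ups match the paired t formula", {
  set.seed(66)
  mt <- data.frame(participant = 1:12)
  for (tag in c("P_true", "P_false", "I_true", "I_false"))
    mt[[paste0("sim_", tag)]] <- runif(12)
  pw <- pairwise_followup(mt, "sim")
  d <- mt$sim_P_true - mt$sim_P_false
  expect_equal(pw$t[pw$plausibility == "plausible"],
               mean(d) / (sd(d) / sqrt(12)))
  expect_equal(pw$df, c(11, 11))
  # identical columns give t = 0, p = 1
  mt$sim_I_false <- mt$sim_I_true
  pw2 <- pairwise_followup(mt, "sim")
  expect_equal(pw2$t[pw2$plausibility == "implausible"], 0)
  expect_equal(pw2$p[pw2$plausibility == "implausible"], 1)
})
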