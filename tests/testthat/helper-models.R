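# Toy models with known structure, used for oracle comparisons.

# one tree, 2 free parameters, 3 categories:
#   u v -> true; u (1-v) -> false; (1-u) -> new
toy_2par <- function() {
  mpt_model(list(mpt_tree("t1", "true", list(
    mpt_branch(c("u", "v"), c(FALSE, FALSE), "true"),
    mpt_branch(c("u", "v"), c(FALSE, TRUE), "false"),
    mpt_branch("u", TRUE, "new")
  ))))
}

# one free parameter: u -> true; (1-u) -> new
toy_1par <- function() {
  mpt_model(list(mpt_tree("t1", "true", list(
    mpt_branch("u", FALSE, "true"),
    mpt_branch("u", TRUE, "new")
  ))))
}

# two trees sharing u, 3 free parameters; given u the likelihood separates
# in v and w, so the exhaustive grid maximum is computable exactly
toy_3par <- function() {
  mpt_model(list(
    mpt_tree("t1", "true", list(
      mpt_branch(c("u", "v"), c(FALSE, FALSE), "true"),
      mpt_branch(c("u", "v"), c(FALSE, TRUE), "false"),
      mpt_branch("u", TRUE, "new")
    )),
    mpt_tree("t2", "?", list(
      mpt_branch(c("u", "w"), c(FALSE, FALSE), "true"),
      mpt_branch(c("u", "w"), c(FALSE, TRUE), "?"),
      mpt_branch("u", TRUE, "new")
    ))
  ))
}

# a genuinely locally non-identifiable model: the two parameters enter all
# category probabilities only through their product
toy_deficient <- function() {
  mpt_model(list(mpt_tree("t1", "true", list(
    mpt_branch(c("u", "v"), c(FALSE, FALSE), "true"),
    mpt_branch(c("u", "v"), c(FALSE, TRUE), "new"),
    mpt_branch("u", TRUE, "new")
  ))))
}

# random named free-parameter vector for a model
random_theta <- function(model, lo = 0.1, hi = 0.9) {
  free <- feedbackmpt:::resolve_parameters(model)$free
  stats::setNames(stats::runif(length(free), lo, hi), free)
}

# small hand-built trial set: one participant, one cell, configurable
make_cell_trials <- function(participant = 1, plausibility = "plausible",
                             feedback = "true", n_old, n_correct,
                             n_targets = 6) {
  resp_old <- c(rep("old", n_old), rep("new", n_targets - n_old))
  fb <- rep(NA_character_, n_targets)
  if (n_old > 0) {
    fb[seq_len(n_old)] <- c(rep(feedback, n_correct),
                            rep(if (feedback == "true") "false" else "true",
                                n_old - n_correct))
  }
  data.frame(participant = participant,
             statement = seq_len(n_targets),
             plausibility = plausibility, condition = feedback,
             old_response = resp_old, feedback_response = fb,
             stringsAsFactors = FALSE)
}
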