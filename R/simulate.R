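## Synthetic data emulating the plausibility-by-feedback study design:
## per participant, 6 targets per plausibility x feedback ("true", "false",
## "?") cell plus 6 new statements per plausibility condition = 48 test
## trials; responses are drawn from the processing trees.

#' Design specification for the synthetic study
#'
#' Defaults reproduce the study design: 328 participants, 6 statements per
#' plausibility x condition cell (2 x 4 cells), hence 48 test trials per
#' participant (36 studied, 12 new) and 328 x 48 = 15,744 observations in
#' total.  The 12 new statements are split 6 plausible / 6 implausible, as
#' required by the per-plausibility new-statement trees.
#'
#' @param n_participants number of participants (default 328)
#' @param items_per_cell statements per plausibility x condition cell
#'   (default 6)
#' @return an object of class `mpt_design`
#' @export
design_spec <- function(n_participants = 328, items_per_cell = 6) {
  stopifnot(n_participants >= 1, items_per_cell >= 1)
  structure(list(n_participants = as.integer(n_participants),
                 items_per_cell = as.integer(items_per_cell),
                 plausibility = PLAUSIBILITY_LEVELS,
                 conditions = ITEM_TYPES),
            class = "mpt_design")
}

#' Simulate trial-level responses from an MPT model
#'
#' For every participant and trial, one branch of the processing tree
#' matching the trial's (plausibility, condition) cell is sampled with its
#' branch probability; the branch terminal is emitted as the response
#' ("new" becomes an old/new response of "new", any feedback category an
#' "old" response with that feedback attribution).  Generation is vectorised
#' per design cell under a single seeded RNG stream, so regeneration with the
#' same seed is bit-identical.
#'
#' @param model an [mpt_model()] whose trees cover the design cells (default
#'   the baseline feedback-memory model)
#' @param theta named parameter vector used for generation
#' @param design a [design_spec()]
#' @param seed integer seed
#' @return a list with `trials` (`data.frame`: `participant`, `statement`,
#'   `plausibility`, `condition`, `old_response`, `feedback_response`) and
#'   `ground_truth` (list echoing `theta`, `design`, `seed`)
#' @export
simulate_trials <- function(model = build_feedback_model(), theta, design = design_spec(),
                            seed = 1) {
  cm <- compile_model(model)
  theta_free <- theta_free_from_named(cm, theta)
  th_full <- full_theta(cm, theta_free)
  set.seed(seed)
  n <- design$n_participants
  m <- design$items_per_cell
  tree_index <- stats::setNames(
    seq_along(model$trees),
    paste(vapply(model$trees, `[[`, character(1), "plausibility"),
          vapply(model$trees, `[[`, character(1), "item_type"), sep = "|"))
  pieces <- list()
  stmt_offset <- 0L
  for (plaus in design$plausibility) {
    for (cond in design$conditions) {
      ti <- tree_index[[paste(plaus, cond, sep = "|")]]
      if (is.null(ti) || is.na(ti))
        stop("model has no tree for cell (", plaus, ", ", cond, ")")
      pb <- branch_probs(cm, th_full)[cm$tree_id == ti]
      terminals <- vapply(model$trees[[ti]]$branches, `[[`, character(1),
                          "terminal")
      draws <- sample.int(length(pb), n * m, replace = TRUE, prob = pb)
      resp <- terminals[draws]
      pieces[[length(pieces) + 1L]] <- data.frame(
        participant = rep(seq_len(n), each = m),
        statement = stmt_offset + rep(seq_len(m), n),
        plausibility = plaus,
        condition = cond,
        old_response = ifelse(resp == "new", "new", "old"),
        feedback_response = ifelse(resp == "new", NA_character_, resp),
        stringsAsFactors = FALSE
      )
      stmt_offset <- stmt_offset + m
    }
  }
  trials <- do.call(rbind, pieces)
  trials <- trials[order(trials$participant, trials$statement), ]
  rownames(trials) <- NULL
  list(trials = trials,
       ground_truth = list(theta = theta, design = design, seed = seed))
}

#' Aggregate trials into a frequency table
#'
#' Counts responses per (plausibility, condition, response) cell in the
#' canonical ordering; an "old" response contributes its feedback
#' attribution, a "new" response the category "new".
#'
#' @param trials trial-level data frame
#' @param design a [design_spec()] fixing the cell grid (default the study
#'   design)
#' @return a frequency-table `data.frame` (columns `plausibility`,
#'   `item_type`, `response`, `count`)
#' @export
aggregate_trials <- function(trials, design = design_spec()) {
  check_trials(trials)
  resp <- ifelse(trials$old_response == "new", "new",
                 trials$feedback_response)
  if (!all(resp %in% RESPONSE_CATEGORIES)) stop("malformed response category")
  grid <- expand.grid(response = RESPONSE_CATEGORIES,
                      item_type = design$conditions,
                      plausibility = design$plausibility,
                      stringsAsFactors = FALSE)[, 3:1]
  key <- paste(trials$plausibility, trials$condition, resp, sep = "|")
  tab <- table(factor(key, levels = paste(grid$plausibility, grid$item_type,
                                          grid$response, sep = "|")))
  grid$count <- as.numeric(tab)
  grid
}

## ---- parameter scenarios -------------------------------------------------

## Estimates from the aggregate model fit of the plausibility study
## (statement memory D, feedback memory d, guessing b / a_fb / a_true /
## g_fb / g_true, per plausibility condition).
study_estimates_theta <- function() {
  c(
    D_P_true = .75, D_P_false = .70, D_P_q = .70, D_P_new = .70,
    d_P_true = .73, d_P_false = .76, d_P_q = .23,
    b_P = .43, a_fb_P = .44, a_true_P = .54, g_fb_P = .73, g_true_P = .65,
    D_I_true = .75, D_I_false = .79, D_I_q = .72, D_I_new = .72,
    d_I_true = .77, d_I_false = .62, d_I_q = .43,
    b_I = .37, a_fb_I = .56, a_true_I = .29, g_fb_I = .64, g_true_I = .36
  )
}

#' Named parameter scenarios for simulation studies
#'
#' * `"study-estimates"`: the aggregate-fit estimates of the plausibility
#'   study (statement memory around .70-.79, feedback memory .62-.77, with
#'   plausibility-consistent guessing).
#' * `"null"`: all pairs tested by the battery are equated (statement and
#'   feedback memory equal across "true"/"false" feedback within
#'   plausibility, "true"-guessing equal across plausibility), by averaging
#'   the corresponding `"study-estimates"` values.  Under this scenario every
#'   battery test's null hypothesis holds.
#' * `"expectation-violation-d"`: the `"null"` scenario with a feedback-
#'   memory advantage of `delta_d = .10` planted for expectation-inconsistent
#'   feedback in both plausibility conditions (plausible: d_false = d_true +
#'   .10; implausible: d_true = d_false + .10).
#' * `"guessing-only"`: statement memory and feedback memory flat across all
#'   cells; only the "true"-guessing parameters differ between plausibility
#'   conditions (plausible .65/.54, implausible .36/.29).  Demonstrates that
#'   guessing alone produces the observable plausibility crossover.
#'
#' @param name scenario name
#' @param delta_d planted feedback-memory difference for
#'   `"expectation-violation-d"` (default 0.10)
#' @return named full parameter vector for [build_feedback_model()]
#' @export
make_effect_scenario <- function(name = c("null", "study-estimates",
                                          "expectation-violation-d",
                                          "guessing-only"),
                                 delta_d = 0.10) {
  name <- match.arg(name)
  th <- study_estimates_theta()
  if (name == "study-estimates") return(th)
  equate <- function(th, a, b) {
    v <- mean(th[c(a, b)]); th[a] <- v; th[b] <- v; th
  }
  ## equate all battery-tested pairs
  th <- equate(th, "D_P_true", "D_P_false")
  th <- equate(th, "D_I_true", "D_I_false")
  th <- equate(th, "d_P_true", "d_P_false")
  th <- equate(th, "d_I_true", "d_I_false")
  th <- equate(th, "a_true_P", "a_true_I")
  th <- equate(th, "g_true_P", "g_true_I")
  if (name == "null") return(th)
  if (name == "expectation-violation-d") {
    ## inconsistent feedback remembered better by delta_d in both conditions
    half <- delta_d / 2
    th["d_P_false"] <- th["d_P_false"] + half
    th["d_P_true"] <- th["d_P_true"] - half
    th["d_I_true"] <- th["d_I_true"] + half
    th["d_I_false"] <- th["d_I_false"] - half
    return(th)
  }
  ## guessing-only: memory parameters flat across every cell, all guessing
  ## equal across plausibility except the "true" guesses, which keep the
  ## plausibility-consistent estimates
  pe <- study_estimates_theta()
  D_names <- grep("^D_", names(th), value = TRUE)
  th[D_names] <- mean(pe[D_names])
  dfb <- c("d_P_true", "d_P_false", "d_I_true", "d_I_false")
  th[dfb] <- mean(pe[dfb])
  th[c("d_P_q", "d_I_q")] <- mean(pe[c("d_P_q", "d_I_q")])
  for (pair in list(c("b_P", "b_I"), c("a_fb_P", "a_fb_I"),
                    c("g_fb_P", "g_fb_I")))
    th <- equate(th, pair[1], pair[2])
  th["a_true_P"] <- pe["a_true_P"]; th["a_true_I"] <- pe["a_true_I"]
  th["g_true_P"] <- pe["g_true_P"]; th["g_true_I"] <- pe["g_true_I"]
  th
}

#' Write / read trial-level CSV
#' @param trials trial-level data frame
#' @param path CSV path
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$feedback_response[df$old_response == "new"] <- NA_character_
  check_trials(df)
}
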