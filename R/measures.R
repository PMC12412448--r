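## Trial-level behavioral measures: CSIM, SIM, discrimination index Pr,
## exclusion rules, and the 2 x 2 within-subject ANOVA stage.

check_trials <- function(trials) {
  need <- c("participant", "plausibility", "condition", "old_response")
  if (!all(need %in% names(trials)))
    stop("trials must have columns: ", paste(need, collapse = ", "))
  bad <- trials$old_response == "old" &
    (is.na(trials$feedback_response) | !nzchar(trials$feedback_response))
  if (any(bad)) stop("feedback_response missing for 'old' responses")
  invisible(trials)
}

cell_counts <- function(trials, participant, plausibility, feedback) {
  idx <- trials$participant == participant &
    trials$plausibility == plausibility & trials$condition == feedback
  sub <- trials[idx, , drop = FALSE]
  old <- sub$old_response == "old"
  list(n_targets = nrow(sub),
       n_old = sum(old),
       n_correct = sum(old & sub$feedback_response == feedback))
}

#' Conditional source identification measure (CSIM)
#'
#' Proportion of correct feedback attributions among the target statements of
#' one cell that were correctly identified as old.  Undefined (`NA`) when the
#' participant gave no correct "old" response in the cell.
#'
#' @param trials trial-level data frame (columns `participant`,
#'   `plausibility`, `condition`, `old_response`, `feedback_response`)
#' @param participant participant id
#' @param plausibility `"plausible"` or `"implausible"`
#' @param feedback `"true"` or `"false"`
#' @return CSIM in `[0, 1]`, or `NA` when undefined
#' @export
csim <- function(trials, participant, plausibility, feedback) {
  stopifnot(feedback %in% c("true", "false"))
  cc <- cell_counts(check_trials(trials), participant, plausibility, feedback)
  if (cc$n_old == 0) return(NA_real_)
  cc$n_correct / cc$n_old
}

#' Source identification measure (SIM)
#'
#' Proportion of correct feedback attributions among *all* target statements
#' of one cell; always defined (0 when no target was called old).
#'
#' @inheritParams csim
#' @return SIM in `[0, 1]`
#' @export
sim <- function(trials, participant, plausibility, feedback) {
  stopifnot(feedback %in% c("true", "false"))
  cc <- cell_counts(check_trials(trials), participant, plausibility, feedback)
  if (cc$n_targets == 0) stop("no targets in cell")
  cc$n_correct / cc$n_targets
}

#' Discrimination index Pr
#'
#' Hit rate (proportion of "old" responses to studied statements) minus
#' false-alarm rate (proportion of "old" responses to new statements).
#' `Pr <= 0` indicates no statement memory.
#'
#' @param trials trial-level data frame
#' @param participant participant id
#' @return Pr in `[-1, 1]`
#' @export
pr_index <- function(trials, participant) {
  sub <- trials[trials$participant == participant, , drop = FALSE]
  if (!nrow(sub)) stop("unknown participant: ", participant)
  target <- sub$condition != "new"
  if (!any(target) || all(target))
    stop("participant needs both target and new trials")
  mean(sub$old_response[target] == "old") -
    mean(sub$old_response[!target] == "old")
}

#' Per-participant measure table
#'
#' Computes CSIM and SIM for every participant x plausibility x feedback
#' ("true"/"false") cell, plus the per-participant discrimination index Pr.
#' Trials studied with "?" feedback enter Pr but not CSIM/SIM (the
#' attribution analyses cover "true" and "false" feedback only).
#'
#' @param trials trial-level data frame
#' @return a `data.frame` with one row per participant and columns
#'   `csim_<plaus>_<fb>`, `sim_<plaus>_<fb>` for plaus in P/I and fb in
#'   true/false, plus `pr`
#' @export
measure_table <- function(trials) {
  check_trials(trials)
  ids <- unique(trials$participant)
  fpart <- factor(trials$participant, levels = ids)
  old <- trials$old_response == "old"
  correct <- old & !is.na(trials$feedback_response) &
    trials$feedback_response == trials$condition
  out <- data.frame(participant = ids)
  for (pl in PLAUSIBILITY_LEVELS) {
    for (fb in c("true", "false")) {
      tag <- paste0(substr(toupper(pl), 1, 1), "_", fb)
      in_cell <- trials$plausibility == pl & trials$condition == fb
      n_tgt <- tapply(in_cell, fpart, sum)
      n_old <- tapply(old & in_cell, fpart, sum)
      n_cor <- tapply(correct & in_cell, fpart, sum)
      out[[paste0("csim_", tag)]] <-
        ifelse(n_old > 0, n_cor / n_old, NA_real_)
      out[[paste0("sim_", tag)]] <- n_cor / n_tgt
    }
  }
  is_new <- trials$condition == "new"
  hit_rate <- tapply(old & !is_new, fpart, sum) / tapply(!is_new, fpart, sum)
  fa_rate <- tapply(old & is_new, fpart, sum) / tapply(is_new, fpart, sum)
  out$pr <- as.numeric(hit_rate - fa_rate)
  for (cl in setdiff(names(out), "participant"))
    out[[cl]] <- as.numeric(out[[cl]])
  out
}

#' Apply the study's exclusion criteria
#'
#' Excludes participants who reported non-serious participation, note taking,
#' or insufficient language skills, or whose discrimination index is
#' `Pr <= 0`.  Each exclusion is logged with its (first matching) reason.
#'
#' @param trials trial-level data frame
#' @param flags optional `data.frame` with columns `participant`, `serious`
#'   (logical), `took_notes` (logical), `language_ok` (logical); participants
#'   missing from `flags` are treated as unflagged
#' @return list with `trials` (retained rows), `retained` (ids), and
#'   `log` (`data.frame` of `participant`, `reason`)
#' @export
apply_exclusions <- function(trials, flags = NULL) {
  check_trials(trials)
  ids <- unique(trials$participant)
  reason <- stats::setNames(rep(NA_character_, length(ids)), as.character(ids))
  if (!is.null(flags)) {
    for (i in seq_len(nrow(flags))) {
      id <- as.character(flags$participant[i])
      if (!id %in% names(reason)) next
      if (isFALSE(flags$serious[i])) reason[id] <- "not serious"
      else if (isTRUE(flags$took_notes[i])) reason[id] <- "took notes"
      else if (isFALSE(flags$language_ok[i])) reason[id] <- "language"
    }
  }
  for (id in ids) {
    idc <- as.character(id)
    if (!is.na(reason[idc])) next
    if (pr_index(trials, id) <= 0) reason[idc] <- "Pr <= 0"
  }
  excluded <- names(reason)[!is.na(reason)]
  retained <- ids[!as.character(ids) %in% excluded]
  list(trials = trials[trials$participant %in% retained, , drop = FALSE],
       retained = retained,
       log = data.frame(participant = excluded,
                        reason = unname(reason[excluded]),
                        stringsAsFactors = FALSE))
}

## ---- 2 x 2 within-subject ANOVA ------------------------------------------

#' Two-by-two repeated-measures ANOVA on CSIM or SIM
#'
#' For a 2 (plausibility) x 2 (feedback) fully within-subject design each
#' effect has one numerator degree of freedom, so its F statistic equals the
#' squared paired t statistic on the corresponding contrast of cell means:
#' plausibility main effect = (P_true + P_false)/2 - (I_true + I_false)/2,
#' feedback main effect = (P_true + I_true)/2 - (P_false + I_false)/2,
#' interaction = (P_true - P_false) - (I_true - I_false) (the
#' double-difference).  Sums of squares, F, p and partial eta squared are
#' computed from these difference scores.  Participants with an undefined
#' cell (possible for CSIM) are dropped listwise.
#'
#' @param measures output of [measure_table()]
#' @param measure `"csim"` or `"sim"`
#' @return an object of class `mpt_rm_anova`: list with `n` (complete
#'   participants), `n_dropped`, and per-effect rows `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq` in `$table`
#' @export
rm_anova_2x2 <- function(measures, measure = c("csim", "sim")) {
  measure <- match.arg(measure)
  cols <- paste0(measure, "_", c("P_true", "P_false", "I_true", "I_false"))
  stopifnot(all(cols %in% names(measures)))
  Y <- as.matrix(measures[, cols])
  complete <- stats::complete.cases(Y)
  Y <- Y[complete, , drop = FALSE]
  n <- nrow(Y)
  if (n < 2) stop("need at least 2 participants with complete cells")
  contrasts <- list(
    plausibility = c(0.5, 0.5, -0.5, -0.5),
    feedback = c(0.5, -0.5, 0.5, -0.5),
    interaction = c(1, -1, -1, 1)
  )
  rows <- lapply(names(contrasts), function(nm) {
    d <- drop(Y %*% contrasts[[nm]])
    sd_d <- stats::sd(d)
    tt <- if (sd_d == 0) {
      if (mean(d) == 0) 0 else Inf
    } else mean(d) / (sd_d / sqrt(n))
    Fv <- tt^2
    df2 <- n - 1
    data.frame(effect = nm, F = Fv, df1 = 1, df2 = df2,
               p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
               partial_eta_sq = Fv / (Fv + df2),
               stringsAsFactors = FALSE)
  })
  structure(list(measure = measure, n = n, n_dropped = sum(!complete),
                 cell_means = colMeans(Y),
                 table = do.call(rbind, rows)),
            class = "mpt_rm_anova")
}

#' @export
print.mpt_rm_anova <- function(x, ...) {
  cat(sprintf("2x2 repeated-measures ANOVA on %s (n = %d complete, %d dropped)\n",
              toupper(x$measure), x$n, x$n_dropped))
  tab <- x$table
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  tab$partial_eta_sq <- round(tab$partial_eta_sq, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pairwise follow-up tests within plausibility condition
#'
#' Paired t tests comparing the "true"- and "false"-feedback cells within
#' each plausibility condition (two-sided, df = n - 1).
#'
#' @param measures output of [measure_table()]
#' @param measure `"csim"` or `"sim"`
#' @return `data.frame` with one row per plausibility condition: `t`, `df`,
#'   `p`, `mean_true`, `mean_false`
#' @export
pairwise_followup <- function(measures, measure = c("csim", "sim")) {
  measure <- match.arg(measure)
  out <- lapply(c(P = "P", I = "I"), function(tag) {
    a <- measures[[paste0(measure, "_", tag, "_true")]]
    b <- measures[[paste0(measure, "_", tag, "_false")]]
    keep <- stats::complete.cases(cbind(a, b))
    d <- a[keep] - b[keep]
    if (stats::sd(d) == 0) {
      tval <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      dfv <- length(d) - 1
      pval <- if (tval == 0) 1 else 0
    } else {
      tt <- stats::t.test(a[keep], b[keep], paired = TRUE)
      tval <- unname(tt$statistic); dfv <- unname(tt$parameter)
      pval <- tt$p.value
    }
    data.frame(plausibility = if (tag == "P") "plausible" else "implausible",
               t = tval, df = dfv, p = pval,
               mean_true = mean(a[keep]), mean_false = mean(b[keep]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
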