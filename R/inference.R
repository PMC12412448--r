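## ---- order-constrained shrinkage reparametrisation -----------------------

#' Default shrinkage specification for the feedback-memory model
#'
#' Expectation-consistent cells are plausible statements with "true" feedback
#' and implausible statements with "false" feedback.  The reparametrisation
#' replaces each expectation-consistent feedback-memory parameter by the
#' product of a shrinkage parameter `s` and the expectation-inconsistent
#' parameter of the same plausibility condition:
#' `d_P_true = s_P_d * d_P_false` and `d_I_false = s_I_d * d_I_true`.
#' Since `s` lies in `[0, 1]`, the order `d_inconsistent >= d_consistent` is
#' enforced by construction, and smaller `s` means a larger
#' expectation-violation effect.
#'
#' @return a list of per-condition specifications with elements `consistent`,
#'   `inconsistent`, `s`
#' @export
shrinkage_spec <- function() {
  list(
    list(consistent = "d_P_true", inconsistent = "d_P_false", s = "s_P_d"),
    list(consistent = "d_I_false", inconsistent = "d_I_true", s = "s_I_d")
  )
}

#' Reparametrise a model with parametric order constraints
#'
#' Rewrites the model's branches so that each designated
#' expectation-consistent parameter `d_c` is expressed as `s * d_i` with the
#' expectation-inconsistent parameter `d_i` and a new shrinkage parameter `s`
#' in `[0, 1]`.  A branch factor `d_c` becomes the two factors `s, d_i`; a
#' complement factor `(1 - d_c) = (1 - d_i) + d_i (1 - s)` splits the branch
#' in two.  The number of free parameters is unchanged (`d_c` is swapped for
#' `s`) and the reparametrised model spans exactly the order-constrained
#' subset of the original parameter space.
#'
#' @param model an [mpt_model()]
#' @param spec as returned by [shrinkage_spec()]
#' @return the reparametrised [mpt_model()]
#' @export
reparametrise_shrinkage <- function(model, spec = shrinkage_spec()) {
  for (sp in spec) {
    if (!all(c(sp$consistent, sp$inconsistent) %in% model$parameters))
      stop("shrinkage spec refers to unknown parameter(s): ",
           sp$consistent, ", ", sp$inconsistent)
    if (!grepl("^d_", sp$consistent) || !grepl("^d_", sp$inconsistent))
      stop("shrinkage reparametrisation applies to feedback-memory (d) ",
           "parameters only")
  }
  trees <- lapply(model$trees, function(tr) {
    new_branches <- list()
    for (br in tr$branches) {
      expanded <- list(br)
      for (sp in spec) {
        expanded <- unlist(lapply(expanded, substitute_shrinkage, sp = sp),
                           recursive = FALSE)
      }
      new_branches <- c(new_branches, expanded)
    }
    mpt_tree(tr$plausibility, tr$item_type, new_branches)
  })
  mpt_model(trees, equality_constraints = model$equality_constraints,
            fixed_values = model$fixed_values)
}

substitute_shrinkage <- function(br, sp) {
  hit <- which(br$params == sp$consistent)
  if (!length(hit)) return(list(br))
  out <- list(br)
  for (k in hit) {
    out <- unlist(lapply(out, function(b) {
      k2 <- which(b$params == sp$consistent)[1]
      pre_p <- b$params[seq_len(k2 - 1)]; pre_c <- b$comp[seq_len(k2 - 1)]
      post_p <- b$params[-seq_len(k2)];   post_c <- b$comp[-seq_len(k2)]
      if (!b$comp[k2]) {
        ## d_c -> s * d_i
        list(mpt_branch(c(pre_p, sp$s, sp$inconsistent, post_p),
                        c(pre_c, FALSE, FALSE, post_c), b$terminal))
      } else {
        ## (1 - d_c) -> (1 - d_i) + d_i (1 - s)
        list(
          mpt_branch(c(pre_p, sp$inconsistent, post_p),
                     c(pre_c, TRUE, post_c), b$terminal),
          mpt_branch(c(pre_p, sp$inconsistent, sp$s, post_p),
                     c(pre_c, FALSE, TRUE, post_c), b$terminal)
        )
      }
    }), recursive = FALSE)
  }
  out
}

## ---- nested-model comparison ---------------------------------------------

#' Likelihood-ratio test of nested parameter constraints
#'
#' Fits the model with and without the constraints and compares twice the
#' log-likelihood difference (equivalently the difference in `G^2`) to a
#' chi-square distribution with degrees of freedom equal to the number of
#' independent constraints imposed.  Both fits share the seed and number of
#' starts; the restricted fit additionally warm-starts from the projection of
#' the unrestricted MLE onto the constraint set, which protects against
#' spurious negative differences.  A negative difference within `1e-6` is
#' clamped to zero; a larger negative difference triggers a refit of the
#' restricted model with doubled starts and a warning.
#'
#' @param model the (unrestricted) [mpt_model()]
#' @param freq frequency table
#' @param equalities,fixings constraints passed to [apply_constraints()]
#' @param label test label carried through to the report
#' @param n_starts,seed fitting settings shared by both fits
#' @param base_fit optional pre-computed fit of `model` (reused across a
#'   battery)
#' @return an object of class `mpt_nested_test` with `delta_g_squared`,
#'   `delta_df`, `p_value`, `base_fit`, `restricted_fit`
#' @export
nested_test <- function(model, freq, equalities = list(),
                        fixings = numeric(0), label = "",
                        n_starts = 20, seed = 1, base_fit = NULL) {
  if (is.null(base_fit))
    base_fit <- fit(model, freq, n_starts = n_starts, seed = seed,
                    ci_level = NA)
  restricted <- apply_constraints(model, equalities, fixings)
  warm <- project_onto_constraints(model, restricted, base_fit$estimates)
  r_fit <- fit(restricted, freq, n_starts = n_starts, seed = seed,
               start = warm, ci_level = NA)
  delta_df <- n_free_parameters(model) - n_free_parameters(restricted)
  dg2 <- r_fit$g_squared - base_fit$g_squared
  if (dg2 < 0) {
    if (dg2 > -1e-6) {
      dg2 <- 0
    } else {
      warning("negative delta G^2 (", signif(dg2, 3),
              "); refitting restricted model with doubled starts")
      r_fit <- fit(restricted, freq, n_starts = 2 * n_starts, seed = seed,
                   start = warm, ci_level = NA)
      dg2 <- max(r_fit$g_squared - base_fit$g_squared, 0)
    }
  }
  structure(list(
    label = label,
    equalities = equalities, fixings = fixings,
    delta_g_squared = dg2, delta_df = delta_df,
    p_value = if (delta_df > 0)
      stats::pchisq(dg2, delta_df, lower.tail = FALSE) else NA_real_,
    base_fit = base_fit, restricted_fit = r_fit,
    converged = base_fit$converged && r_fit$converged
  ), class = "mpt_nested_test")
}

## Map the unrestricted MLE onto the restricted model's free parameters:
## equality classes take the mean of their members, new parameters (e.g. a
## shrinkage s) start at 0.5.
project_onto_constraints <- function(model, restricted, estimates) {
  cm_base <- compile_model(model)
  cm_r <- compile_model(restricted)
  full <- stats::setNames(rep(NA_real_, length(model$parameters)),
                          model$parameters)
  for (nm in model$parameters) {
    r <- cm_base$representative[[nm]]
    full[nm] <- if (r %in% names(estimates)) estimates[[r]]
                else cm_base$theta_fixed[match(r, cm_base$par_names)]
  }
  vapply(cm_r$free, function(r) {
    members <- names(cm_r$representative)[cm_r$representative == r]
    vals <- full[members[members %in% names(full)]]
    vals <- vals[!is.na(vals)]
    if (length(vals)) min(max(mean(vals), 1e-3), 1 - 1e-3) else 0.5
  }, numeric(1))
}

#' @export
print.mpt_nested_test <- function(x, ...) {
  cat(sprintf("Nested test %s: delta G^2(%d) = %.3f, p = %s\n",
              x$label, x$delta_df, x$delta_g_squared,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

## ---- the test battery ----------------------------------------------------

#' Parameter constraints of the standard test battery
#'
#' Test 1 equates statement memory for "true" and "false" feedback within
#' plausibility; Test 2a does the same for feedback memory; Test 2b equates
#' the two shrinkage parameters of the order-constrained model; Test 3
#' equates the "true"-guessing parameters across plausibility conditions.
#'
#' @return named list of equality-constraint lists
#' @export
battery_constraints <- function() {
  list(
    "1"  = list(c("D_P_true", "D_P_false"), c("D_I_true", "D_I_false")),
    "2a" = list(c("d_P_true", "d_P_false"), c("d_I_true", "d_I_false")),
    "2b" = list(c("s_P_d", "s_I_d")),
    "3"  = list(c("a_true_P", "a_true_I"), c("g_true_P", "g_true_I"))
  )
}

#' Run the full nested-test battery on a frequency table
#'
#' Fits the baseline feedback-memory model, reports its goodness of fit
#' (evaluated at `alpha_fit`, default 0.001, chosen because the aggregated
#' test is extremely sensitive at conventional levels), then runs Tests 1, 2a
#' and 3 against the baseline model and Test 2b against the shrinkage
#' reparametrisation, each as a likelihood-ratio test at `alpha`.
#'
#' @param freq frequency table from the full 2 x 4 design
#' @param n_starts,seed fitting settings
#' @param alpha significance level for the parameter tests (default 0.05)
#' @param alpha_fit significance level for the baseline fit test (default
#'   0.001)
#' @return an object of class `mpt_battery`: list with `baseline_fit`,
#'   `shrinkage_fit`, `tests` (named list of `mpt_nested_test`), and a
#'   `summary` data frame
#' @export
run_test_battery <- function(freq, n_starts = 20, seed = 1, alpha = 0.05,
                             alpha_fit = 0.001) {
  model <- build_feedback_model()
  cons <- battery_constraints()
  base_fit <- fit(model, freq, n_starts = n_starts, seed = seed,
                  ci_level = NA)
  tests <- list()
  for (lab in c("1", "2a", "3")) {
    tests[[lab]] <- nested_test(model, freq, equalities = cons[[lab]],
                                label = lab, n_starts = n_starts, seed = seed,
                                base_fit = base_fit)
  }
  smodel <- reparametrise_shrinkage(model)
  s_warm <- shrinkage_warm_start(model, smodel, base_fit$estimates)
  s_fit <- fit(smodel, freq, n_starts = n_starts, seed = seed,
               start = s_warm, ci_level = NA)
  tests[["2b"]] <- nested_test(smodel, freq, equalities = cons[["2b"]],
                               label = "2b", n_starts = n_starts, seed = seed,
                               base_fit = s_fit)
  tests <- tests[c("1", "2a", "2b", "3")]
  summary <- data.frame(
    test = names(tests),
    delta_g_squared = vapply(tests, `[[`, numeric(1), "delta_g_squared"),
    delta_df = vapply(tests, `[[`, numeric(1), "delta_df"),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    significant = vapply(tests, function(t) t$p_value < alpha, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(baseline_fit = base_fit, shrinkage_fit = s_fit,
                 tests = tests, summary = summary,
                 alpha = alpha, alpha_fit = alpha_fit,
                 baseline_fit_rejected = base_fit$p_value < alpha_fit),
            class = "mpt_battery")
}

## Warm start for the shrinkage model from baseline estimates: s is the
## ratio of consistent to inconsistent d, clipped into (0, 1).
shrinkage_warm_start <- function(model, smodel, estimates,
                                 spec = shrinkage_spec()) {
  cm_s <- compile_model(smodel)
  vapply(cm_s$free, function(r) {
    if (r %in% names(estimates))
      return(min(max(estimates[[r]], 1e-3), 1 - 1e-3))
    for (sp in spec) {
      if (r == sp$s) {
        ratio <- estimates[[sp$consistent]] / estimates[[sp$inconsistent]]
        if (!is.finite(ratio)) ratio <- 1
        return(min(max(ratio, 1e-3), 1 - 1e-3))
      }
    }
    0.5
  }, numeric(1))
}

#' @export
print.mpt_battery <- function(x, ...) {
  cat(sprintf("Baseline model: G^2(%d) = %.3f, p = %s (fit test at alpha = %g)\n",
              x$baseline_fit$df, x$baseline_fit$g_squared,
              format.pval(x$baseline_fit$p_value, digits = 3), x$alpha_fit))
  print(transform(x$summary,
                  delta_g_squared = round(delta_g_squared, 3),
                  p_value = signif(p_value, 3)))
  invisible(x)
}
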