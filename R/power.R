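## Power analysis: simulation-based power for nested likelihood-ratio tests,
## analytic noncentral-chi-square power for model misfit, and analytic
## sample-size computation for the 2 x 2 within-subject ANOVA interaction.

binom_ci <- function(k, n, level = 0.95) {
  ci <- stats::binom.test(k, n)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Simulation-based power of a nested likelihood-ratio test
#'
#' Repeatedly simulates full datasets under `theta_h1`, aggregates them, and
#' runs the nested test of `equalities`; power is the fraction of replicates
#' with `p < alpha`.  The whole pipeline (trial simulation, aggregation,
#' both model fits) is the package's own analysis path, so the estimate
#' reflects the test as actually performed.
#'
#' @param model the unrestricted [mpt_model()]
#' @param theta_h1 generating parameter vector (violating the constraints by
#'   the planted effect)
#' @param equalities constraint list under test
#' @param n_participants participants per simulated dataset
#' @param n_reps Monte-Carlo replicates (default 1000; >= 100 recommended for
#'   reported estimates)
#' @param alpha test level (default 0.05)
#' @param n_starts random starts per fit (default 5; simulation workloads use
#'   fewer starts than reported fits, protected by the warm start)
#' @param seed integer seed; replicate r uses seed `seed + r`
#' @return an object of class `mpt_power`: `power`, binomial `ci`, `n_reps`,
#'   `n_failed` (non-converged replicates, excluded), settings echo
#' @export
power_delta_g2 <- function(model, theta_h1, equalities, n_participants,
                           n_reps = 1000, alpha = 0.05, n_starts = 5,
                           seed = 1) {
  design <- design_spec(n_participants = n_participants)
  reject <- logical(0); failed <- 0L
  for (r in seq_len(n_reps)) {
    sim <- simulate_trials(model, theta_h1, design, seed = seed + r)
    freq <- aggregate_trials(sim$trials, design)
    nt <- nested_test(model, freq, equalities = equalities,
                      n_starts = n_starts, seed = seed + r)
    if (!nt$converged) { failed <- failed + 1L; next }
    reject <- c(reject, nt$p_value < alpha)
  }
  k <- sum(reject); n_ok <- length(reject)
  structure(list(power = k / n_ok, ci = binom_ci(k, n_ok),
                 n_reps = n_reps, n_failed = failed,
                 n_participants = n_participants, alpha = alpha,
                 seed = seed),
            class = "mpt_power")
}

#' Required sample size for a nested likelihood-ratio test
#'
#' Doubles the sample size from `n_min` until the simulated power reaches
#' `target_power`, then bisects to the smallest qualifying N on the grid
#' (step `n_step`).  Reproducible given `seed` and grid settings.
#'
#' @inheritParams power_delta_g2
#' @param target_power desired power (default 0.90)
#' @param n_min smallest sample size considered (default 8)
#' @param n_max cap; if power at `n_max` is still below target the result is
#'   flagged with `reached = FALSE`
#' @param n_step grid resolution of the bisection (default 4)
#' @return an object of class `mpt_power` with `required_n` and the power
#'   estimates at the visited grid points
#' @export
required_n_delta_g2 <- function(model, theta_h1, equalities,
                                target_power = 0.90, n_reps = 200,
                                alpha = 0.05, n_starts = 5, seed = 1,
                                n_min = 8, n_max = 4096, n_step = 4) {
  pow_at <- function(n) power_delta_g2(model, theta_h1, equalities, n,
                                       n_reps = n_reps, alpha = alpha,
                                       n_starts = n_starts, seed = seed)$power
  visited <- list()
  lo <- n_min
  p_lo <- pow_at(lo); visited[[as.character(lo)]] <- p_lo
  if (p_lo >= target_power)
    return(structure(list(required_n = lo, reached = TRUE,
                          power_at_n = unlist(visited), target_power = target_power,
                          seed = seed), class = "mpt_power"))
  hi <- lo
  repeat {
    hi <- min(hi * 2, n_max)
    p_hi <- pow_at(hi); visited[[as.character(hi)]] <- p_hi
    if (p_hi >= target_power || hi == n_max) break
  }
  if (p_hi < target_power)
    return(structure(list(required_n = NA_integer_, reached = FALSE,
                          power_at_n = unlist(visited), target_power = target_power,
                          seed = seed), class = "mpt_power"))
  lo_n <- hi %/% 2
  while (hi - lo_n > n_step) {
    mid <- ((lo_n + hi) %/% 2 %/% n_step) * n_step
    if (mid <= lo_n) break
    p_mid <- pow_at(mid); visited[[as.character(mid)]] <- p_mid
    if (p_mid >= target_power) hi <- mid else lo_n <- mid
  }
  structure(list(required_n = hi, reached = TRUE,
                 power_at_n = unlist(visited), target_power = target_power,
                 seed = seed), class = "mpt_power")
}

#' Analytic power of the goodness-of-fit test against small misfit
#'
#' Power of the `G^2` model test to detect a deviation of effect size `w`
#' (Cohen's omega for multinomial misfit) with `n_total` observations:
#' `P[chi2_df(ncp = n_total * w^2) > chi2_crit(df, alpha)]`.
#'
#' @param w misfit effect size (>= 0)
#' @param df degrees of freedom of the fit test
#' @param n_total total number of observations entering the test
#' @param alpha significance level
#' @return power in `[alpha, 1]`
#' @export
power_model_misfit <- function(w, df, n_total, alpha = 0.05) {
  stopifnot(w >= 0, n_total > 0, df >= 1)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = n_total * w^2, lower.tail = FALSE)
}

#' Required sample size for the 2 x 2 within-subject ANOVA interaction
#'
#' Analytic noncentral-F computation.  Under the default convention the
#' noncentrality parameter is `lambda = f^2 * N * m / (1 - rho)` with `m`
#' repeated measurements (4 cells for the 2 x 2 design) and repeated-measures
#' correlation `rho`; the interaction has numerator df 1 and denominator df
#' `N - 1`.  Conventions of external power programs differ in whether the
#' `m / (1 - rho)` multiplier is applied; the multiplier is therefore
#' exposed via `convention`.
#'
#' @param f Cohen's f for the interaction (default 0.10)
#' @param rho assumed repeated-measures correlation (default 0.50)
#' @param alpha significance level (default 0.05)
#' @param target_power desired power (default 0.90)
#' @param m number of repeated measurements (default 4)
#' @param convention `"multiplier"` (default, `lambda = f^2 N m / (1 - rho)`)
#'   or `"plain"` (`lambda = f^2 N`)
#' @param n_max search cap
#' @return smallest integer N with power >= `target_power`
#' @export
required_n_rm_anova <- function(f = 0.10, rho = 0.50, alpha = 0.05,
                                target_power = 0.90, m = 4,
                                convention = c("multiplier", "plain"),
                                n_max = 1e6) {
  convention <- match.arg(convention)
  stopifnot(f >= 0, rho > -1, rho < 1)
  power_at <- function(n) {
    lambda <- if (convention == "multiplier") f^2 * n * m / (1 - rho)
              else f^2 * n
    crit <- stats::qf(1 - alpha, 1, n - 1)
    stats::pf(crit, 1, n - 1, ncp = lambda, lower.tail = FALSE)
  }
  n <- 2L
  while (n <= n_max && power_at(n) < target_power) n <- n + 1L
  if (n > n_max) stop("target power unreachable below n_max")
  n
}

#' @export
print.mpt_power <- function(x, ...) {
  if (!is.null(x$required_n)) {
    cat("Required N:", x$required_n,
        if (isFALSE(x$reached)) "(target not reached)" else "", "\n")
  } else {
    cat(sprintf("Estimated power: %.3f [%.3f, %.3f] (%d reps, %d failed)\n",
                x$power, x$ci[1], x$ci[2], x$n_reps, x$n_failed))
  }
  invisible(x)
}
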