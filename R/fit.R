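## ---- frequency tables ----------------------------------------------------

#' Build a frequency table skeleton for a model
#'
#' @param model an [mpt_model()]
#' @param counts numeric vector of cell counts in compiled category order
#'   (trees in model order, responses in canonical order within tree)
#' @return a `data.frame` with columns `plausibility`, `item_type`,
#'   `response`, `count`
#' @export
frequency_table <- function(model, counts) {
  cm <- compile_model(model)
  if (length(counts) != length(cm$cat_tree))
    stop("counts must have length ", length(cm$cat_tree))
  data.frame(
    plausibility = vapply(model$trees[cm$cat_tree], `[[`, character(1),
                          "plausibility"),
    item_type = vapply(model$trees[cm$cat_tree], `[[`, character(1),
                       "item_type"),
    response = cm$cat_resp,
    count = as.numeric(counts),
    stringsAsFactors = FALSE
  )
}

## Align a frequency table (or bare vector) with a compiled model.
freq_vector <- function(model, cm, freq) {
  if (is.numeric(freq)) {
    if (length(freq) != length(cm$cat_tree))
      stop("frequency vector must have length ", length(cm$cat_tree))
    return(as.numeric(freq))
  }
  stopifnot(is.data.frame(freq),
            all(c("plausibility", "item_type", "response", "count") %in%
                  names(freq)))
  key_model <- paste(
    vapply(model$trees[cm$cat_tree], `[[`, character(1), "plausibility"),
    vapply(model$trees[cm$cat_tree], `[[`, character(1), "item_type"),
    cm$cat_resp, sep = "|")
  key_freq <- paste(freq$plausibility, freq$item_type, freq$response,
                    sep = "|")
  idx <- match(key_model, key_freq)
  if (anyNA(idx))
    stop("frequency table is missing cells: ",
         paste(utils::head(key_model[is.na(idx)], 4), collapse = "; "))
  as.numeric(freq$count[idx])
}

#' Read / write a frequency table as CSV
#' @param path CSV file with columns plausibility, item_type, response, count
#' @return a frequency-table `data.frame`
#' @export
read_frequency_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character",
                                       "numeric"))
  stopifnot(all(c("plausibility", "item_type", "response", "count") %in%
                  names(df)))
  df
}

#' @rdname read_frequency_csv
#' @param freq frequency-table `data.frame`
#' @export
write_frequency_csv <- function(freq, path) {
  utils::write.csv(freq, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expected cell frequencies under a parameter vector
#'
#' @param model an [mpt_model()]
#' @param theta named parameter vector (see [category_probabilities()])
#' @param totals per-tree trial totals: a single number (recycled) or a
#'   vector with one entry per tree
#' @return a frequency-table `data.frame` with real-valued `count`
#' @export
expected_frequencies <- function(model, theta, totals) {
  cm <- compile_model(model)
  if (length(totals) == 1L) totals <- rep(totals, cm$n_trees)
  stopifnot(length(totals) == cm$n_trees, all(totals > 0))
  p <- cat_probs_free(cm, theta_free_from_named(cm, theta))
  frequency_table(model, p * totals[cm$cat_tree])
}

#' Multinomial log-likelihood kernel
#'
#' Computes `sum(n * log(p))` over cells, with the convention that cells with
#' zero observed count contribute zero.  Returns `-Inf` when a cell has
#' positive count but zero model probability.
#'
#' @param model an [mpt_model()]
#' @param theta named parameter vector
#' @param freq frequency table (`data.frame` or vector in compiled order)
#' @return log-likelihood kernel (constant terms omitted)
#' @export
log_likelihood <- function(model, theta, freq) {
  cm <- compile_model(model)
  n <- freq_vector(model, cm, freq)
  p <- cat_probs_free(cm, theta_free_from_named(cm, theta))
  ll_kernel(n, p)
}

ll_kernel <- function(n, p) {
  pos <- n > 0
  if (any(p[pos] <= 0)) return(-Inf)
  sum(n[pos] * log(p[pos]))
}

g_squared_stat <- function(n, m) {
  pos <- n > 0
  if (any(m[pos] <= 0)) return(Inf)
  2 * sum(n[pos] * log(n[pos] / m[pos]))
}

## ---- maximum-likelihood fitting -----------------------------------------

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

## negative log-likelihood and gradient on the logit scale
make_objective <- function(cm, n) {
  tree_tot <- as.numeric(tapply(n, cm$cat_tree, sum)[as.character(
    seq_len(cm$n_trees))])
  list(
    fn = function(eta) {
      th <- inv_logit(eta)
      p <- cat_probs_free(cm, th)
      -ll_kernel(n, p)
    },
    gr = function(eta) {
      th <- inv_logit(eta)
      p <- cat_probs_free(cm, th)
      J <- cat_prob_jacobian(cm, th)
      w <- ifelse(n > 0, n / pmax(p, 1e-300), 0)
      g_theta <- -drop(crossprod(J, w))
      g_theta * th * (1 - th)
    }
  )
}

#' Fit an MPT model to aggregated frequencies by maximum likelihood
#'
#' Optimizes the multinomial log-likelihood on logit-transformed parameters
#' with multiple random starts (uniform on (0, 1), seeded) using a
#' quasi-Newton method (PORT routines via [stats::nlminb()]) with analytic
#' gradients, and reports the likelihood-ratio goodness-of-fit
#' statistic `G^2 = 2 * sum(n * log(n / m))` against the saturated model,
#' referred to a chi-square distribution with `df = ` free categories minus
#' free parameters.
#'
#' @param model an [mpt_model()]
#' @param freq frequency table (`data.frame` with columns plausibility,
#'   item_type, response, count, or a numeric vector in compiled order)
#' @param n_starts number of random starts (default 20)
#' @param tol convergence tolerance on the objective (default 1e-9)
#' @param seed integer seed making the random starts reproducible
#' @param start optional numeric matrix (rows = extra start vectors on the
#'   probability scale) prepended to the random starts, e.g. for warm starts
#' @param ci_level confidence level for Wald intervals (default 0.95); set to
#'   `NA` to skip interval computation
#' @return an object of class `mpt_fit` with elements `estimates` (named by
#'   free parameter), `log_likelihood`, `g_squared`, `df`, `p_value`, `ci`,
#'   `n_starts`, `converged`, `seed`
#' @export
fit <- function(model, freq, n_starts = 20, tol = 1e-9, seed = 1,
                start = NULL, ci_level = 0.95) {
  cm <- compile_model(model)
  n <- freq_vector(model, cm, freq)
  k <- length(cm$free)
  obj <- make_objective(cm, n)
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * k, 0.05, 0.95), n_starts, k)
  if (!is.null(start)) {
    start <- rbind(start)
    starts <- rbind(pmin(pmax(start, 1e-4), 1 - 1e-4), starts)
  }
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(logit(starts[s, ]), obj$fn, obj$gr,
                    control = list(iter.max = 500, rel.tol = tol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    res$value <- res$objective
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(estimates = stats::setNames(rep(NA_real_, k),
                                                      cm$free),
                          log_likelihood = NA_real_, g_squared = NA_real_,
                          df = count_df(model), p_value = NA_real_, ci = NULL,
                          n_starts = n_starts, converged = FALSE, seed = seed,
                          model = model),
                     class = "mpt_fit"))
  theta_hat <- inv_logit(best$par)
  p_hat <- cat_probs_free(cm, theta_hat)
  tree_tot <- tapply(n, cm$cat_tree, sum)
  m_hat <- p_hat * as.numeric(tree_tot[as.character(cm$cat_tree)])
  g2 <- g_squared_stat(n, m_hat)
  df <- n_free_categories(model) - n_free_parameters(model)
  out <- structure(list(
    estimates = stats::setNames(theta_hat, cm$free),
    log_likelihood = -best$value,
    g_squared = g2,
    df = df,
    p_value = if (df > 0) stats::pchisq(g2, df, lower.tail = FALSE) else NA_real_,
    ci = NULL,
    n_starts = n_starts,
    converged = any_conv,
    seed = seed,
    expected = m_hat,
    observed = n,
    model = model
  ), class = "mpt_fit")
  if (!is.na(ci_level)) out$ci <- confidence_intervals(out, level = ci_level)
  out
}

#' Wald confidence intervals for a fitted model
#'
#' Intervals are computed on the probability scale from the inverse observed
#' information (finite-difference Hessian of the negative log-likelihood) and
#' clipped to `[0, 1]`.  When the information matrix is singular or an
#' estimate lies within 0.01 of a boundary, a profile-likelihood interval is
#' substituted for the affected parameter and flagged.
#'
#' @param fit an `mpt_fit`
#' @param level confidence level (default 0.95)
#' @return a `data.frame` with columns `parameter`, `estimate`, `lower`,
#'   `upper`, `se`, `method`
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  model <- fit$model
  cm <- compile_model(model)
  n <- fit$observed
  est <- unname(fit$estimates)
  k <- length(est)
  z <- stats::qnorm(1 - (1 - level) / 2)
  nll_theta <- function(th) -ll_kernel(n, cat_probs_free(cm, th))
  H <- tryCatch(pracma::hessian(nll_theta, est), error = function(e) NULL)
  se <- rep(NA_real_, k)
  ok <- FALSE
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dg <- diag(V)
      dg[dg <= 0] <- NA_real_
      se <- sqrt(dg)
      ok <- TRUE
    }
  }
  lower <- pmax(est - z * se, 0)
  upper <- pmin(est + z * se, 1)
  method <- rep(if (ok) "wald" else "profile", k)
  need_profile <- !ok | is.na(se) | est < 0.01 | est > 0.99
  if (any(need_profile)) {
    for (i in which(need_profile)) {
      pl <- profile_ci(cm, n, est, i, level)
      lower[i] <- pl[1]; upper[i] <- pl[2]
      method[i] <- "profile"
    }
  }
  data.frame(parameter = cm$free, estimate = est, lower = lower,
             upper = upper, se = se, method = method,
             stringsAsFactors = FALSE)
}

## Profile-likelihood interval for free parameter i via bisection on the
## likelihood-ratio boundary.
profile_ci <- function(cm, n, est, i, level) {
  k <- length(est)
  ll_max <- ll_kernel(n, cat_probs_free(cm, est))
  crit <- stats::qchisq(level, 1) / 2
  prof <- function(v) {
    if (k == 1L) return(ll_kernel(n, cat_probs_free(cm, v)))
    obj <- function(eta) {
      th <- est; th[-i] <- inv_logit(eta); th[i] <- v
      -ll_kernel(n, cat_probs_free(cm, th))
    }
    start <- logit(pmin(pmax(est[-i], 1e-4), 1 - 1e-4))
    res <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 200))
    -res$value
  }
  root <- function(lo, hi, target_below) {
    ## find v with ll_max - prof(v) = crit, between lo (inside) and hi (outside)
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (ll_max - prof(mid) > crit) hi <- mid else lo <- mid
      if (abs(hi - lo) < 1e-4) break
    }
    (lo + hi) / 2
  }
  lo_bound <- if (ll_max - prof(1e-8) <= crit) 0 else root(est[i], 1e-8)
  hi_bound <- if (ll_max - prof(1 - 1e-8) <= crit) 1 else root(est[i], 1 - 1e-8)
  c(lo_bound, hi_bound)
}

#' @export
print.mpt_fit <- function(x, digits = 3, ...) {
  cat("MPT model fit\n")
  cat(sprintf("  G^2(%d) = %.3f, p = %s; logLik kernel = %.3f; converged: %s\n",
              x$df, x$g_squared,
              format.pval(x$p_value, digits = 3), x$log_likelihood,
              x$converged))
  if (!is.null(x$ci)) {
    print(cbind(round(x$ci[, c("estimate", "lower", "upper")], digits)),
          quote = FALSE)
  } else {
    print(round(x$estimates, digits))
  }
  invisible(x)
}

#' Numerical local-identifiability check
#'
#' Evaluates the analytic Jacobian of all category probabilities with respect
#' to the free parameters at random interior points and reports its column
#' rank.  A rank below the number of free parameters indicates local
#' non-identifiability (some parameter directions leave all category
#' probabilities unchanged).
#'
#' @param model an [mpt_model()]
#' @param n_points number of random interior evaluation points (default 10)
#' @param seed RNG seed
#' @return a list with `n_free`, `max_rank`, `identifiable`, and
#'   `deficient_directions` (null-space basis at the highest-rank point, or
#'   `NULL`)
#' @export
identifiability_check <- function(model, n_points = 10, seed = 1) {
  cm <- compile_model(model)
  k <- length(cm$free)
  set.seed(seed)
  best_rank <- 0L
  best_J <- NULL
  for (i in seq_len(n_points)) {
    th <- stats::runif(k, 0.1, 0.9)
    J <- cat_prob_jacobian(cm, th)
    r <- qr(J)$rank
    if (r > best_rank) { best_rank <- r; best_J <- J }
  }
  deficient <- NULL
  if (best_rank < k && !is.null(best_J)) {
    sv <- svd(best_J)
    deficient <- sv$v[, (best_rank + 1):k, drop = FALSE]
    rownames(deficient) <- cm$free
  }
  list(n_free = k, max_rank = best_rank, identifiable = best_rank == k,
       deficient_directions = deficient)
}
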