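#' @keywords internal
"_PACKAGE"

## Canonical orderings used throughout the package.  A single fixed category
## order prevents silent permutation of cells between model, frequency table
## and simulator.
RESPONSE_CATEGORIES <- c("true", "false", "?", "new")
PLAUSIBILITY_LEVELS <- c("plausible", "implausible")
ITEM_TYPES <- c("true", "false", "?", "new")  # studied feedback; "new" = unstudied

#' Construct an MPT branch
#'
#' A branch is an ordered product of parameters (possibly complemented)
#' terminating in a response category.
#'
#' @param params character vector of parameter names along the branch
#' @param comp logical vector, `TRUE` where the factor enters as `1 - theta`
#' @param terminal response category, one of `"true"`, `"false"`, `"?"`, `"new"`
#' @return an object of class `mpt_branch`
#' @export
mpt_branch <- function(params, comp, terminal) {
  stopifnot(length(params) == length(comp), terminal %in% RESPONSE_CATEGORIES)
  structure(list(params = as.character(params), comp = as.logical(comp),
                 terminal = terminal),
            class = "mpt_branch")
}

#' Construct a processing tree for one statement condition
#'
#' @param plausibility `"plausible"` or `"implausible"` (or any label for toy
#'   models)
#' @param item_type studied feedback condition: `"true"`, `"false"`, `"?"`,
#'   or `"new"` for unstudied statements
#' @param branches list of [mpt_branch()] objects
#' @return an object of class `mpt_tree`
#' @export
mpt_tree <- function(plausibility, item_type, branches) {
  stopifnot(length(branches) >= 1,
            all(vapply(branches, inherits, logical(1), "mpt_branch")))
  structure(list(plausibility = plausibility, item_type = item_type,
                 branches = branches),
            class = "mpt_tree")
}

#' Construct an MPT model from trees
#'
#' @param trees list of [mpt_tree()] objects
#' @param equality_constraints list of length-2 character vectors
#'   `c(kept, dropped)`: the second parameter is set equal to the first
#' @param fixed_values named numeric vector of parameters fixed to constants
#' @return an object of class `mpt_model`
#' @export
mpt_model <- function(trees, equality_constraints = list(),
                      fixed_values = numeric(0)) {
  pars <- unique(unlist(lapply(trees, function(tr)
    unlist(lapply(tr$branches, `[[`, "params")))))
  m <- structure(list(trees = trees,
                      parameters = pars,
                      equality_constraints = equality_constraints,
                      fixed_values = fixed_values),
                 class = "mpt_model")
  validate_constraints(m)
  m
}

validate_constraints <- function(model) {
  for (eq in model$equality_constraints) {
    if (length(eq) != 2L || !all(eq %in% model$parameters))
      stop("equality constraint refers to unknown parameter: ",
           paste(eq, collapse = " = "))
  }
  fx <- model$fixed_values
  if (length(fx)) {
    if (is.null(names(fx)) || !all(names(fx) %in% model$parameters))
      stop("fixed value for unknown parameter")
    if (any(fx < 0 | fx > 1)) stop("fixed values must lie in [0, 1]")
  }
  ## contradictory fixings through equality chains
  cm <- resolve_parameters(model)
  reps <- cm$representative[names(fx)]
  if (length(fx) && anyDuplicated(reps)) {
    sp <- split(fx, reps)
    for (v in sp) if (length(unique(v)) > 1L)
      stop("contradictory constraints: parameter equated to two different constants")
  }
  invisible(model)
}

## Union-find style resolution of equality constraints into a map
## parameter -> representative, plus the set of free parameters.
resolve_parameters <- function(model) {
  pars <- model$parameters
  rep_of <- stats::setNames(pars, pars)
  find <- function(x) {
    while (rep_of[[x]] != x) x <- rep_of[[x]]
    x
  }
  for (eq in model$equality_constraints) {
    a <- find(eq[[1]]); b <- find(eq[[2]])
    if (a != b) rep_of[[b]] <- a
  }
  representative <- vapply(pars, find, character(1))
  fixed <- model$fixed_values
  fixed_reps <- unique(representative[names(fixed)])
  free <- setdiff(unique(representative), fixed_reps)
  ## value of each representative that is fixed (first fixing wins; validated
  ## for consistency in validate_constraints)
  fixed_value <- stats::setNames(rep(NA_real_, length(fixed_reps)), fixed_reps)
  for (nm in names(fixed)) {
    r <- representative[[nm]]
    if (is.na(fixed_value[[r]])) fixed_value[[r]] <- fixed[[nm]]
  }
  list(representative = representative, free = free, fixed_value = fixed_value)
}

#' Number of free parameters of a model
#' @param model an [mpt_model()]
#' @return integer count after collapsing equality constraints and removing
#'   fixed parameters
#' @export
n_free_parameters <- function(model) length(resolve_parameters(model)$free)

#' Number of free response categories
#'
#' Each tree contributes the number of distinct response categories it emits
#' minus one (its probabilities sum to one).
#' @param model an [mpt_model()]
#' @return integer
#' @export
n_free_categories <- function(model) {
  sum(vapply(model$trees, function(tr) {
    length(unique(vapply(tr$branches, `[[`, character(1), "terminal"))) - 1L
  }, integer(1)))
}

#' Degrees of freedom of the goodness-of-fit test
#'
#' df = free response categories - free parameters.  Negative values indicate
#' a structurally non-identifiable model and are flagged with a warning.
#'
#' @param model an [mpt_model()]
#' @return integer degrees of freedom
#' @export
count_df <- function(model) {
  df <- n_free_categories(model) - n_free_parameters(model)
  if (df < 0)
    warning("negative df: model has more free parameters than free categories")
  df
}

## ---- compilation ---------------------------------------------------------

## Compile a model into incidence matrices for fast likelihood evaluation.
## A[b, j] = 1 if parameter j enters branch b untransformed, C[b, j] = 1 if it
## enters as (1 - theta_j).  Parameters are the *representatives* after
## constraint resolution; fixed representatives are substituted at evaluation.
compile_model <- function(model) {
  res <- resolve_parameters(model)
  all_reps <- unique(res$representative)
  np <- length(all_reps)
  branches <- list(); tree_id <- integer(0); terminal <- character(0)
  for (i in seq_along(model$trees)) {
    tr <- model$trees[[i]]
    for (br in tr$branches) {
      branches[[length(branches) + 1L]] <- br
      tree_id <- c(tree_id, i)
      terminal <- c(terminal, br$terminal)
    }
  }
  nb <- length(branches)
  A <- matrix(0, nb, np, dimnames = list(NULL, all_reps))
  C <- matrix(0, nb, np, dimnames = list(NULL, all_reps))
  for (b in seq_len(nb)) {
    br <- branches[[b]]
    reps <- res$representative[br$params]
    for (k in seq_along(reps)) {
      if (br$comp[k]) C[b, reps[k]] <- C[b, reps[k]] + 1
      else            A[b, reps[k]] <- A[b, reps[k]] + 1
    }
  }
  ## categories: per tree, in canonical response order, only emitted ones
  cat_key <- character(0); cat_tree <- integer(0); cat_resp <- character(0)
  for (i in seq_along(model$trees)) {
    emitted <- unique(vapply(model$trees[[i]]$branches, `[[`, character(1),
                             "terminal"))
    emitted <- RESPONSE_CATEGORIES[RESPONSE_CATEGORIES %in% emitted]
    cat_key <- c(cat_key, paste(i, emitted, sep = ":"))
    cat_tree <- c(cat_tree, rep(i, length(emitted)))
    cat_resp <- c(cat_resp, emitted)
  }
  branch_cat <- match(paste(tree_id, terminal, sep = ":"), cat_key)
  nc <- length(cat_key)
  Tmat <- matrix(0, nc, nb)
  Tmat[cbind(branch_cat, seq_len(nb))] <- 1
  free_idx <- match(res$free, all_reps)
  fixed_idx <- match(names(res$fixed_value), all_reps)
  theta_fixed <- rep(NA_real_, np)
  theta_fixed[fixed_idx] <- res$fixed_value
  list(A = A, C = C, Tmat = Tmat,
       tree_id = tree_id, branch_cat = branch_cat,
       cat_tree = cat_tree, cat_resp = cat_resp,
       par_names = all_reps, free = res$free, free_idx = free_idx,
       theta_fixed = theta_fixed, representative = res$representative,
       n_trees = length(model$trees))
}

## Assemble the full representative-parameter vector from a free vector.
full_theta <- function(cm, theta_free) {
  th <- cm$theta_fixed
  th[cm$free_idx] <- theta_free
  th
}

## Branch probabilities for a full representative theta.
branch_probs <- function(cm, th) {
  eps <- 1e-300
  lb <- cm$A %*% log(pmax(th, eps)) + cm$C %*% log(pmax(1 - th, eps))
  pb <- exp(lb)
  ## exact zeros where a factor is exactly 0
  zero <- (cm$A %*% (th == 0) + cm$C %*% (th == 1)) > 0
  pb[zero] <- 0
  drop(pb)
}

## Category probabilities (vector over compiled categories) for free theta.
cat_probs_free <- function(cm, theta_free) {
  drop(cm$Tmat %*% branch_probs(cm, full_theta(cm, theta_free)))
}

## Analytic Jacobian of category probabilities w.r.t. free theta.
cat_prob_jacobian <- function(cm, theta_free) {
  th <- full_theta(cm, theta_free)
  pb <- branch_probs(cm, th)
  fi <- cm$free_idx
  ## d branch_b / d theta_j = pb_b * (A_bj / theta_j - C_bj / (1 - theta_j));
  ## vectorised over branches and parameters
  M <- sweep(cm$A[, fi, drop = FALSE], 2, th[fi], "/") -
    sweep(cm$C[, fi, drop = FALSE], 2, 1 - th[fi], "/")
  W <- pb * M
  bad <- which(!is.finite(W), arr.ind = TRUE)
  if (nrow(bad)) {
    for (r in seq_len(nrow(bad)))
      W[bad[r, 1], bad[r, 2]] <-
        branch_deriv_direct(cm, th, bad[r, 1], fi[bad[r, 2]])
  }
  cm$Tmat %*% W
}

branch_deriv_direct <- function(cm, th, b, j) {
  ## derivative of branch b w.r.t. theta_j by explicit product over the
  ## remaining factors (used only at boundary values)
  a <- cm$A[b, ]; cc <- cm$C[b, ]
  sign <- a[j] - cc[j]
  a[j] <- max(a[j] - 1, 0); cc[j] <- max(cc[j] - 1, 0)
  sign * prod(th^a) * prod((1 - th)^cc)
}

#' Category probabilities of an MPT model
#'
#' Evaluates, for each processing tree, the probability of each emitted
#' response category at a given parameter vector.
#'
#' @param model an [mpt_model()]
#' @param theta named numeric vector in `[0, 1]`.  Names must cover the free
#'   parameters (after constraint resolution); values for constrained-away or
#'   fixed parameters are ignored.
#' @return a data frame with columns `tree`, `plausibility`, `item_type`,
#'   `response`, `prob`; within each tree the probabilities sum to 1
#' @export
category_probabilities <- function(model, theta) {
  cm <- compile_model(model)
  theta_free <- theta_free_from_named(cm, theta)
  p <- cat_probs_free(cm, theta_free)
  data.frame(
    tree = cm$cat_tree,
    plausibility = vapply(model$trees[cm$cat_tree], `[[`, character(1),
                          "plausibility"),
    item_type = vapply(model$trees[cm$cat_tree], `[[`, character(1),
                       "item_type"),
    response = cm$cat_resp,
    prob = p,
    stringsAsFactors = FALSE
  )
}

theta_free_from_named <- function(cm, theta) {
  if (is.null(names(theta))) {
    if (length(theta) != length(cm$free))
      stop("unnamed theta must have length ", length(cm$free))
    th <- as.numeric(theta)
  } else {
    unknown <- setdiff(names(theta), names(cm$representative))
    if (length(unknown))
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    miss <- setdiff(cm$free, names(theta))
    ## a free representative may be supplied under any member of its class
    vals <- stats::setNames(rep(NA_real_, length(cm$free)), cm$free)
    for (nm in names(theta)) {
      r <- cm$representative[[nm]]
      if (r %in% cm$free && is.na(vals[[r]])) vals[[r]] <- theta[[nm]]
    }
    if (anyNA(vals))
      stop("missing value(s) for free parameter(s): ",
           paste(names(vals)[is.na(vals)], collapse = ", "))
    th <- unname(vals)
  }
  if (any(th < 0 | th > 1)) stop("parameter values must lie in [0, 1]")
  th
}

## ---- the feedback-memory model ------------------------------------------

guess_branches <- function(D_par, b, g_fb, g_true) {
  ## the "unrecognised" half shared by all trees: guess old, then feedback
  list(
    mpt_branch(c(D_par, b, g_fb, g_true), c(TRUE, FALSE, FALSE, FALSE), "true"),
    mpt_branch(c(D_par, b, g_fb, g_true), c(TRUE, FALSE, FALSE, TRUE),  "false"),
    mpt_branch(c(D_par, b, g_fb),         c(TRUE, FALSE, TRUE),         "?"),
    mpt_branch(c(D_par, b),               c(TRUE, TRUE),                "new")
  )
}

target_tree <- function(plaus, fb, suffix) {
  D <- paste0("D_", suffix, "_", fb_code(fb))
  d <- paste0("d_", suffix, "_", fb_code(fb))
  a_fb <- paste0("a_fb_", suffix); a_true <- paste0("a_true_", suffix)
  b <- paste0("b_", suffix)
  g_fb <- paste0("g_fb_", suffix); g_true <- paste0("g_true_", suffix)
  branches <- c(
    list(
      ## recognised, feedback remembered -> the studied feedback
      mpt_branch(c(D, d), c(FALSE, FALSE), fb),
      ## recognised, feedback not remembered -> guess among feedbacks
      mpt_branch(c(D, d, a_fb, a_true), c(FALSE, TRUE, FALSE, FALSE), "true"),
      mpt_branch(c(D, d, a_fb, a_true), c(FALSE, TRUE, FALSE, TRUE),  "false"),
      mpt_branch(c(D, d, a_fb),         c(FALSE, TRUE, TRUE),         "?")
    ),
    guess_branches(D, b, g_fb, g_true)
  )
  mpt_tree(plaus, fb, branches)
}

new_tree <- function(plaus, suffix) {
  D <- paste0("D_", suffix, "_new")
  b <- paste0("b_", suffix)
  g_fb <- paste0("g_fb_", suffix); g_true <- paste0("g_true_", suffix)
  branches <- c(
    list(mpt_branch(D, FALSE, "new")),
    guess_branches(D, b, g_fb, g_true)
  )
  mpt_tree(plaus, "new", branches)
}

fb_code <- function(fb) if (fb == "?") "q" else fb

#' Build the three-source two-high-threshold feedback-memory model
#'
#' Constructs the eight-tree MPT model for the plausibility-by-feedback
#' design: 2 plausibility conditions (plausible, implausible) x 4 statement
#' types (studied with "true", "false" or "?" feedback, or new).  Parameters
#' are suffixed `_P` / `_I` for the plausibility condition and by feedback
#' condition (e.g. `D_P_true`, `d_I_false`, `D_I_q`).  Statement memory `D`,
#' feedback memory `d`, and the guessing processes `b` (guess "old"),
#' `a_fb`/`a_true` (feedback guesses after recognition) and `g_fb`/`g_true`
#' (feedback guesses after an "old" guess) follow the two-high-threshold
#' source-monitoring structure.
#'
#' For identifiability the baseline model equates the detection parameters
#' for new statements and statements studied without veracity feedback
#' (`D_P_q = D_P_new`, `D_I_q = D_I_new`).  The constraint is represented
#' explicitly so it can be removed or tested.
#'
#' @param baseline_constraints logical; apply the `D_q = D_new`
#'   identifiability constraints (default `TRUE`)
#' @return an [mpt_model()] with 8 trees, 24 free response categories and
#'   (with the baseline constraints) 22 free parameters
#' @export
build_feedback_model <- function(baseline_constraints = TRUE) {
  trees <- list()
  for (i in seq_along(PLAUSIBILITY_LEVELS)) {
    plaus <- PLAUSIBILITY_LEVELS[i]
    sfx <- c("P", "I")[i]
    trees <- c(trees,
               list(target_tree(plaus, "true", sfx),
                    target_tree(plaus, "false", sfx),
                    target_tree(plaus, "?", sfx),
                    new_tree(plaus, sfx)))
  }
  constraints <- if (baseline_constraints)
    list(c("D_P_q", "D_P_new"), c("D_I_q", "D_I_new")) else list()
  mpt_model(trees, equality_constraints = constraints)
}

#' Impose additional constraints on a model
#'
#' Returns a restricted copy of the model; the original is unmodified.
#'
#' @param model an [mpt_model()]
#' @param equalities list of length-2 character vectors `c(a, b)` imposing
#'   `a = b`
#' @param fixings named numeric vector fixing parameters to constants
#' @return the restricted [mpt_model()]
#' @export
apply_constraints <- function(model, equalities = list(), fixings = numeric(0)) {
  if (length(equalities) && is.character(equalities))
    equalities <- list(equalities)
  m <- model
  m$equality_constraints <- c(m$equality_constraints, equalities)
  m$fixed_values <- c(m$fixed_values, fixings)
  validate_constraints(m)
  m
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("MPT model:", length(x$trees), "trees,",
      n_free_categories(x), "free categories,",
      n_free_parameters(x), "free parameters (df =",
      n_free_categories(x) - n_free_parameters(x), ")\n")
  if (length(x$equality_constraints))
    cat("  equalities:",
        paste(vapply(x$equality_constraints,
                     function(e) paste(e[2], "=", e[1]), character(1)),
              collapse = ", "), "\n")
  if (length(x$fixed_values))
    cat("  fixed:",
        paste(names(x$fixed_values), "=", x$fixed_values, collapse = ", "),
        "\n")
  invisible(x)
}
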