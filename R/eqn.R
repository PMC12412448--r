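#' Write a model to an EQN file
#'
#' The EQN dialect follows the multiTree/MPTinR convention: a first line with
#' the number of branch lines, then one line per branch consisting of a tree
#' index, a global category index, and the branch term as a `*`-separated
#' product of parameter names and complements written `(1-name)`.  Category
#' indices are assigned per tree in the canonical response order
#' ("true", "false", "?", "new"), numbered consecutively across trees.
#'
#' @param model an [mpt_model()].  Equality constraints and fixed values are
#'   not representable in EQN and are dropped with a warning.
#' @param path file to write
#' @return `path`, invisibly
#' @export
write_eqn <- function(model, path) {
  if (length(model$equality_constraints) || length(model$fixed_values))
    warning("EQN cannot express constraints; writing the unconstrained model")
  cm <- compile_model(mpt_model(model$trees))
  lines <- character(0)
  for (i in seq_along(model$trees)) {
    for (br in model$trees[[i]]$branches) {
      cat_id <- match(paste(i, br$terminal, sep = ":"),
                      paste(cm$cat_tree, cm$cat_resp, sep = ":"))
      term <- paste(ifelse(br$comp, paste0("(1-", br$params, ")"), br$params),
                    collapse = "*")
      lines <- c(lines, paste(i, cat_id, term))
    }
  }
  writeLines(c(as.character(length(lines)), lines), path)
  invisible(path)
}

#' Read a model from an EQN file
#'
#' Inverse of [write_eqn()] (up to branch ordering).  Response-category names
#' are recovered from the canonical per-tree numbering; each tree's branch
#' probabilities are validated to sum to one at a random interior parameter
#' vector.
#'
#' @param path EQN file
#' @param validate check tree normalization (default `TRUE`)
#' @return an [mpt_model()]
#' @export
read_eqn <- function(path, validate = TRUE) {
  raw <- trimws(readLines(path))
  raw <- raw[nzchar(raw)]
  if (!length(raw)) stop("empty EQN file")
  n_declared <- suppressWarnings(as.integer(raw[1]))
  body <- if (!is.na(n_declared) && length(raw) == n_declared + 1L)
    raw[-1] else raw
  recs <- lapply(body, parse_eqn_line)
  tree_ids <- vapply(recs, `[[`, numeric(1), "tree")
  cat_ids <- vapply(recs, `[[`, numeric(1), "cat")
  utree <- sort(unique(tree_ids))
  ## reconstruct per-tree category labels from global consecutive numbering
  cat_label <- character(max(cat_ids))
  for (t in utree) {
    cats <- sort(unique(cat_ids[tree_ids == t]))
    if (length(cats) > 4L) stop("tree ", t, " has more than 4 categories")
    cat_label[cats] <- RESPONSE_CATEGORIES[seq_along(cats)]
  }
  trees <- lapply(utree, function(t) {
    idx <- which(tree_ids == t)
    branches <- lapply(idx, function(k) {
      r <- recs[[k]]
      mpt_branch(r$params, r$comp, cat_label[r$cat])
    })
    mpt_tree(plausibility = paste0("tree", t), item_type = paste0("tree", t),
             branches = branches)
  })
  model <- mpt_model(trees)
  if (validate) {
    cm <- compile_model(model)
    th <- 0.3 + 0.4 * seq(0, 1, length.out = length(cm$free))
    p <- cat_probs_free(cm, th)
    sums <- tapply(p, cm$cat_tree, sum)
    if (any(abs(sums - 1) > 1e-8))
      stop("invalid EQN model: tree probabilities do not sum to 1 ",
           "(tree ", names(sums)[which.max(abs(sums - 1))], ")")
  }
  model
}

parse_eqn_line <- function(line) {
  ## "tree category term" with term a product over '*' and/or whitespace
  toks <- strsplit(line, "[ \t]+")[[1]]
  if (length(toks) < 3) stop("malformed EQN line: ", line)
  tree <- suppressWarnings(as.integer(toks[1]))
  cat_id <- suppressWarnings(as.integer(toks[2]))
  if (is.na(tree) || is.na(cat_id) || tree < 1 || cat_id < 1)
    stop("malformed EQN line (bad tree/category index): ", line)
  factors <- unlist(strsplit(paste(toks[-(1:2)], collapse = "*"), "*",
                             fixed = TRUE))
  factors <- factors[nzchar(factors)]
  comp <- grepl("^\\(1-.*\\)$", factors)
  params <- ifelse(comp, sub("^\\(1-(.*)\\)$", "\\1", factors), factors)
  ok <- grepl("^[A-Za-z][A-Za-z0-9_]*$", params)
  if (!all(ok))
    stop("illegal parameter name in EQN line: ", paste(params[!ok], collapse = ", "))
  list(tree = tree, cat = cat_id, params = params, comp = comp)
}
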