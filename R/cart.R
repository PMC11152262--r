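#' Best binary split of a node by squared-error reduction
#'
#' Exhaustively evaluates candidate binary splits on every predictor and
#' returns the one with the largest reduction in the sum of squared errors
#' (SSE). Numeric predictors are split at thresholds halfway between
#' consecutive distinct values (rule \code{x <= t}). Categorical predictors
#' use the classical CART mean-ordering device: levels are ordered by their
#' mean outcome and only the contiguous prefixes of that ordering are
#' evaluated as left subsets, which is exactly optimal for a single
#' squared-error split. Ties are broken by predictor order, then by the
#' smaller threshold / shorter subset, so the result is deterministic.
#'
#' @param X data.frame of predictors (numeric, 0/1 or categorical).
#' @param y numeric outcome vector.
#' @return a list of class \code{"split_candidate"} with the variable, the
#'   rule (threshold or left-category subset), the SSE reduction and the
#'   left/right counts; or \code{NULL} when no split has positive gain
#'   (e.g. constant \code{y}).
#' @export
best_split <- function(X, y) {
  n <- length(y)
  if (n < 2L) return(NULL)
  sse <- function(v) if (length(v) < 2L) 0 else sum((v - mean(v))^2)
  total <- sse(y)
  if (total <= 0) return(NULL)
  best <- NULL
  consider <- function(cand) {
    if (is.null(best) || cand$gain > best$gain + 1e-12) best <<- cand
  }
  for (v in names(X)) {
    x <- X[[v]]
    if (is.numeric(x) || is.logical(x)) {
      ux <- sort(unique(as.numeric(x)))
      if (length(ux) < 2L) next
      for (t in (utils::head(ux, -1) + utils::tail(ux, -1)) / 2) {
        left <- as.numeric(x) <= t
        gain <- total - sse(y[left]) - sse(y[!left])
        consider(list(variable = v, kind = "numeric", threshold = t,
                      gain = gain, n_left = sum(left),
                      n_right = sum(!left)))
      }
    } else {
      x <- as.character(x)
      lev_means <- vapply(split(y, x), mean, 0)
      ord <- names(sort(lev_means))
      if (length(ord) < 2L) next
      for (p in seq_len(length(ord) - 1L)) {
        left_set <- ord[seq_len(p)]
        left <- x %in% left_set
        gain <- total - sse(y[left]) - sse(y[!left])
        consider(list(variable = v, kind = "categorical",
                      left_levels = left_set, gain = gain,
                      n_left = sum(left), n_right = sum(!left)))
      }
    }
  }
  if (is.null(best) || best$gain <= 1e-12) return(NULL)
  class(best) <- "split_candidate"
  best
}

split_goes_left <- function(split, x) {
  if (split$kind == "numeric") as.numeric(x) <= split$threshold
  else as.character(x) %in% split$left_levels
}

#' Grow a pre-pruned CART regression tree
#'
#' Recursive binary splitting on squared error with two pre-pruning rules:
#' a node with fewer than \code{min_node} observations is never split
#' (default 20), and a split is accepted only if its SSE reduction is at
#' least \code{min_gain_frac} of the root SSE (default 1%, mirroring the
#' complexity parameter of classical CART implementations). Each node
#' records its outcome mean, size, and share of the root sample.
#'
#' @param X data.frame of predictors; complete cases required.
#' @param y numeric outcome, same length as \code{nrow(X)}.
#' @param min_node minimum observations a node must have to be considered
#'   for splitting.
#' @param min_gain_frac minimum SSE reduction as a fraction of root SSE.
#' @return nested list of class \code{"tree_node"}; internal nodes carry a
#'   \code{split} and \code{left}/\code{right} children (left = rule true).
#' @export
grow_tree <- function(X, y, min_node = 20, min_gain_frac = 0.01) {
  if (length(y) == 0L) stop("empty input")
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (anyNA(y) || anyNA(X)) stop("complete cases required; drop missing rows first")
  root_sse <- sum((y - mean(y))^2)
  n_root <- length(y)
  grow <- function(idx) {
    yy <- y[idx]
    node <- list(mean = mean(yy), n = length(idx),
                 proportion = length(idx) / n_root)
    class(node) <- "tree_node"
    if (length(idx) < min_node) return(node)
    cand <- best_split(X[idx, , drop = FALSE], yy)
    if (is.null(cand) || cand$gain < min_gain_frac * root_sse) return(node)
    left <- split_goes_left(cand, X[[cand$variable]][idx])
    node$split <- cand
    node$left <- grow(idx[left])
    node$right <- grow(idx[!left])
    node
  }
  grow(seq_along(y))
}

#' Predict from a grown tree
#' @param object a \code{tree_node}.
#' @param newdata data.frame with the predictor columns used at fit time.
#' @param ... unused.
#' @return numeric vector of leaf means.
#' @export
predict.tree_node <- function(object, newdata, ...) {
  one <- function(node, row) {
    while (!is.null(node$split)) {
      node <- if (split_goes_left(node$split,
                                  row[[node$split$variable]]))
        node$left else node$right
    }
    node$mean
  }
  vapply(seq_len(nrow(newdata)), function(i) one(object, newdata[i, ]), 0)
}

rule_text <- function(split, side) {
  if (split$kind == "numeric") {
    sprintf("%s %s %g", split$variable,
            if (side == "left") "<=" else ">", split$threshold)
  } else {
    lv <- split$left_levels
    if (side == "left")
      paste0(paste(split$variable, lv, sep = "_"), collapse = " | ")
    else paste0("not ",
                paste(paste(split$variable, lv, sep = "_"),
                      collapse = " | "))
  }
}

#' Render a tree as an indented outline
#'
#' Each node prints its outcome mean to 2 decimals and its share of the
#' root sample to a whole percent (mean on top, share below in the figures
#' this mirrors); child lines carry the split rule in
#' \code{variable_level} notation.
#'
#' @param tree a \code{tree_node}.
#' @return character vector of lines, invisibly printed by \code{cat}.
#' @export
render_tree <- function(tree) {
  lines <- character(0)
  walk <- function(node, prefix, rule) {
    lab <- sprintf("%.2f / %.0f%%", node$mean, 100 * node$proportion)
    lines <<- c(lines, paste0(prefix, if (nzchar(rule))
      paste0("[", rule, "] ") else "", lab))
    if (!is.null(node$split)) {
      walk(node$left, paste0(prefix, "  "), rule_text(node$split, "left"))
      walk(node$right, paste0(prefix, "  "), rule_text(node$split, "right"))
    }
  }
  walk(tree, "", "")
  lines
}

#' @export
print.tree_node <- function(x, ...) {
  cat(render_tree(x), sep = "\n")
  invisible(x)
}

#' Fit the wellbeing regression tree for one outcome
#'
#' Convenience wrapper: assembles the predictor set used by the regression
#' stage (as categorical/numeric columns), drops incomplete rows, and grows
#' a pre-pruned tree for the chosen wellbeing index.
#'
#' @param coded a \code{coded_table}.
#' @param scores matching \code{wellbeing_scores}.
#' @param outcome one of \code{"quality"}, \code{"satisfaction"},
#'   \code{"psychological"}.
#' @param min_node,min_gain_frac passed to \code{\link{grow_tree}}.
#' @return a \code{tree_node} with attributes \code{n_used} and
#'   \code{n_dropped}.
#' @export
wellbeing_tree <- function(coded, scores,
                           outcome = c("quality", "satisfaction",
                                       "psychological"),
                           min_node = 20, min_gain_frac = 0.01) {
  outcome <- match.arg(outcome)
  y <- scores[[paste0("mwi_", outcome)]]
  vars <- c("learn_elderly", "class_total", "places_total", "disability",
            "mobility", "health_good", "family_good", "friends_good",
            "retired_yes", "female", "married", "education_band",
            "children_band")
  X <- coded[vars]
  keep <- stats::complete.cases(X) & !is.na(y)
  tree <- grow_tree(X[keep, , drop = FALSE], y[keep],
                    min_node = min_node, min_gain_frac = min_gain_frac)
  attr(tree, "n_used") <- sum(keep)
  attr(tree, "n_dropped") <- sum(!keep)
  tree
}
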