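#' One-hot indicator matrix of a coded table
#'
#' Expands the active categorical variables into a cases-by-categories
#' binary matrix with one 1 per variable per respondent. Column names follow
#' the \code{variable_level} convention (e.g. \code{learn_elderly_no},
#' \code{class_total_1}). Rows with a missing value on any active variable
#' are dropped (complete-case analysis); the dropped count is recorded.
#'
#' @param coded a \code{coded_table} (or any data.frame of categoricals).
#' @param active_vars character vector of active variable names; default
#'   \code{\link{default_active_vars}}.
#' @return object of class \code{"indicator_matrix"}: list with the binary
#'   matrix \code{Z}, \code{var_of_column}, active-variable count \code{Q},
#'   category count \code{J}, \code{n_dropped} and the kept row ids.
#' @export
one_hot <- function(coded, active_vars = default_active_vars()) {
  missing_vars <- setdiff(active_vars, names(coded))
  if (length(missing_vars))
    stop("active variable(s) not in table: ",
         paste(missing_vars, collapse = ", "))
  sub <- coded[active_vars]
  keep <- stats::complete.cases(sub)
  sub <- sub[keep, , drop = FALSE]
  blocks <- list(); var_of_column <- character(0)
  for (v in active_vars) {
    x <- sub[[v]]
    if (is.factor(x)) x <- droplevels(x)
    x <- as.character(x)
    lev <- sort(unique(x))
    if (length(lev) < 2L)
      stop("active variable '", v, "' has a single observed level")
    B <- outer(x, lev, "==") + 0
    colnames(B) <- paste(v, lev, sep = "_")
    blocks[[v]] <- B
    var_of_column <- c(var_of_column, rep(v, length(lev)))
  }
  Z <- do.call(cbind, blocks)
  names(var_of_column) <- colnames(Z)
  structure(list(Z = Z, var_of_column = var_of_column,
                 Q = length(active_vars), J = ncol(Z),
                 n_dropped = sum(!keep),
                 row_id = coded$respondent_id[keep]),
            class = "indicator_matrix")
}

#' Default active variable set for the MCA
#'
#' The categorical fields shown on the factor maps: the three wellbeing
#' quartile variables, the demographic recodes, and the lifelong-learning
#' variables.
#' @return character vector.
#' @export
default_active_vars <- function() {
  c("quality_q", "satisfaction_q", "psychological_q",
    "health_good", "family_good", "friends_good", "disability", "mobility",
    "working", "education_band", "children_band", "married", "female",
    "learn_elderly", "class_total_bin", "places_total_bin")
}

#' Multiple correspondence analysis of an indicator matrix
#'
#' Correspondence analysis of the cases-by-categories indicator matrix
#' \code{Z}: with correspondence matrix \code{P = Z/sum(Z)}, row masses
#' \code{r}, column masses \code{c}, the matrix of standardized residuals
#' \eqn{S = D_r^{-1/2}(P - r c^T) D_c^{-1/2}} is decomposed by SVD
#' \eqn{S = U \Sigma V^T}. Principal inertias are the squared singular
#' values; category principal coordinates are
#' \eqn{D_c^{-1/2} V \Sigma} and individual principal coordinates
#' \eqn{D_r^{-1/2} U \Sigma}. Dimensions are ordered by decreasing inertia
#' and each is oriented so the category contributing most to it has a
#' positive coordinate (SVD signs are arbitrary).
#'
#' Explained-inertia proportions are reported on the raw principal inertias
#' (summing to 1 over all dimensions); Benzécri-corrected proportions, which
#' re-express inertia only on dimensions exceeding the average \code{1/Q},
#' are also returned for reference.
#'
#' @param ind an \code{\link{indicator_matrix}}.
#' @param n_dims number of dimensions to retain (default 5).
#' @return object of class \code{"mca_result"}: principal \code{inertias}
#'   (all dimensions), \code{explained} and \code{explained_benzecri}
#'   proportions, \code{total_inertia}, retained \code{category_coords},
#'   \code{individual_coords}, per-dimension category \code{contributions},
#'   masses, and bookkeeping from the indicator matrix.
#' @export
fit_mca <- function(ind, n_dims = 5) {
  Z <- ind$Z
  if (nrow(Z) < 2L) stop("need at least 2 complete rows")
  P <- Z / sum(Z)
  r <- rowSums(P); cc <- colSums(P)
  S <- sweep(sweep(P - outer(r, cc), 1, sqrt(r), "/"), 2, sqrt(cc), "/")
  dec <- svd(S)
  pos <- dec$d > 1e-12
  if (!any(pos)) stop("degenerate indicator matrix: residual has rank 0")
  sv <- dec$d[pos]
  inertias <- sv^2
  n_dims <- min(n_dims, length(sv))
  U <- dec$u[, pos, drop = FALSE][, seq_len(n_dims), drop = FALSE]
  V <- dec$v[, pos, drop = FALSE][, seq_len(n_dims), drop = FALSE]
  svk <- sv[seq_len(n_dims)]
  G <- sweep(V %*% diag(svk, n_dims), 1, sqrt(cc), "/")
  F_ <- sweep(U %*% diag(svk, n_dims), 1, sqrt(r), "/")
  # contribution of category j to dim s: c_j g_js^2 / lambda_s
  contrib <- sweep(sweep(G^2, 1, cc, "*"), 2, svk^2, "/")
  flip <- vapply(seq_len(n_dims), function(s) {
    sign(G[which.max(contrib[, s]), s])
  }, 0)
  flip[flip == 0] <- 1
  G <- sweep(G, 2, flip, "*")
  F_ <- sweep(F_, 2, flip, "*")
  dimnames(G) <- list(colnames(Z), paste0("dim", seq_len(n_dims)))
  dimnames(F_) <- list(ind$row_id, paste0("dim", seq_len(n_dims)))
  dimnames(contrib) <- dimnames(G)
  # Benzécri correction: only dimensions with inertia above average 1/Q
  Q <- ind$Q
  bz <- (Q / (Q - 1))^2 * pmax(inertias - 1 / Q, 0)^2
  explained_bz <- if (sum(bz) > 0) bz / sum(bz) else bz
  structure(list(inertias = inertias,
                 explained = inertias / sum(inertias),
                 explained_benzecri = explained_bz,
                 total_inertia = sum(inertias),
                 singular_values = sv,
                 category_coords = G,
                 individual_coords = F_,
                 contributions = contrib,
                 row_mass = r, col_mass = cc,
                 var_of_column = ind$var_of_column,
                 Q = Q, J = ind$J, n = nrow(Z),
                 n_dropped = ind$n_dropped),
            class = "mca_result")
}

#' Long-format factor coordinates for plotting
#'
#' Returns one row per category and per individual on a chosen pair of
#' dimensions, with a group tag (\code{wellbeing}, \code{learning},
#' \code{demographic}) for categories and, for individuals, the
#' lifelong-learning attitude label used to colour the individual map.
#'
#' @param result an \code{mca_result}.
#' @param dims integer pair of retained dimension indices (default 1:2).
#' @param coded the coded table the MCA was fitted on (used to attach
#'   \code{learn_elderly} labels to individuals); optional.
#' @return data.frame with columns \code{type} (category/individual),
#'   \code{label}, \code{variable}, \code{group}, \code{x}, \code{y}.
#' @export
factor_table <- function(result, dims = c(1, 2), coded = NULL) {
  nd <- ncol(result$category_coords)
  if (any(dims < 1 | dims > nd))
    stop("dimension index out of range; retained 1..", nd)
  grp <- function(v) {
    if (v %in% c("quality_q", "satisfaction_q", "psychological_q"))
      "wellbeing"
    else if (v %in% c("learn_elderly", "class_total_bin",
                      "places_total_bin")) "learning"
    else "demographic"
  }
  cats <- data.frame(
    type = "category",
    label = rownames(result$category_coords),
    variable = unname(result$var_of_column),
    group = vapply(unname(result$var_of_column), grp, ""),
    x = result$category_coords[, dims[1]],
    y = result$category_coords[, dims[2]],
    stringsAsFactors = FALSE, row.names = NULL)
  learn <- rep(NA_character_, nrow(result$individual_coords))
  ids <- rownames(result$individual_coords)
  if (!is.null(coded))
    learn <- coded$learn_elderly[match(ids, coded$respondent_id)]
  inds <- data.frame(
    type = "individual", label = ids, variable = "respondent",
    group = ifelse(is.na(learn), "unknown", paste0("learn_", learn)),
    x = result$individual_coords[, dims[1]],
    y = result$individual_coords[, dims[2]],
    stringsAsFactors = FALSE, row.names = NULL)
  rbind(cats, inds)
}

#' @export
print.mca_result <- function(x, ...) {
  cat(sprintf("<mca_result> %d cases, %d variables, %d categories\n",
              x$n, x$Q, x$J))
  cat(sprintf("  total inertia %.4f = (J - Q)/Q; first dims explain %s\n",
              x$total_inertia,
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 3)),
                    collapse = ", ")))
  invisible(x)
}
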