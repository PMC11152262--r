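#' Build the regression design from a coded table
#'
#' Assembles the numeric predictor matrix used by the wellbeing
#' regressions: \code{learn_elderly} (1 = the elderly should keep
#' learning), the activity counts \code{class_total} and
#' \code{places_total}, the \code{disability}, \code{mobility},
#' \code{health_good}, \code{family_good}, \code{friends_good},
#' \code{retired_yes}, \code{female} and \code{married} dummies,
#' \code{secondary_more} (1 = more than secondary education) and the child
#' count \code{no_children}, plus an intercept. Rows with a missing value
#' in any outcome or predictor are dropped (listwise deletion).
#'
#' @param coded a \code{coded_table}.
#' @param scores matching \code{wellbeing_scores}.
#' @return list with the design matrix \code{X} (intercept first), the
#'   outcome matrix \code{Y} (three columns), the retained
#'   \code{respondent_id}s and \code{n_dropped}.
#' @export
build_design <- function(coded, scores) {
  stopifnot(identical(coded$respondent_id, scores$respondent_id))
  need <- c("learn_elderly", "class_total", "places_total", "disability",
            "mobility", "health_good", "family_good", "friends_good",
            "retired_yes", "female", "married", "education_band",
            "children_band")
  absent <- setdiff(need, names(coded))
  if (length(absent))
    stop("predictor column(s) absent: ", paste(absent, collapse = ", "))
  X <- cbind(
    learn_elderly = as.integer(coded$learn_elderly == "yes"),
    class_total = coded$class_total,
    places_total = coded$places_total,
    disability = coded$disability,
    mobility = coded$mobility,
    health_good = as.integer(coded$health_good == "good"),
    family_good = as.integer(coded$family_good == "good"),
    friends_good = as.integer(coded$friends_good == "good"),
    retired_yes = coded$retired_yes,
    female = coded$female,
    married = coded$married,
    secondary_more = as.integer(coded$education_band ==
                                  "more than secondary"),
    no_children = children_band_to_count(coded))
  Y <- cbind(quality = scores$mwi_quality,
             satisfaction = scores$mwi_satisfaction,
             psychological = scores$mwi_psychological)
  keep <- stats::complete.cases(X) & stats::complete.cases(Y)
  list(X = cbind(`(Intercept)` = 1, X[keep, , drop = FALSE]),
       Y = Y[keep, , drop = FALSE],
       respondent_id = coded$respondent_id[keep],
       n_dropped = sum(!keep))
}

# the raw child count survives recoding when present; fall back to bands
children_band_to_count <- function(coded) {
  if (!is.null(coded$no_children)) return(coded$no_children)
  stop("coded table lacks a usable child count")
}

#' OLS with heteroskedasticity-robust standard errors
#'
#' Ordinary least squares via \code{stats::lm} with sandwich covariance
#' from \pkg{sandwich} (\code{vcovHC}). The default HC1 variant applies the
#' degrees-of-freedom factor \code{n/(n - k)} to the HC0 estimator, the
#' convention of the usual econometrics robust-SE output. Significance
#' stars: *** p<0.01, ** p<0.05, * p<0.1 (two-sided).
#'
#' @param X design matrix including an intercept column.
#' @param y outcome vector.
#' @param variant one of \code{"HC0"}, \code{"HC1"}, \code{"HC2"},
#'   \code{"HC3"}.
#' @param df_method \code{"normal"} for normal-approximation p-values
#'   (default), \code{"t"} for Student-t with \code{n - k} df.
#' @return object of class \code{"regression_result"} with coefficients,
#'   robust SEs, t statistics, p-values, stars, \code{r_squared} and
#'   \code{n}.
#' @export
fit_ols_robust <- function(X, y, variant = c("HC1", "HC0", "HC2", "HC3"),
                           df_method = c("normal", "t")) {
  variant <- match.arg(variant)
  df_method <- match.arg(df_method)
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need more rows than columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  has_icpt <- any(apply(X, 2, function(v) all(v == 1)))
  fit <- stats::lm(y ~ X - 1)
  beta <- stats::setNames(stats::coef(fit), colnames(X))
  V <- sandwich::vcovHC(fit, type = variant)
  se <- stats::setNames(sqrt(diag(V)), colnames(X))
  tstat <- beta / se
  n <- nrow(X); k <- ncol(X)
  p <- if (df_method == "normal") 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = n - k)
  stars <- ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                                          ifelse(p < 0.1, "*", "")))
  tss <- if (has_icpt) sum((y - mean(y))^2) else sum(y^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(coefficients = beta, se = se, t = tstat, p = p,
                 stars = stars, r_squared = r2, n = n,
                 variant = variant, vcov = V),
            class = "regression_result")
}

#' Fit the three wellbeing regressions
#'
#' @param coded a \code{coded_table}.
#' @param scores matching \code{wellbeing_scores}.
#' @param variant robust-variance variant (see
#'   \code{\link{fit_ols_robust}}).
#' @return named list of three \code{regression_result}s (quality,
#'   satisfaction, psychological) plus the design's dropped-row count as
#'   attribute \code{"n_dropped"}.
#' @export
fit_wellbeing_regressions <- function(coded, scores, variant = "HC1") {
  des <- build_design(coded, scores)
  res <- lapply(colnames(des$Y), function(h)
    fit_ols_robust(des$X, des$Y[, h], variant = variant))
  names(res) <- colnames(des$Y)
  attr(res, "n_dropped") <- des$n_dropped
  res
}

#' Render three regressions as a comparison table
#'
#' Predictors as rows, outcomes as columns; each cell shows the
#' coefficient (4 significant-figure style, 4 decimals) with stars, and
#' the robust SE in parentheses on the following line; \code{Observations}
#' and \code{R-squared} rows close the table.
#'
#' @param results named list of three \code{regression_result}s sharing a
#'   predictor set.
#' @return character matrix with one column per outcome, ready for
#'   printing; also of class \code{"comparison_table"}.
#' @export
table3_layout <- function(results) {
  if (length(results) != 3L) stop("expected three fitted models")
  preds <- lapply(results, function(r) names(r$coefficients))
  if (!all(vapply(preds, identical, TRUE, preds[[1]])))
    stop("models do not share the same predictor set")
  pn <- preds[[1]]
  ord <- c(setdiff(pn, "(Intercept)"), "(Intercept)")
  rows <- character(0); rn <- character(0)
  for (p in ord) {
    coefs <- vapply(results, function(r)
      sprintf("%.4f%s", r$coefficients[[p]], r$stars[[p]]), "")
    ses <- vapply(results, function(r) sprintf("(%.4f)", r$se[[p]]), "")
    rows <- rbind(rows, coefs, ses)
    rn <- c(rn, if (p == "(Intercept)") "Constant" else p, "")
  }
  rows <- rbind(rows,
                vapply(results, function(r) sprintf("%d", r$n), ""),
                vapply(results, function(r) sprintf("%.3f", r$r_squared),
                       ""))
  rn <- c(rn, "Observations", "R-squared")
  dimnames(rows) <- list(rn, names(results))
  class(rows) <- c("comparison_table", class(rows))
  rows
}

#' @export
print.comparison_table <- function(x, ...) {
  print(unclass(x), quote = FALSE)
  invisible(x)
}

#' @export
print.regression_result <- function(x, ...) {
  out <- data.frame(coef = sprintf("%.4f", x$coefficients),
                    robust_se = sprintf("%.4f", x$se),
                    p = sprintf("%.3f", x$p), stars = x$stars,
                    row.names = names(x$coefficients))
  print(out)
  cat(sprintf("n = %d, R-squared = %.3f (%s robust SEs)\n",
              x$n, x$r_squared, x$variant))
  invisible(x)
}
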