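#' Normalize a raw survey response to [0, 1]
#'
#' Maps a raw response \code{A} on an item with bounds \code{[m, M]} to the
#' unit interval: \code{(A - m) / (M - m)} when a larger response means
#' better wellbeing, and \code{(M - A) / (M - m)} when a smaller one does.
#' After normalization, 1 is always the best attainable answer and 0 the
#' worst, regardless of how the instrument is keyed.
#'
#' @param A raw response value(s); missing values propagate.
#' @param m,M item lower/upper bounds, \code{M > m}.
#' @param orientation \code{"higher_is_better"} or \code{"lower_is_better"}.
#' @return numeric in \code{[0, 1]}.
#' @export
normalize_response <- function(A, m, M, orientation = "higher_is_better") {
  orientation <- match.arg(orientation,
                           c("higher_is_better", "lower_is_better"))
  if (any(M <= m)) stop("upper bound M must exceed lower bound m")
  ok <- is.na(A) | (A >= m & A <= M)
  if (!all(ok))
    stop("response ", A[which(!ok)[1]], " outside bounds [", m, ", ", M, "]")
  d <- (A - m) / (M - m)
  if (orientation == "lower_is_better") d <- 1 - d
  d
}

#' Multidimensional Wellbeing Index of one normalized response vector
#'
#' Aggregates \code{k} normalized responses \code{d} (each in \code{[0, 1]})
#' into a single score via the two-component normalized-Euclidean-distance
#' form
#' \deqn{MWI(d) = \frac{1}{2}\left[\frac{\|d\|_2}{\sqrt{k}} +
#'   \left(1 - \frac{\|1 - d\|_2}{\sqrt{k}}\right)\right],}
#' i.e. the average of the normalized distance from the worst point (the
#' zero vector) and one minus the normalized distance from the best point
#' (the unit vector). The index is unit free, bounded in \code{[0, 1]} with
#' 0 attained only at the worst corner and 1 only at the best, strictly
#' monotone in each coordinate on the interior, and invariant to affine
#' rescaling of the raw responses. It also satisfies the complement symmetry
#' \code{MWI(d) + MWI(1 - d) = 1}.
#'
#' @param d numeric vector of normalized responses in \code{[0, 1]}.
#' @return a single score in \code{[0, 1]}.
#' @export
compute_mwi <- function(d) {
  if (length(d) == 0L) stop("empty response vector")
  if (anyNA(d)) return(NA_real_)
  if (any(d < 0 | d > 1)) stop("normalized responses must lie in [0, 1]")
  k <- length(d)
  0.5 * (sqrt(sum(d^2)) / sqrt(k) + 1 - sqrt(sum((1 - d)^2)) / sqrt(k))
}

#' Score a survey table on the three wellbeing indices
#'
#' Normalizes every item of every scale and aggregates per respondent with
#' \code{\link{compute_mwi}}. Under the default \code{policy = "strict"} a
#' respondent missing any item of a scale gets a missing score for that
#' scale (the index fixes \code{k} at the instrument's item count);
#' \code{policy = "rescale"} instead aggregates over the observed items with
#' \code{k} equal to their number.
#'
#' @param table a validated \code{survey_table}.
#' @param scales list of \code{\link{scale_definition}} objects.
#' @param policy missing-data policy, \code{"strict"} or \code{"rescale"}.
#' @return data.frame of class \code{"wellbeing_scores"} with columns
#'   \code{respondent_id}, \code{mwi_quality}, \code{mwi_satisfaction},
#'   \code{mwi_psychological}.
#' @export
score_table <- function(table, scales = default_scales(),
                        policy = c("strict", "rescale")) {
  policy <- match.arg(policy)
  out <- data.frame(respondent_id = table$respondent_id,
                    stringsAsFactors = FALSE)
  for (sc in scales) {
    missing_items <- setdiff(sc$items, names(table))
    if (length(missing_items))
      stop("scale '", sc$scale_id, "' references unknown item column(s): ",
           paste(missing_items, collapse = ", "))
    d <- normalize_items(table, sc)
    score <- apply(d, 1, function(row) {
      obs <- !is.na(row)
      if (policy == "strict" && !all(obs)) return(NA_real_)
      if (!any(obs)) return(NA_real_)
      compute_mwi(row[obs])
    })
    out[[paste0("mwi_", sc$scale_id)]] <- score
  }
  class(out) <- c("wellbeing_scores", "data.frame")
  out
}

#' Normalized response matrix for one scale
#'
#' @param table a survey table holding the scale's item columns.
#' @param sc a \code{scale_definition}.
#' @return numeric matrix, respondents by items, entries in \code{[0, 1]}
#'   with missing responses propagated.
#' @export
normalize_items <- function(table, sc) {
  d <- matrix(NA_real_, nrow(table), sc$k,
              dimnames = list(NULL, sc$items))
  for (j in seq_len(sc$k)) {
    d[, j] <- normalize_response(as.numeric(table[[sc$items[j]]]),
                                 sc$m[j], sc$M[j], sc$orientation[j])
  }
  d
}
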