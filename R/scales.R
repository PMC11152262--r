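#' Define a wellbeing instrument
#'
#' A scale definition records, for one wellbeing instrument, its ordered item
#' columns, the per-item response bounds \code{m} (lower) and \code{M}
#' (upper), and the per-item orientation: whether a larger raw response means
#' better wellbeing (\code{"higher_is_better"}) or worse
#' (\code{"lower_is_better"}).
#'
#' @param scale_id one of \code{"quality"}, \code{"satisfaction"},
#'   \code{"psychological"}.
#' @param items character vector of item column names, in instrument order.
#' @param m,M numeric per-item lower/upper response bounds; recycled to
#'   \code{length(items)} if scalar.
#' @param orientation per-item orientation flag; recycled if scalar.
#' @return an object of class \code{"scale_definition"}.
#' @export
scale_definition <- function(scale_id, items,
                             m, M,
                             orientation = "higher_is_better") {
  scale_id <- match.arg(scale_id, c("quality", "satisfaction", "psychological"))
  items <- as.character(items)
  k <- length(items)
  if (k < 1L) stop("a scale needs at least one item")
  m <- rep_len(as.numeric(m), k)
  M <- rep_len(as.numeric(M), k)
  orientation <- rep_len(as.character(orientation), k)
  if (!all(orientation %in% c("higher_is_better", "lower_is_better")))
    stop("orientation must be 'higher_is_better' or 'lower_is_better'")
  if (any(M <= m)) stop("upper bound M must exceed lower bound m for every item")
  structure(
    list(scale_id = scale_id, items = items, m = m, M = M,
         orientation = orientation, k = k),
    class = "scale_definition")
}

#' Default wellbeing scales
#'
#' The three instruments used throughout the package:
#' \describe{
#'   \item{quality}{CASP-19 quality-of-life construct: 19 items
#'     (Control, Autonomy, Self-realisation, Pleasure) rated on a 4-point
#'     frequency scale, stored as 1 ("Never") to 4 ("Often").}
#'   \item{satisfaction}{Satisfaction with Life: 5 statements rated
#'     1 (strongly disagree) to 7 (strongly agree).}
#'   \item{psychological}{WHO-5 wellbeing index: 5 statements rated
#'     1 ("All of the time") to 6 ("At no time"); since a low raw response is
#'     the favourable one, these items are oriented \code{lower_is_better}.}
#' }
#' All items are oriented so that a larger normalized response always means
#' better wellbeing. Whether any CASP-19 item should be reverse-scored is a
#' property of the questionnaire wording; the default treats all 19 as
#' positively worded, and \code{\link{scale_definition}} lets callers flip
#' individual items.
#'
#' @return named list of three \code{scale_definition} objects.
#' @export
default_scales <- function() {
  list(
    quality = scale_definition(
      "quality", sprintf("casp_%02d", 1:19), m = 1, M = 4),
    satisfaction = scale_definition(
      "satisfaction", sprintf("swl_%02d", 1:5), m = 1, M = 7),
    psychological = scale_definition(
      "psychological", sprintf("who_%02d", 1:5), m = 1, M = 6,
      orientation = "lower_is_better")
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items, bounds [%s, %s]\n",
              x$scale_id, x$k, format(min(x$m)), format(max(x$M))))
  invisible(x)
}
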