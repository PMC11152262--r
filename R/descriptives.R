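#' Category frequencies of one field
#'
#' @param table a survey or coded table.
#' @param field column name.
#' @return list of class \code{"frequency_report"} with the field name,
#'   per-category \code{counts}, \code{n_missing} and base \code{n}.
#' @export
frequency_counts <- function(table, field) {
  if (!field %in% names(table)) stop("unknown field '", field, "'")
  x <- table[[field]]
  counts <- table(x, useNA = "no")
  structure(list(field = field,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts)),
                 n_missing = sum(is.na(x)),
                 n = length(x)),
            class = "frequency_report")
}

#' @export
print.frequency_report <- function(x, ...) {
  cat(sprintf("<frequency_report> %s (n = %d, missing = %d)\n",
              x$field, x$n, x$n_missing))
  print(x$counts)
  invisible(x)
}

#' Distribution of activity participation
#'
#' Counts respondents with zero, exactly one, and two-or-more distinct
#' activities, separately for class participation and place visits.
#'
#' @param table a \code{survey_table} with the activity flag columns.
#' @return list with integer triples \code{classes} and \code{places},
#'   each named \code{none}/\code{one}/\code{two_plus}.
#' @export
activity_distribution <- function(table) {
  triple <- function(tot) {
    c(none = sum(tot == 0), one = sum(tot == 1), two_plus = sum(tot >= 2))
  }
  list(classes = triple(rowSums(table[class_flag_fields()])),
       places = triple(rowSums(table[place_flag_fields()])))
}

#' Cross-correlations of the three wellbeing indices
#'
#' Pearson correlations over complete score rows. Zero-variance scores
#' yield \code{NA} entries with a warning.
#'
#' @param scores a \code{wellbeing_scores} data.frame.
#' @return symmetric 3x3 correlation matrix with unit diagonal.
#' @export
mwi_correlations <- function(scores) {
  m <- as.matrix(scores[c("mwi_quality", "mwi_satisfaction",
                          "mwi_psychological")])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 complete score rows")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance score column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  suppressWarnings(stats::cor(m))
}

#' Wellbeing distributions by learning attitude
#'
#' Per-group (learn_elderly yes/no) summaries of each wellbeing index:
#' mean, quartiles, and adjusted Fisher-Pearson sample skewness. Rows with
#' missing group membership are skipped; groups with fewer than 2 members
#' get \code{NA} summaries.
#'
#' @param scores a \code{wellbeing_scores} data.frame.
#' @param group grouping vector aligned with \code{scores} rows
#'   (e.g. \code{coded$learn_elderly}).
#' @return data.frame with one row per group and index.
#' @export
grouped_distribution <- function(scores, group) {
  stopifnot(length(group) == nrow(scores))
  out <- NULL
  for (h in c("quality", "satisfaction", "psychological")) {
    x <- scores[[paste0("mwi_", h)]]
    for (g in sort(unique(stats::na.omit(group)))) {
      v <- x[!is.na(group) & group == g & !is.na(x)]
      row <- if (length(v) >= 2L) {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(index = h, group = g, n = length(v), mean = mean(v),
                   q25 = q[1], median = q[2], q75 = q[3],
                   skewness = sample_skewness(v))
      } else {
        data.frame(index = h, group = g, n = length(v), mean = NA_real_,
                   q25 = NA_real_, median = NA_real_, q75 = NA_real_,
                   skewness = NA_real_)
      }
      out <- rbind(out, row)
    }
  }
  out
}

#' Adjusted Fisher-Pearson sample skewness
#' @param x numeric vector, length >= 3.
#' @return skewness estimate.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  g1 <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
  sqrt(n * (n - 1)) / (n - 2) * g1
}
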