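#' Quartile discretization of wellbeing scores
#'
#' Bins scores into quartile categories Q1 (worst wellbeing) to Q4 (best),
#' with breakpoints at the 25/50/75 linear-interpolation sample percentiles.
#' A value exactly at a breakpoint falls in the lower bin. Missing scores
#' stay missing. If all scores are identical the quartiles degenerate: all
#' values go to Q1 and a warning is emitted.
#'
#' @param scores numeric vector of index values.
#' @return factor with levels \code{Q1..Q4}.
#' @export
quartile_bin <- function(scores) {
  obs <- scores[!is.na(scores)]
  if (length(obs) < 4L)
    stop("need at least 4 non-missing scores to form quartiles")
  brk <- stats::quantile(obs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (length(unique(obs)) == 1L) {
    warning("all scores identical; quartile binning is degenerate")
    out <- factor(ifelse(is.na(scores), NA, "Q1"), levels = paste0("Q", 1:4))
    return(out)
  }
  bin <- findInterval(scores, brk, left.open = TRUE) + 1L  # <= brk -> lower
  factor(paste0("Q", bin), levels = paste0("Q", 1:4), exclude = "QNA")
}

#' Band the number of children
#'
#' @param n_children non-negative integer count(s).
#' @return factor with levels \code{no child}, \code{1-3 children},
#'   \code{more than 3 children}.
#' @export
recode_children <- function(n_children) {
  if (any(!is.na(n_children) & (n_children < 0 |
                                n_children != round(n_children))))
    stop("number of children must be a non-negative integer")
  lev <- c("no child", "1-3 children", "more than 3 children")
  band <- ifelse(is.na(n_children), NA_character_,
                 ifelse(n_children == 0, lev[1],
                        ifelse(n_children <= 3, lev[2], lev[3])))
  factor(band, levels = lev)
}

#' Binarize an activity count
#'
#' Flags sustained engagement: 1 if the respondent took part in
#' \code{threshold} or more distinct activities, else 0.
#'
#' @param total non-negative activity count(s).
#' @param threshold count at or above which the flag is 1 (default 2).
#' @return integer 0/1 vector.
#' @export
binarize_activity <- function(total, threshold = 2) {
  if (any(!is.na(total) & total < 0)) stop("activity count must be >= 0")
  as.integer(total >= threshold)
}

#' Collapse raw survey categories into the analysis coding
#'
#' Applies every recoding rule feeding the MCA, tree and regression stages:
#' \itemize{
#'   \item wellbeing quartile tags per domain (Q1 worst .. Q4 best);
#'   \item \code{children_band} (no child / 1-3 / more than 3), with the
#'     raw \code{no_children} count kept alongside for the regression
#'     stage;
#'   \item \code{class_total}, \code{places_total}: number of distinct
#'     activity types flagged, plus binarized versions at the
#'     two-or-more threshold;
#'   \item \code{working}: yes for working, working part-time, ad-hoc or
#'     freelance; no otherwise; \code{retired_yes} from work status;
#'   \item \code{health_good}: good for "good"/"very good";
#'   \item \code{family_good}, \code{friends_good}: good for
#'     "good"/"excellent";
#'   \item \code{education_band}: "more than secondary" versus
#'     "secondary or less";
#'   \item \code{female}, \code{married}, \code{disability}, \code{mobility}
#'     flags; \code{learn_elderly} retained with its missing values.
#' }
#' Rows are never dropped; each downstream stage applies its own
#' complete-case rule.
#'
#' @param table a validated \code{survey_table}.
#' @param scores matching \code{wellbeing_scores} (from
#'   \code{\link{score_table}}); if \code{NULL}, computed here.
#' @param scales scale definitions used when scoring.
#' @return data.frame of class \code{"coded_table"}.
#' @export
collapse_levels <- function(table, scores = NULL,
                            scales = default_scales()) {
  if (is.null(scores)) scores <- score_table(table, scales)
  stopifnot(identical(table$respondent_id, scores$respondent_id))
  map_or_stop <- function(x, from, what) {
    bad <- !is.na(x) & !x %in% from
    if (any(bad))
      stop("unmapped ", what, " category '", x[which(bad)[1]], "'")
    x
  }
  health <- map_or_stop(table$health,
                        c("poor", "fair", "good", "very good"), "health")
  work <- map_or_stop(table$work,
                      c("working", "working part-time", "ad-hoc",
                        "freelance", "retired", "not working"), "work")
  edu <- map_or_stop(table$education,
                     c("none", "primary", "secondary", "post-secondary",
                       "diploma", "degree"), "education")
  rel_good <- function(x, what) {
    x <- map_or_stop(x, c("poor", "fair", "good", "excellent"), what)
    ifelse(is.na(x), NA_character_,
           ifelse(x %in% c("good", "excellent"), "good", "not good"))
  }
  class_total <- rowSums(table[class_flag_fields()])
  places_total <- rowSums(table[place_flag_fields()])
  out <- data.frame(
    respondent_id = table$respondent_id,
    quality_q = quartile_bin(scores$mwi_quality),
    satisfaction_q = quartile_bin(scores$mwi_satisfaction),
    psychological_q = quartile_bin(scores$mwi_psychological),
    no_children = table$no_children,
    children_band = recode_children(table$no_children),
    class_total = as.integer(class_total),
    places_total = as.integer(places_total),
    class_total_bin = binarize_activity(class_total),
    places_total_bin = binarize_activity(places_total),
    working = ifelse(is.na(work), NA_character_,
                     ifelse(work %in% c("working", "working part-time",
                                        "ad-hoc", "freelance"),
                            "yes", "no")),
    retired_yes = as.integer(work == "retired"),
    health_good = ifelse(is.na(health), NA_character_,
                         ifelse(health %in% c("good", "very good"),
                                "good", "not good")),
    family_good = rel_good(table$family_rel, "family relationship"),
    friends_good = rel_good(table$friends_rel, "friends relationship"),
    education_band = ifelse(is.na(edu), NA_character_,
                            ifelse(edu %in% c("post-secondary", "diploma",
                                              "degree"),
                                   "more than secondary",
                                   "secondary or less")),
    learn_elderly = table$learn_elderly,
    disability = table$disability,
    mobility = table$mobility,
    female = as.integer(table$gender == "female"),
    married = as.integer(table$marital == "married"),
    stringsAsFactors = FALSE)
  class(out) <- c("coded_table", "data.frame")
  out
}
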