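#' Survey codebook
#'
#' The codebook declares, for every column of a survey table, its kind
#' (\code{id}, \code{ordinal}, \code{nominal}, \code{count} or \code{flag}),
#' the allowed categories or levels, and — for wellbeing items — which scale
#' the column belongs to. Validation in \code{\link{read_survey}} is driven
#' entirely by this declaration, so alternative column names or response
#' labels in a deposited dataset can be accommodated by editing the codebook
#' rather than the code.
#'
#' Field entry structure:
#' \itemize{
#'   \item \code{kind}: one of \code{"id"}, \code{"ordinal"}, \code{"nominal"},
#'     \code{"count"}, \code{"flag"}.
#'   \item \code{levels}: for nominal fields, the allowed category strings;
#'     for ordinal item fields, optional verbal labels mapped to the equally
#'     spaced integers \code{1..length(levels)} at read time.
#'   \item \code{scale}: scale id for wellbeing item fields.
#'   \item \code{missing_ok}: whether an empty cell is tolerated
#'     (default \code{FALSE} except where declared).
#' }
#'
#' @param fields named list of field declarations (see Details).
#' @return object of class \code{"codebook"}.
#' @export
codebook <- function(fields) {
  stopifnot(is.list(fields), !is.null(names(fields)))
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.null(f$kind) ||
        !f$kind %in% c("id", "ordinal", "nominal", "count", "flag"))
      stop("field '", nm, "': kind must be id/ordinal/nominal/count/flag")
    if (is.null(f$missing_ok)) fields[[nm]]$missing_ok <- FALSE
  }
  structure(list(fields = fields), class = "codebook")
}

#' Default codebook for the elderly lifelong-learning survey
#'
#' Reconstructs the survey schema: the three wellbeing instruments (CASP-19,
#' Satisfaction with Life, WHO-5), demographics (gender, marital status,
#' children, education, work status, health, disability, mobility, family and
#' friend relationship quality), the lifelong-learning attitude question
#' \code{learn_elderly} (the one field where a missing answer is tolerated),
#' per-class participation flags (singing, dancing, music, exercise, other)
#' and per-place visit flags (gym, sports club, museum, library, educational
#' institute, other).
#'
#' @param scales list of scale definitions, as \code{\link{default_scales}}.
#' @return a \code{codebook}.
#' @export
default_codebook <- function(scales = default_scales()) {
  fields <- list(respondent_id = list(kind = "id"))
  casp_labels <- c("Never", "Not often", "Sometimes", "Often")
  who_labels <- c("All of the time", "Most of the time",
                  "More than half of the time", "Less than half of the time",
                  "Some of the time", "At no time")
  for (it in scales$quality$items)
    fields[[it]] <- list(kind = "ordinal", levels = casp_labels,
                         scale = "quality")
  for (it in scales$satisfaction$items)
    fields[[it]] <- list(kind = "ordinal", levels = as.character(1:7),
                         scale = "satisfaction")
  for (it in scales$psychological$items)
    fields[[it]] <- list(kind = "ordinal", levels = who_labels,
                         scale = "psychological")
  fields$gender <- list(kind = "nominal", levels = c("female", "male"))
  fields$marital <- list(kind = "nominal",
                         levels = c("single", "married", "widowed", "divorced"))
  fields$no_children <- list(kind = "count")
  fields$education <- list(kind = "nominal",
                           levels = c("none", "primary", "secondary",
                                      "post-secondary", "diploma", "degree"))
  fields$work <- list(kind = "nominal",
                      levels = c("working", "working part-time", "ad-hoc",
                                 "freelance", "retired", "not working"))
  fields$health <- list(kind = "nominal",
                        levels = c("poor", "fair", "good", "very good"))
  fields$disability <- list(kind = "flag")
  fields$mobility <- list(kind = "flag")
  fields$family_rel <- list(kind = "nominal",
                            levels = c("poor", "fair", "good", "excellent"))
  fields$friends_rel <- list(kind = "nominal",
                             levels = c("poor", "fair", "good", "excellent"))
  fields$learn_elderly <- list(kind = "nominal", levels = c("yes", "no"),
                               missing_ok = TRUE)
  for (cl in class_flag_fields())
    fields[[cl]] <- list(kind = "flag")
  for (pl in place_flag_fields())
    fields[[pl]] <- list(kind = "flag")
  codebook(fields)
}

#' @rdname default_codebook
#' @export
class_flag_fields <- function() {
  paste0("class_", c("singing", "dancing", "music", "exercise", "other"))
}

#' @rdname default_codebook
#' @export
place_flag_fields <- function() {
  paste0("place_", c("gym", "sports_club", "museum", "library",
                     "educational_institute", "other"))
}

#' Read or write a codebook as JSON
#'
#' @param path file path.
#' @param cb a \code{codebook}.
#' @return \code{read_codebook} returns a \code{codebook};
#'   \code{write_codebook} returns \code{path} invisibly.
#' @export
read_codebook <- function(path) {
  codebook(jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE))
}

#' @rdname read_codebook
#' @export
write_codebook <- function(cb, path) {
  jsonlite::write_json(cb$fields, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.codebook <- function(x, ...) {
  kinds <- vapply(x$fields, `[[`, "", "kind")
  cat(sprintf("<codebook> %d fields (%s)\n", length(kinds),
              paste(sprintf("%s: %d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
  invisible(x)
}
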