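#' Read a respondent-level survey table
#'
#' Reads a delimited text file (CSV, UTF-8, header row) and validates every
#' cell against the codebook. Verbal ordinal responses are mapped to equally
#' spaced integers \code{1..L} where \code{L} is the number of declared
#' labels; flags are coerced to 0/1; empty cells become missing values and
#' are rejected unless the field declares \code{missing_ok}.
#'
#' @param path path to a CSV file.
#' @param cb a \code{\link{codebook}}; defaults to the shipped survey schema.
#' @return a validated \code{data.frame} of class \code{"survey_table"} with
#'   the codebook attached as attribute \code{"codebook"}.
#' @export
read_survey <- function(path, cb = default_codebook()) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  validate_survey(raw, cb)
}

#' Validate a raw survey table against a codebook
#'
#' Every declared column must be present and every cell is checked; there is
#' no silent coercion. Works on freshly read character data or on an already
#' typed table (idempotent on valid input).
#'
#' @param df data.frame of raw survey fields.
#' @param cb a \code{\link{codebook}}.
#' @return a typed, validated \code{survey_table}.
#' @export
validate_survey <- function(df, cb = default_codebook()) {
  fields <- cb$fields
  missing_cols <- setdiff(names(fields), names(df))
  if (length(missing_cols))
    stop("survey table is missing declared column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), names(fields))
  if (length(extra))
    stop("survey table has undeclared column(s): ",
         paste(extra, collapse = ", "))
  out <- df[names(fields)]
  for (nm in names(fields)) {
    f <- fields[[nm]]
    x <- out[[nm]]
    if (is.factor(x)) x <- as.character(x)
    chr <- as.character(x)
    is_na <- is.na(chr) | chr == ""
    if (any(is_na) && !isTRUE(f$missing_ok))
      stop("field '", nm, "': missing value in row(s) ",
           paste(utils::head(which(is_na), 5), collapse = ", "),
           " but missing values are not allowed")
    val <- switch(
      f$kind,
      id = chr,
      nominal = {
        bad <- !is_na & !chr %in% f$levels
        if (any(bad))
          stop("field '", nm, "': value '", chr[which(bad)[1]],
               "' in row ", which(bad)[1], " not among allowed levels")
        chr
      },
      ordinal = {
        v <- rep(NA_integer_, length(chr))
        lab <- match(chr, f$levels)
        num <- suppressWarnings(as.integer(chr))
        v[!is_na] <- ifelse(!is.na(lab[!is_na]), lab[!is_na], num[!is_na])
        bad <- !is_na & (is.na(v) | v < 1L | v > length(f$levels))
        if (any(bad))
          stop("field '", nm, "': value '", chr[which(bad)[1]],
               "' in row ", which(bad)[1], " is out of range 1..",
               length(f$levels))
        v
      },
      count = {
        v <- suppressWarnings(as.integer(chr))
        bad <- !is_na & (is.na(v) | v < 0L)
        if (any(bad))
          stop("field '", nm, "': value '", chr[which(bad)[1]],
               "' in row ", which(bad)[1], " is not a non-negative integer")
        v
      },
      flag = {
        v <- rep(NA_integer_, length(chr))
        v[chr %in% c("1", "yes", "TRUE", "true")] <- 1L
        v[chr %in% c("0", "no", "FALSE", "false")] <- 0L
        bad <- !is_na & is.na(v)
        if (any(bad))
          stop("field '", nm, "': value '", chr[which(bad)[1]],
               "' in row ", which(bad)[1], " is not a 0/1 flag")
        v
      })
    val[is_na] <- NA
    out[[nm]] <- val
  }
  if (anyDuplicated(out$respondent_id))
    stop("respondent_id must be unique")
  structure(out, codebook = cb, class = c("survey_table", "data.frame"))
}

#' Write a table as CSV
#'
#' Missing cells are written as the empty-string sentinel, so
#' \code{read_survey(write_table(tab))} round-trips a survey table.
#'
#' @param tab a non-empty data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(tab, path) {
  if (!is.data.frame(tab) || nrow(tab) == 0L || ncol(tab) == 0L)
    stop("refusing to write an empty table")
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Item columns of a survey table belonging to one scale
#' @param cb a codebook.
#' @param scale_id scale identifier.
#' @return character vector of column names, in declared order.
#' @export
scale_items <- function(cb, scale_id) {
  keep <- vapply(cb$fields, function(f) identical(f$scale, scale_id), FALSE)
  names(cb$fields)[keep]
}
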