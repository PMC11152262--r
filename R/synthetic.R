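#' Ground-truth effect sizes used by the synthetic generator
#'
#' One row per covariate (in the coding used by the regression stage), one
#' column per wellbeing domain, in latent index units. The defaults plant
#' effects of the magnitudes the analysis is designed to detect, e.g. a
#' 0.0611 quality-of-life effect of a positive lifelong-learning attitude
#' and class-participation effects of 0.05--0.08 across all three domains.
#'
#' @return numeric matrix, covariates by domains.
#' @export
default_effects <- function() {
  m <- rbind(
    learn_elderly  = c(0.0611,  0.0414,   0.0289),
    class_total    = c(0.0491,  0.0739,   0.0802),
    places_total   = c(0.00355, -0.00305, 0.000605),
    disability     = c(-0.00879, 0.0989,  0.0137),
    mobility       = c(-0.0197, -0.0601, -0.0501),
    health_good    = c(0.0957,  0.108,    0.0972),
    family_good    = c(0.0482,  0.128,    0.111),
    friends_good   = c(0.0299,  0.0281,   0.0103),
    retired_yes    = c(0.0160,  0.0844,   0.0658),
    female         = c(-0.0259, -0.00938, 0.000197),
    married        = c(0.0260,  0.0202,   0.0322),
    secondary_more = c(0.0173,  -0.0620, -0.0485),
    no_children    = c(0.00714, 0.00244, -0.000965))
  colnames(m) <- c("quality", "satisfaction", "psychological")
  m
}

#' Default category probabilities for the demographic fields
#'
#' Category probabilities emulating the marginal profile of a community
#' sample of Singapore residents aged 65+: a mostly retired population,
#' primary education as the modal level with only ~14% educated beyond
#' secondary school, ~63% in good or very good self-rated health, two
#' children as the modal family size, a 205:87 split of positive versus
#' negative lifelong-learning attitudes, exercise as the most common class
#' activity and the library as the most visited place, with activity-count
#' distributions concentrated at zero.
#'
#' @return named list of probability vectors.
#' @export
default_marginals <- function() {
  list(
    gender = c(female = 0.5, male = 0.5),
    marital = c(single = 0.10, married = 0.62, widowed = 0.22,
                divorced = 0.06),
    no_children = c("0" = 0.09, "1" = 0.19, "2" = 0.35, "3" = 0.20,
                    "4" = 0.11, "5" = 0.06),
    education = c(none = 0.10, primary = 0.3434, secondary = 0.4133,
                  "post-secondary" = 0.06, diploma = 0.05, degree = 0.0333),
    work = c(working = 0.12, "working part-time" = 0.06, "ad-hoc" = 0.02,
             freelance = 0.01, retired = 0.76, "not working" = 0.03),
    health = c(poor = 0.07, fair = 0.30, good = 0.45, "very good" = 0.18),
    disability = c("0" = 0.95, "1" = 0.05),
    mobility = c("0" = 0.91, "1" = 0.09),
    family_rel = c(poor = 0.03, fair = 0.17, good = 0.55, excellent = 0.25),
    friends_rel = c(poor = 0.04, fair = 0.26, good = 0.55, excellent = 0.15),
    learn_elderly = c(yes = 205 / 292, no = 87 / 292),
    class_count = c("0" = 147 / 292, "1" = 118 / 292, "2" = 22 / 292,
                    "3" = 4 / 292, "4" = 1 / 292),
    class_weights = c(class_singing = 0.25, class_dancing = 0.10,
                      class_music = 0.08, class_exercise = 0.45,
                      class_other = 0.12),
    place_count = c("0" = 225 / 292, "1" = 52 / 292, "2" = 12 / 292,
                    "3" = 3 / 292),
    place_weights = c(place_gym = 0.12, place_sports_club = 0.10,
                      place_museum = 0.12, place_library = 0.45,
                      place_educational_institute = 0.09,
                      place_other = 0.12))
}

#' Configuration for the synthetic survey generator
#'
#' @param n respondent count (default 300, the study design size).
#' @param seed integer seed; all randomness flows from it.
#' @param effects covariate-by-domain effect matrix in latent units;
#'   row names must be regression covariate names
#'   (see \code{\link{default_effects}}).
#' @param intercepts per-domain latent intercepts.
#' @param noise_sd per-domain residual standard deviation (latent units).
#' @param resid_cor correlation of residuals across domains (a shared latent
#'   wellbeing factor), so the three indices correlate at realistic levels
#'   beyond what shared covariates induce.
#' @param item_noise_sd per-item noise added to the target normalized
#'   response before discretization to the ordinal grid.
#' @param squash map from the latent index to the unit interval:
#'   \code{"identity"} (clip to \code{[0,1]}; effects pass through
#'   undistorted — the test default) or \code{"logistic"}.
#' @param missing_learn number of respondents whose \code{learn_elderly}
#'   answer is blanked (default 8).
#' @param marginals category probabilities, see \code{\link{default_marginals}}.
#' @return object of class \code{"generator_config"}.
#' @export
generator_config <- function(n = 300, seed = 1,
                             effects = default_effects(),
                             intercepts = c(quality = 0.343,
                                            satisfaction = 0.293,
                                            psychological = 0.348),
                             noise_sd = 0.11,
                             resid_cor = 0.5,
                             item_noise_sd = 0.08,
                             squash = c("identity", "logistic"),
                             missing_learn = 8,
                             marginals = default_marginals()) {
  squash <- match.arg(squash)
  if (n < 1) stop("n must be at least 1")
  if (noise_sd <= 0 || item_noise_sd < 0) stop("noise scales must be positive")
  if (resid_cor < 0 || resid_cor > 1) stop("resid_cor must lie in [0, 1]")
  if (missing_learn < 0 || missing_learn > n)
    stop("missing_learn must lie in [0, n]")
  unknown <- setdiff(rownames(effects), rownames(default_effects()))
  if (length(unknown))
    stop("effect(s) named for unknown covariate(s): ",
         paste(unknown, collapse = ", "))
  for (nm in names(marginals)) {
    p <- marginals[[nm]]
    if (!grepl("weights$", nm) && abs(sum(p) - 1) > 1e-8)
      stop("marginal probabilities for '", nm, "' must sum to 1")
  }
  structure(list(n = n, seed = seed, effects = effects,
                 intercepts = intercepts, noise_sd = noise_sd,
                 resid_cor = resid_cor, item_noise_sd = item_noise_sd,
                 squash = squash, missing_learn = missing_learn,
                 marginals = marginals),
            class = "generator_config")
}

draw_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

draw_flag_set <- function(count, weights) {
  flags <- setNames(integer(length(weights)), names(weights))
  if (count > 0) {
    pick <- sample(names(weights), min(count, length(weights)),
                   prob = weights)
    flags[pick] <- 1L
  }
  flags
}

#' Generate a synthetic survey with known ground truth
#'
#' Simulation model: (1) demographics and activity flags are drawn from the
#' configured marginals; (2) a latent wellbeing index per domain is
#' \code{intercept + X beta + noise}, with residuals sharing a common factor
#' across domains; (3) the latent index is squashed to \code{[0, 1]} and
#' treated as the target mean normalized response; (4) each item response is
#' the target plus item noise, clipped to \code{[0, 1]}, mapped back to the
#' item's raw range and rounded to the ordinal grid, honouring item
#' orientation; (5) exactly \code{missing_learn} respondents get a missing
#' \code{learn_elderly}.
#'
#' @param config a \code{\link{generator_config}}.
#' @param scales scale definitions (default \code{\link{default_scales}}).
#' @param cb codebook (default \code{\link{default_codebook}}).
#' @return list with elements \code{table} (a validated
#'   \code{survey_table}) and \code{truth} (latent wellbeing matrix
#'   \code{W}, numeric design matrix \code{X}, the effect matrix, and the
#'   config).
#' @export
generate_survey <- function(config = generator_config(),
                            scales = default_scales(),
                            cb = default_codebook()) {
  set.seed(config$seed)
  n <- config$n
  mg <- config$marginals

  df <- data.frame(respondent_id = sprintf("R%04d", seq_len(n)),
                   stringsAsFactors = FALSE)
  df$gender <- draw_cat(n, mg$gender)
  df$marital <- draw_cat(n, mg$marital)
  df$no_children <- as.integer(draw_cat(n, mg$no_children))
  df$education <- draw_cat(n, mg$education)
  df$work <- draw_cat(n, mg$work)
  df$health <- draw_cat(n, mg$health)
  df$disability <- as.integer(draw_cat(n, mg$disability))
  df$mobility <- as.integer(draw_cat(n, mg$mobility))
  df$family_rel <- draw_cat(n, mg$family_rel)
  df$friends_rel <- draw_cat(n, mg$friends_rel)
  df$learn_elderly <- draw_cat(n, mg$learn_elderly)

  class_n <- as.integer(draw_cat(n, mg$class_count))
  place_n <- as.integer(draw_cat(n, mg$place_count))
  class_flags <- t(vapply(class_n, draw_flag_set,
                          setNames(integer(5), names(mg$class_weights)),
                          weights = mg$class_weights))
  place_flags <- t(vapply(place_n, draw_flag_set,
                          setNames(integer(6), names(mg$place_weights)),
                          weights = mg$place_weights))
  df <- cbind(df, as.data.frame(class_flags), as.data.frame(place_flags))

  # numeric design in the regression stage's coding
  X <- cbind(
    learn_elderly = as.integer(df$learn_elderly == "yes"),
    class_total = rowSums(class_flags),
    places_total = rowSums(place_flags),
    disability = df$disability,
    mobility = df$mobility,
    health_good = as.integer(df$health %in% c("good", "very good")),
    family_good = as.integer(df$family_rel %in% c("good", "excellent")),
    friends_good = as.integer(df$friends_rel %in% c("good", "excellent")),
    retired_yes = as.integer(df$work == "retired"),
    female = as.integer(df$gender == "female"),
    married = as.integer(df$marital == "married"),
    secondary_more = as.integer(df$education %in%
                                  c("post-secondary", "diploma", "degree")),
    no_children = df$no_children)

  beta <- matrix(0, ncol(X), 3,
                 dimnames = list(colnames(X),
                                 c("quality", "satisfaction",
                                   "psychological")))
  beta[rownames(config$effects), colnames(config$effects)] <- config$effects

  z0 <- stats::rnorm(n)
  W <- matrix(NA_real_, n, 3, dimnames = list(NULL, colnames(beta)))
  for (h in colnames(beta)) {
    eps <- config$noise_sd * (sqrt(config$resid_cor) * z0 +
                                sqrt(1 - config$resid_cor) * stats::rnorm(n))
    W[, h] <- config$intercepts[[h]] + drop(X %*% beta[, h]) + eps
  }
  target <- switch(config$squash,
                   identity = pmin(pmax(W, 0), 1),
                   logistic = stats::plogis(4 * (W - 0.5)))

  for (sc in scales) {
    for (j in seq_len(sc$k)) {
      d <- target[, sc$scale_id] +
        stats::rnorm(n, sd = config$item_noise_sd)
      d <- pmin(pmax(d, 0), 1)
      if (sc$orientation[j] == "lower_is_better") d <- 1 - d
      df[[sc$items[j]]] <- as.integer(round(sc$m[j] + d * (sc$M[j] - sc$m[j])))
    }
  }

  if (config$missing_learn > 0) {
    blank <- sample.int(n, config$missing_learn)
    df$learn_elderly[blank] <- NA_character_
  }

  table <- validate_survey(df[names(cb$fields)], cb)
  truth <- list(W = W, X = X, effects = beta, config = config)
  list(table = table, truth = truth)
}

#' Built-in deterministic fixtures
#'
#' \describe{
#'   \item{tiny8}{8 respondents, all fields populated, no missing values.}
#'   \item{paper_like_300}{300 respondents with default marginals and
#'     effects, exactly 8 missing \code{learn_elderly}.}
#'   \item{allbest4}{4 respondents answering every wellbeing item at its
#'     best level (constructed, not simulated).}
#' }
#'
#' @param name fixture id.
#' @return a validated \code{survey_table}.
#' @export
make_fixture <- function(name) {
  switch(
    name,
    tiny8 = generate_survey(generator_config(n = 8, seed = 8,
                                             missing_learn = 0))$table,
    paper_like_300 = generate_survey(generator_config(n = 300,
                                                      seed = 300))$table,
    allbest4 = {
      tab <- generate_survey(generator_config(n = 4, seed = 4,
                                              missing_learn = 0))$table
      for (sc in default_scales()) {
        best <- ifelse(sc$orientation == "lower_is_better", sc$m, sc$M)
        for (j in seq_len(sc$k)) tab[[sc$items[j]]] <- as.integer(best[j])
      }
      validate_survey(tab)
    },
    stop("unknown fixture '", name, "'"))
}
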