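#' End-to-end analysis run
#'
#' Orchestrates the full pipeline — load or synthesize the survey, score
#' the wellbeing indices, recode, descriptives, MCA, the three regression
#' trees and the three robust-SE regressions — writing a reproducible
#' bundle of CSV/JSON/text outputs plus a manifest to \code{out_dir}.
#'
#' @param input either a path to a survey CSV or a
#'   \code{\link{generator_config}} for synthetic input (exactly one
#'   source).
#' @param out_dir output directory; created if absent.
#' @param cb codebook used to read/validate the survey.
#' @param scales scale definitions.
#' @param stages character vector of stage names to run, a subset of
#'   \code{c("score", "recode", "describe", "mca", "tree", "regress")}.
#'   Scoring and recoding always run (everything downstream needs them);
#'   toggles control what is written and which analyses execute.
#' @param min_node,min_gain_frac tree pre-pruning parameters.
#' @param hc_variant robust-variance variant for the regressions.
#' @param mca_vars active variable set for the MCA.
#' @param n_dims retained MCA dimensions.
#' @return invisible list with every stage result and the manifest.
#' @export
run_full_analysis <- function(input,
                              out_dir,
                              cb = default_codebook(),
                              scales = default_scales(),
                              stages = c("score", "recode", "describe",
                                         "mca", "tree", "regress"),
                              min_node = 20, min_gain_frac = 0.01,
                              hc_variant = "HC1",
                              mca_vars = default_active_vars(),
                              n_dims = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  manifest <- list(package_version = as.character(
    utils::packageVersion("elderwell")),
    stages = stages, min_node = min_node,
    min_gain_frac = min_gain_frac, hc_variant = hc_variant)
  stage <- "input"
  result <- list()
  tryCatch({
    if (inherits(input, "generator_config")) {
      manifest$input <- list(source = "synthetic", n = input$n,
                             seed = input$seed)
      gen <- generate_survey(input, scales, cb)
      table <- gen$table
      result$truth <- gen$truth
      note("input: synthesized %d respondents (seed %d)", input$n,
           input$seed)
    } else {
      manifest$input <- list(source = "csv", path = input)
      table <- read_survey(input, cb)
      note("input: read %d respondents from %s", nrow(table), input)
    }
    result$table <- table

    stage <- "score"
    scores <- score_table(table, scales)
    result$scores <- scores
    note("score: %d/%d respondents fully scored on all three indices",
         sum(stats::complete.cases(scores[-1])), nrow(scores))
    if ("score" %in% stages)
      write_table(scores, file.path(out_dir, "scores.csv"))

    stage <- "recode"
    coded <- collapse_levels(table, scores, scales)
    result$coded <- coded
    if ("recode" %in% stages)
      write_table(coded, file.path(out_dir, "coded.csv"))

    if ("describe" %in% stages) {
      stage <- "describe"
      freq <- frequency_counts(table, "learn_elderly")
      act <- activity_distribution(table)
      corr <- mwi_correlations(scores)
      dist <- grouped_distribution(scores, coded$learn_elderly)
      result$describe <- list(learn_elderly = freq, activity = act,
                              correlations = corr, grouped = dist)
      write_table(data.frame(category = names(freq$counts),
                             count = freq$counts,
                             row.names = NULL),
                  file.path(out_dir, "freq_learn_elderly.csv"))
      write_table(as.data.frame(corr),
                  file.path(out_dir, "mwi_correlations.csv"))
      write_table(dist, file.path(out_dir, "grouped_distribution.csv"))
      note("describe: learn_elderly yes=%d no=%d missing=%d",
           freq$counts[["yes"]], freq$counts[["no"]], freq$n_missing)
    }

    if ("mca" %in% stages) {
      stage <- "mca"
      ind <- one_hot(coded, mca_vars)
      mca <- fit_mca(ind, n_dims = n_dims)
      result$mca <- mca
      note("mca: %d complete cases (%d dropped), dims 1-2 explain %.1f%%",
           mca$n, mca$n_dropped, 100 * sum(mca$explained[1:2]))
      write_table(data.frame(dim = seq_along(mca$inertias),
                             inertia = mca$inertias,
                             explained = mca$explained),
                  file.path(out_dir, "mca_inertia.csv"))
      ft <- factor_table(mca, c(1, 2), coded)
      write_table(ft[ft$type == "category", ],
                  file.path(out_dir, "mca_categories.csv"))
      write_table(ft[ft$type == "individual", ],
                  file.path(out_dir, "mca_individuals.csv"))
    }

    if ("tree" %in% stages) {
      stage <- "tree"
      trees <- lapply(c(quality = "quality", satisfaction = "satisfaction",
                        psychological = "psychological"),
                      function(h) wellbeing_tree(coded, scores, h,
                                                 min_node, min_gain_frac))
      result$trees <- trees
      for (h in names(trees)) {
        writeLines(render_tree(trees[[h]]),
                   file.path(out_dir, paste0("tree_", h, ".txt")))
        note("tree %s: root mean %.2f on n=%d (%d dropped)", h,
             trees[[h]]$mean, attr(trees[[h]], "n_used"),
             attr(trees[[h]], "n_dropped"))
      }
      jsonlite::write_json(lapply(trees, tree_to_list),
                           file.path(out_dir, "trees.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    if ("regress" %in% stages) {
      stage <- "regress"
      regs <- fit_wellbeing_regressions(coded, scores, hc_variant)
      result$regressions <- regs
      note("regress: n=%d after listwise deletion (%d dropped)",
           regs$quality$n, attr(regs, "n_dropped"))
      tab <- table3_layout(regs)
      utils::write.table(cbind(rownames(tab), unclass(tab)),
                         file.path(out_dir, "regressions.txt"),
                         quote = FALSE, sep = "\t", row.names = FALSE,
                         col.names = c("", colnames(tab)))
      tidy <- do.call(rbind, lapply(names(regs), function(h) {
        r <- regs[[h]]
        data.frame(outcome = h, term = names(r$coefficients),
                   estimate = unname(r$coefficients),
                   robust_se = unname(r$se), p_value = unname(r$p),
                   stringsAsFactors = FALSE)
      }))
      write_table(tidy, file.path(out_dir, "regressions.csv"))
    }

    manifest$stages_completed <- intersect(
      c("score", "recode", "describe", "mca", "tree", "regress"), stages)
    manifest$log <- log_lines
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    manifest$log <- log_lines
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  result$manifest <- manifest
  invisible(result)
}

tree_to_list <- function(node) {
  out <- list(mean = node$mean, n = node$n, proportion = node$proportion)
  if (!is.null(node$split)) {
    out$split <- node$split[setdiff(names(node$split), "gain")]
    out$split$gain <- node$split$gain
    out$left <- tree_to_list(node$left)
    out$right <- tree_to_list(node$right)
  }
  out
}
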