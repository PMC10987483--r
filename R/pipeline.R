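#' Pipeline run configuration
#'
#' Collects every stage parameter with its default and a single master seed;
#' each stochastic stage receives a seed derived deterministically from it.
#' The full configuration is mirrored into the run manifest so any run is
#' replayable.
#'
#' @param seed master integer seed.
#' @param bulk a [bulk_sim_config()] for the simulated cohort.
#' @param k_range,n_runs_survey,n_runs_final subtype-discovery parameters.
#' @param min_genes_found,min_abs_cor scoring/filter parameters.
#' @param n_folds_lasso,n_trees,top_n,drop_fraction selection parameters.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, bulk = bulk_sim_config(seed = seed),
                       k_range = 3:8, n_runs_survey = 50, n_runs_final = 500,
                       min_genes_found = 2, min_abs_cor = 0.3,
                       n_folds_lasso = 10, n_trees = 1000, top_n = 30,
                       drop_fraction = 0.1) {
  structure(list(seed = as.integer(seed), bulk = bulk, k_range = k_range,
                 n_runs_survey = n_runs_survey, n_runs_final = n_runs_final,
                 min_genes_found = min_genes_found, min_abs_cor = min_abs_cor,
                 n_folds_lasso = n_folds_lasso, n_trees = n_trees,
                 top_n = top_n, drop_fraction = drop_fraction),
            class = "run_config")
}

#' Run the end-to-end bulk pipeline on a synthetic cohort
#'
#' Executes simulate -> score -> outlier removal -> correlation filter ->
#' subtype discovery -> self-projection -> survival statistics -> signature
#' selection, writing every stage output under `out_dir` and recording a
#' manifest (parameter snapshot, derived seeds, md5 hash of every output
#' file). Re-running with an identical configuration reproduces identical
#' hashes. A stage failure is recorded in the manifest and aborts the
#' remaining stages.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest (list), invisibly written as `manifest.json`.
#' @export
run_tme_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  manifest <- list(config = unclass_deep(config), seeds = seeds,
                   stages = list(), status = "running")
  state <- new.env(parent = emptyenv())

  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      stage = stage, outputs = files,
      md5 = as.vector(tools::md5sum(files)))
  }
  run_stage <- function(stage, fun) {
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     manifest$stages[[stage]] <<- list(stage = stage,
                                                       error = conditionMessage(e))
                     manifest$status <<- paste0("failed at ", stage)
                     FALSE
                   })
    ok
  }

  stages <- list(
    simulate = function() {
      cohort <- gen_bulk_cohort(config$bulk)
      state$cohort <- cohort
      f1 <- file.path(out_dir, "expression.tsv")
      f2 <- file.path(out_dir, "survival.tsv")
      f3 <- file.path(out_dir, "signatures.gmt")
      f4 <- file.path(out_dir, "ground_truth.json")
      write_expression_tsv(cohort$expr, f1)
      write_survival_tsv(cohort$survival, f2)
      write_gmt(cohort$signatures, f3)
      jsonlite::write_json(list(subtype = as.list(cohort$truth$subtype)),
                           f4, auto_unbox = TRUE)
      record("simulate", c(f1, f2, f3, f4))
    },
    score = function() {
      sc <- score_signatures(state$cohort$expr, state$cohort$signatures,
                             min_genes_found = config$min_genes_found)
      out <- detect_outlier_samples(sc)
      if (length(out)) sc <- sc[, setdiff(colnames(sc), out), drop = FALSE]
      keep <- filter_signatures_by_correlation(sc, config$min_abs_cor)
      sc <- sc[keep, , drop = FALSE]
      state$scores <- sc
      f1 <- file.path(out_dir, "scores.tsv")
      write_expression_tsv(sc, f1)
      f2 <- file.path(out_dir, "preprocess.json")
      jsonlite::write_json(list(outliers = out, retained_signatures = keep),
                           f2, auto_unbox = FALSE)
      record("score", c(f1, f2))
    },
    discover = function() {
      fit <- tmes_fit(state$scores, k_range = config$k_range,
                      n_runs_survey = config$n_runs_survey,
                      n_runs_final = config$n_runs_final, seed = seeds[1L])
      state$fit <- fit
      f1 <- file.path(out_dir, "labels.tsv")
      write.table(data.frame(sample_id = names(fit$assignment),
                             subtype = fit$assignment),
                  f1, sep = "\t", quote = FALSE, row.names = FALSE)
      f2 <- file.path(out_dir, "survey.json")
      jsonlite::write_json(list(table = fit$survey$table,
                                chosen_k = fit$survey$chosen_k),
                           f2, auto_unbox = TRUE, digits = NA)
      f3 <- file.path(out_dir, "consensus.tsv")
      write_expression_tsv(fit$consensus, f3)
      record("discover", c(f1, f2, f3))
    },
    project_survival_select = function() {
      fit <- state$fit
      proj <- predict(fit, state$scores)
      f1 <- file.path(out_dir, "projection.tsv")
      write.table(data.frame(sample_id = names(proj$assignment),
                             subtype = proj$assignment,
                             correlation = proj$correlation),
                  f1, sep = "\t", quote = FALSE, row.names = FALSE)
      surv <- state$cohort$survival
      lr <- logrank_test(surv, fit$assignment)
      screen <- cox_screen(state$scores, surv)
      sel <- select_signatures(state$scores, surv, seed = seeds[2L],
                               n_folds_lasso = config$n_folds_lasso,
                               n_trees = config$n_trees, top_n = config$top_n,
                               drop_fraction = config$drop_fraction)
      f2 <- file.path(out_dir, "survival_stats.json")
      jsonlite::write_json(list(logrank = list(chi_square = lr$chi_square,
                                               df = lr$df, p = lr$p_value),
                                cox_screen = as.data.frame(screen)),
                           f2, auto_unbox = TRUE, digits = NA)
      f3 <- file.path(out_dir, "selection.json")
      jsonlite::write_json(list(lasso = sel$lasso_set, rf = sel$rf_set,
                                svmrfe = sel$svmrfe_set,
                                intersection = sel$intersection),
                           f3, auto_unbox = FALSE)
      record("project_survival_select", c(f1, f2, f3))
    })

  for (nm in names(stages)) {
    if (!run_stage(nm, stages[[nm]])) break
  }
  if (manifest$status == "running") manifest$status <- "complete"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

# strip S3 classes so a config serializes cleanly into the manifest
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_deep)
  x
}
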