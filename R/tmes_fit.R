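#' Fit tumor-microenvironment subtypes by consensus NMF
#'
#' The main entry point of the package: given a signatures x samples score
#' matrix (see [score_signatures()]), surveys candidate ranks by consensus
#' cophenetic and dispersion coefficients (unless `k` is fixed), fits the
#' final subtype assignment at the chosen rank, and computes subtype
#' centroids for projection onto external cohorts via [predict()].
#'
#' Rows containing negative values (e.g. pre-centered scores) are shifted up
#' by their minimum before factorization, with a logged note.
#'
#' @param scores signatures x samples numeric score matrix.
#' @param k_range candidate ranks for the survey.
#' @param k fixed rank; skips the survey when given.
#' @param n_runs_survey NMF restarts per candidate rank.
#' @param n_runs_final NMF restarts at the chosen rank.
#' @param seed master seed; all restarts derive their seeds from it.
#' @param max_iter,tol forwarded to [nmf_run()].
#' @return object of class `tmes_fit` with elements `assignment` (named
#'   sample -> TMES label), `model` (best-objective `nmf_model`), `consensus`,
#'   `survey` (`rank_survey` or `NULL`), `centroids` (for projection), `k`.
#' @seealso [predict.tmes_fit()], [rank_survey()], [final_subtypes()]
#' @examples
#' cohort <- gen_bulk_cohort(bulk_sim_config(k_true = 3, n_per_subtype = 15,
#'                                           n_signatures = 6, seed = 7))
#' sc <- score_signatures(cohort$expr, cohort$signatures)
#' fit <- tmes_fit(sc, k = 3, n_runs_survey = 5, n_runs_final = 10, seed = 7)
#' table(fit$assignment, cohort$truth$subtype)
#' @export
tmes_fit <- function(scores, k_range = 3:8, k = NULL, n_runs_survey = 50,
                     n_runs_final = 500, seed = 1, max_iter = 2000,
                     tol = 1e-6) {
  validate_scores(scores)
  V <- prepare_nmf_input(scores)
  seeds <- derive_seeds(seed, 2L)
  survey <- NULL
  if (is.null(k)) {
    survey <- rank_survey(V, k_range = k_range, n_runs = n_runs_survey,
                          seed = seeds[1L], max_iter = max_iter, tol = tol)
    k <- survey$chosen_k
  }
  fin <- final_subtypes(V, k = k, n_runs = n_runs_final, seed = seeds[2L],
                        max_iter = max_iter, tol = tol)
  centroids <- compute_centroids(scores, fin$assignment)
  structure(list(assignment = fin$assignment, model = fin$model,
                 consensus = fin$consensus, survey = survey,
                 centroids = centroids, k = as.integer(k), seed = seed),
            class = "tmes_fit")
}

#' @export
print.tmes_fit <- function(x, ...) {
  cat(sprintf("TME subtype fit: k = %d, %d samples, %d signatures\n",
              x$k, length(x$assignment), nrow(x$model$W)))
  print(table(x$assignment))
  if (!is.null(x$survey)) {
    cat(sprintf("rank chosen by cophenetic x dispersion over k = %s\n",
                paste(range(x$survey$k_range), collapse = "-")))
  }
  invisible(x)
}

#' @export
summary.tmes_fit <- function(object, ...) {
  cat("Consensus NMF subtype model\n")
  print(object)
  cat(sprintf("best-run KL objective: %.6g (%d iterations)\n",
              object$model$objective, object$model$n_iter))
  cat(sprintf("consensus dispersion: %.4f\n",
              dispersion_coefficient(object$consensus)))
  co <- suppressWarnings(cophenetic_coefficient(object$consensus))
  cat(sprintf("consensus cophenetic: %.4f\n", co))
  if (!is.null(object$survey)) print(object$survey)
  invisible(object)
}

#' @export
coef.tmes_fit <- function(object, ...) {
  object$model$W
}

#' Plot a subtype fit: rank-survey coefficients and consensus heatmap
#' @param x a `tmes_fit`.
#' @param ... unused.
#' @export
plot.tmes_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$survey)) 1 else 2))
  on.exit(graphics::par(op))
  if (!is.null(x$survey)) {
    tab <- x$survey$table
    graphics::matplot(tab$k, cbind(tab$cophenetic, tab$dispersion, tab$product),
                      type = "b", pch = 1:3, lty = 1, xlab = "rank k",
                      ylab = "coefficient",
                      main = "NMF rank survey")
    graphics::legend("bottomleft", c("cophenetic", "dispersion", "product"),
                     pch = 1:3, col = 1:3, bty = "n")
    graphics::abline(v = x$survey$chosen_k, lty = 3)
  }
  ord <- order(x$assignment)
  graphics::image(x$consensus[ord, ord], axes = FALSE,
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  main = sprintf("Consensus (k = %d)", x$k))
  invisible(x)
}
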