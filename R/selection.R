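# Binary outcome for the classifier-based selectors: vital status at the
# fixed horizon = the cohort's median follow-up time. Dead by the horizon ->
# 1; still under observation at the horizon (alive then, whatever happened
# later) -> 0; censored before the horizon -> excluded (status unknown).
# The median horizon balances the classes by construction.
binary_outcome_from_survival <- function(surv) {
  validate_survival(surv)
  med <- median(surv$time)
  y <- ifelse(surv$time >= med, 0L,
              ifelse(surv$event == 1, 1L, NA_integer_))
  names(y) <- surv$sample_id
  yy <- y[!is.na(y)]
  if (length(unique(yy)) < 2) stop("binary outcome is degenerate (one class)")
  y
}

# stratified fold assignment (by a binary label), reproducible from seed
stratified_folds <- function(y, n_folds, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' LASSO-penalized Cox selection with cross-validated lambda
#'
#' Fits an L1-penalized Cox partial likelihood over a 100-point log-spaced
#' lambda path (via `glmnet`), with event-stratified 10-fold cross-validation;
#' `lambda*` minimizes the mean CV partial-likelihood deviance and the
#' selected set is the signatures with nonzero coefficients there. Scores are
#' standardized per signature before fitting.
#'
#' @param scores signatures x samples score matrix.
#' @param surv survival data.frame (needs at least `n_folds` events).
#' @param n_folds CV folds.
#' @param seed seed for fold assignment.
#' @return list with `set` (selected signature names), `lambda_min`,
#'   `cv` (data.frame lambda, mean deviance, nonzero count).
#' @export
lasso_cox_select <- function(scores, surv, n_folds = 10, seed = 1) {
  validate_scores(scores)
  surv <- align_survival(surv, colnames(scores))
  if (sum(surv$event) < n_folds) stop("need at least n_folds observed events")
  x <- t(standardize_rows(scores)$z)
  y <- cbind(time = surv$time, status = surv$event)
  foldid <- stratified_folds(surv$event, n_folds, seed)
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                             nlambda = 100, standardize = FALSE)
  cf <- as.matrix(glmnet::coef.glmnet(cvfit, s = "lambda.min"))
  set <- rownames(cf)[cf[, 1L] != 0]
  if (length(set) == 0) tme_log("LASSO selected the empty set at lambda.min")
  list(set = set, lambda_min = cvfit$lambda.min,
       cv = data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                       nzero = as.vector(cvfit$nzero)))
}

#' Random-forest selection by dual top-n importance ranking
#'
#' Trains a classification forest on the binary survival outcome (death vs
#' survival past the median follow-up; early-censored samples excluded) and
#' returns the intersection of the top-`top_n` signatures by impurity (Gini)
#' importance and by out-of-bag permutation-accuracy importance.
#'
#' @param scores signatures x samples score matrix (>= 50 usable samples).
#' @param surv survival data.frame, or pass `outcome` directly.
#' @param outcome optional named binary vector overriding the survival-derived
#'   outcome.
#' @param n_trees trees in the forest.
#' @param top_n size of each importance ranking.
#' @param seed seed.
#' @return list with `set`, `importance` (data.frame signature, gini,
#'   accuracy).
#' @export
rf_select <- function(scores, surv, outcome = NULL, n_trees = 1000,
                      top_n = 30, seed = 1) {
  validate_scores(scores)
  if (is.null(outcome)) {
    surv <- align_survival(surv, colnames(scores))
    outcome <- binary_outcome_from_survival(surv)
  }
  outcome <- outcome[!is.na(outcome)]
  keep <- intersect(colnames(scores), names(outcome))
  if (length(keep) < 50) stop("random-forest selection needs >= 50 samples")
  x <- t(scores[, keep, drop = FALSE])
  y <- factor(outcome[keep])
  if (nlevels(y) < 2) stop("binary outcome is degenerate (one class)")
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  gini <- imp[, "MeanDecreaseGini"]
  acc <- imp[, "MeanDecreaseAccuracy"]
  top_n <- min(top_n, nrow(imp))
  top_gini <- rownames(imp)[order(-gini, seq_along(gini))][seq_len(top_n)]
  top_acc <- rownames(imp)[order(-acc, seq_along(acc))][seq_len(top_n)]
  set <- rownames(scores)[rownames(scores) %in% intersect(top_gini, top_acc)]
  list(set = set,
       importance = data.frame(signature = rownames(imp), gini = gini,
                               accuracy = acc, row.names = NULL))
}

#' SVM recursive feature elimination with a one-standard-error stop
#'
#' Repeatedly trains a linear max-margin classifier (cost 1, standardized
#' inputs) on the binary survival outcome, ranks features by squared weight,
#' and removes the lowest `ceil(drop_fraction * remaining)` until one
#' remains. Each candidate set along the path is scored by stratified 5-fold
#' CV accuracy; the returned set is the smallest whose CV accuracy is within
#' one standard error of the best. Constant features are removed up front
#' with a warning.
#'
#' @param scores signatures x samples score matrix.
#' @param surv survival data.frame, or pass `outcome`.
#' @param outcome optional named binary vector.
#' @param drop_fraction fraction of remaining features removed per step.
#' @param cost SVM regularization constant.
#' @param n_folds CV folds along the path.
#' @param seed seed (fold assignment).
#' @return list with `set`, `path` (data.frame step, n_features, cv_accuracy,
#'   cv_se), `ranking` (elimination order, last survivor first).
#' @export
svm_rfe_select <- function(scores, surv, outcome = NULL, drop_fraction = 0.1,
                           cost = 1, n_folds = 5, seed = 1) {
  validate_scores(scores)
  if (is.null(outcome)) {
    surv <- align_survival(surv, colnames(scores))
    outcome <- binary_outcome_from_survival(surv)
  }
  outcome <- outcome[!is.na(outcome)]
  keep <- intersect(colnames(scores), names(outcome))
  x_all <- scores[, keep, drop = FALSE]
  y <- factor(outcome[keep])
  if (nlevels(y) < 2) stop("binary outcome is degenerate (one class)")
  sdv <- apply(x_all, 1L, sd)
  if (any(sdv == 0)) {
    warning("removing constant feature(s) before RFE: ",
            paste(rownames(x_all)[sdv == 0], collapse = ", "))
    x_all <- x_all[sdv > 0, , drop = FALSE]
  }
  z <- standardize_rows(x_all)$z
  foldid <- stratified_folds(as.integer(y) - 1L, n_folds, seed)

  cv_accuracy <- function(feats) {
    accs <- vapply(seq_len(n_folds), function(f) {
      tr <- foldid != f
      m <- e1071::svm(x = t(z[feats, tr, drop = FALSE]), y = y[tr],
                      kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(m, t(z[feats, !tr, drop = FALSE]))
      mean(pred == y[!tr])
    }, numeric(1))
    c(mean(accs), sd(accs) / sqrt(n_folds))
  }

  surviving <- rownames(z)
  elim <- character(0)
  path <- list()
  step <- 0L
  while (length(surviving) >= 1) {
    step <- step + 1L
    acc <- cv_accuracy(surviving)
    path[[step]] <- data.frame(step = step, n_features = length(surviving),
                               cv_accuracy = acc[1], cv_se = acc[2])
    attr(path[[step]], "features") <- surviving
    if (length(surviving) == 1) break
    m <- e1071::svm(x = t(z[surviving, , drop = FALSE]), y = y,
                    kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(m$coefs, m$SV)[1L, ]
    w2 <- w[surviving]^2
    n_drop <- ceiling(drop_fraction * length(surviving))
    n_drop <- min(n_drop, length(surviving) - 1L)
    # ties: drop the alphabetically-later feature first, so on full symmetry
    # the first name alphabetically is the last survivor
    ord <- order(w2, -xtfrm(names(w2)))
    drop <- names(w2)[ord][seq_len(n_drop)]
    elim <- c(elim, drop)
    surviving <- setdiff(surviving, drop)
  }
  ptab <- do.call(rbind, path)
  best <- which.max(ptab$cv_accuracy)
  thr <- ptab$cv_accuracy[best] - ptab$cv_se[best]
  ok <- which(ptab$cv_accuracy >= thr)
  pick <- ok[which.min(ptab$n_features[ok])]
  set_feats <- attr(path[[pick]], "features")
  list(set = rownames(scores)[rownames(scores) %in% set_feats],
       path = ptab,
       ranking = c(rev(attr(path[[length(path)]], "features")), rev(elim)))
}

#' Three-algorithm prognostic-signature selection ensemble
#'
#' Runs [lasso_cox_select()], [rf_select()] and [svm_rfe_select()] on the
#' same cohort and intersects the three selected sets: signatures identified
#' by all three algorithms form the consensus prognostic set.
#'
#' @param scores signatures x samples score matrix.
#' @param surv survival data.frame.
#' @param seed master seed (each selector receives a derived seed).
#' @param n_folds_lasso,n_trees,top_n,drop_fraction forwarded to the
#'   selectors.
#' @return object of class `tmes_selection`: `lasso_set`, `rf_set`,
#'   `svmrfe_set`, `intersection` (ordered by input signature order), plus
#'   per-method diagnostics.
#' @export
select_signatures <- function(scores, surv, seed = 1, n_folds_lasso = 10,
                              n_trees = 1000, top_n = 30,
                              drop_fraction = 0.1) {
  seeds <- derive_seeds(seed, 3L)
  lasso <- lasso_cox_select(scores, surv, n_folds = n_folds_lasso,
                            seed = seeds[1L])
  rf <- rf_select(scores, surv, n_trees = n_trees, top_n = top_n,
                  seed = seeds[2L])
  svm <- svm_rfe_select(scores, surv, drop_fraction = drop_fraction,
                        seed = seeds[3L])
  sel <- structure(list(lasso_set = lasso$set, rf_set = rf$set,
                        svmrfe_set = svm$set,
                        intersection = character(0),
                        diagnostics = list(lasso = lasso[c("lambda_min", "cv")],
                                           rf = rf["importance"],
                                           svmrfe = svm[c("path", "ranking")]),
                        signature_order = rownames(scores)),
                   class = "tmes_selection")
  sel$intersection <- intersect_selections(sel)
  sel
}

#' Intersection of the three selected sets
#'
#' @param result a `tmes_selection`.
#' @return character vector: signatures selected by all three methods, in
#'   input signature order.
#' @export
intersect_selections <- function(result) {
  stopifnot(inherits(result, "tmes_selection"))
  common <- Reduce(intersect,
                   list(result$lasso_set, result$rf_set, result$svmrfe_set))
  result$signature_order[result$signature_order %in% common]
}

#' @export
print.tmes_selection <- function(x, ...) {
  cat(sprintf("Signature selection ensemble: LASSO %d, RF %d, SVM-RFE %d\n",
              length(x$lasso_set), length(x$rf_set), length(x$svmrfe_set)))
  cat("three-way intersection (", length(x$intersection), "): ",
      paste(x$intersection, collapse = ", "), "\n", sep = "")
  invisible(x)
}
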