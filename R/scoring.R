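#' Score gene signatures as per-sample mean expression
#'
#' The score of a signature in a sample is the arithmetic mean of the
#' sample's expression over the signature's genes that are present in the
#' matrix. Signatures matching fewer than `min_genes_found` genes are dropped
#' (and logged).
#'
#' @param expr genes x samples expression matrix (log2 scale).
#' @param sigs named list of gene vectors.
#' @param min_genes_found minimum matched genes for a signature to be scored.
#' @return signatures x samples numeric score matrix.
#' @export
score_signatures <- function(expr, sigs, min_genes_found = 2) {
  validate_expression(expr)
  validate_signatures(sigs)
  rows <- lapply(names(sigs), function(nm) {
    found <- intersect(sigs[[nm]], rownames(expr))
    if (length(found) < min_genes_found) {
      tme_log("dropping signature '", nm, "': only ", length(found),
              " of ", length(sigs[[nm]]), " genes found")
      return(NULL)
    }
    colMeans(expr[found, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no signature matched at least ", min_genes_found, " genes")
  scores <- do.call(rbind, rows[keep])
  rownames(scores) <- names(sigs)[keep]
  validate_scores(scores)
}

#' Detect outlier samples by hierarchical clustering of score profiles
#'
#' Samples are clustered by average linkage on the distance
#' `1 - Pearson(signature-score profiles)` and cut into two clusters. If the
#' smaller cluster holds less than `max_minority_frac` of the samples *and*
#' the height at which the two clusters merge exceeds `min_separation`
#' (i.e. the minority is genuinely dissimilar, not an arbitrary split of a
#' homogeneous cohort), its members are flagged as outliers and the cut is
#' repeated once on the remainder; otherwise no outliers are reported.
#' Samples with a constant (zero-variance) score profile are flagged
#' directly, since their correlation to anything is undefined.
#'
#' @param scores signatures x samples score matrix (>= 10 samples).
#' @param max_minority_frac minority-cluster fraction below which the cluster
#'   is declared outlying.
#' @param min_separation minimum root merge height (on the `1 - cor` scale)
#'   for the minority to count as outlying.
#' @return character vector of outlier sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(scores, max_minority_frac = 0.02,
                                   min_separation = 0.5) {
  validate_scores(scores)
  if (ncol(scores) < 10) stop("outlier detection needs at least 10 samples")
  sdv <- apply(scores, 2L, sd)
  flat <- colnames(scores)[sdv == 0]
  if (length(flat)) {
    tme_log("flagging ", length(flat), " constant-profile sample(s) as outliers")
  }
  remaining <- setdiff(colnames(scores), flat)
  outliers <- flat
  for (pass in 1:2) {
    if (length(remaining) < 10) break
    cc <- cor(scores[, remaining, drop = FALSE])
    hc <- hclust(as.dist(1 - cc), method = "average")
    cl <- cutree(hc, k = 2)
    sizes <- table(cl)
    minority <- names(sizes)[which.min(sizes)]
    if (min(sizes) >= max_minority_frac * length(remaining) ||
        max(hc$height) <= min_separation) break
    bad <- remaining[cl == as.integer(minority)]
    outliers <- c(outliers, bad)
    remaining <- setdiff(remaining, bad)
  }
  outliers
}

#' Filter signatures by their strongest pairwise correlation
#'
#' A signature is retained iff the maximum over other signatures of the
#' absolute Pearson correlation of its scores is at least `min_abs_cor`.
#' Zero-variance signatures correlate with nothing (treated as 0, logged).
#' Input order is preserved; lowering the threshold retains a superset.
#'
#' @param scores signatures x samples score matrix (>= 2 signatures).
#' @param min_abs_cor retention threshold on `max |cor|`.
#' @return character vector of retained signature names.
#' @export
filter_signatures_by_correlation <- function(scores, min_abs_cor = 0.3) {
  validate_scores(scores)
  if (nrow(scores) < 2) stop("correlation filter needs at least 2 signatures")
  sdv <- apply(scores, 1L, sd)
  if (any(sdv == 0)) {
    tme_log("zero-variance signature(s) treated as uncorrelated: ",
            paste(rownames(scores)[sdv == 0], collapse = ", "))
  }
  cc <- suppressWarnings(cor(t(scores)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  keep <- apply(abs(cc), 1L, max) >= min_abs_cor
  rownames(scores)[keep]
}

#' Univariate Cox screen of signatures against overall survival
#'
#' Each signature's scores are standardized (mean 0, SD 1) and fit in a
#' univariate Cox proportional-hazards model (Newton maximization of the
#' Breslow partial likelihood). A signature is `protective` if HR < 1 with
#' p < `alpha`, `unfavorable` if HR > 1 with p < `alpha`, otherwise
#' `neutral`. Zero-variance or non-convergent signatures are neutral (HR 1),
#' with a logged warning.
#'
#' @param scores signatures x samples score matrix.
#' @param surv survival data.frame (>= 2 events).
#' @param alpha significance level for the direction call.
#' @return object of class `cox_screen`: data.frame with signature,
#'   hazard_ratio, ci_low, ci_high, p_value, direction.
#' @export
cox_screen <- function(scores, surv, alpha = 0.05) {
  validate_scores(scores)
  surv <- align_survival(surv, colnames(scores))
  if (sum(surv$event) < 2) stop("Cox screen needs at least 2 observed events")
  rows <- lapply(rownames(scores), function(nm) {
    x <- scores[nm, ]
    if (sd(x) == 0) {
      tme_log("zero-variance signature '", nm, "': neutral")
      return(data.frame(signature = nm, hazard_ratio = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = 1,
                        direction = "neutral", stringsAsFactors = FALSE))
    }
    z <- (x - mean(x)) / sd(x)
    fit <- cox_fit_newton(z, surv$time, surv$event)
    if (!fit$converged || fit$degenerate) {
      tme_log("Cox fit for '", nm, "' did not converge: neutral")
      return(data.frame(signature = nm, hazard_ratio = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = 1,
                        direction = "neutral", stringsAsFactors = FALSE))
    }
    ci <- exp(fit$beta + c(-1, 1) * qnorm(0.975) * fit$se)
    hr <- exp(fit$beta)
    dir <- if (fit$p < alpha && hr < 1) "protective"
           else if (fit$p < alpha && hr > 1) "unfavorable" else "neutral"
    data.frame(signature = nm, hazard_ratio = hr, ci_low = ci[1],
               ci_high = ci[2], p_value = fit$p, direction = dir,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("cox_screen", "data.frame"))
}

#' @export
print.cox_screen <- function(x, ...) {
  cat(sprintf("Cox screen of %d signatures: %d protective, %d unfavorable, %d neutral\n",
              nrow(x), sum(x$direction == "protective"),
              sum(x$direction == "unfavorable"), sum(x$direction == "neutral")))
  NextMethod()
}
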