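#' Subtype centroids from a labeled training cohort
#'
#' Scores are z-scored per signature over the training cohort; the centroid
#' of a subtype is the mean z-profile of its samples. The training
#' standardization parameters are stored with the centroids.
#'
#' @param scores signatures x samples score matrix.
#' @param labels named character vector sample -> subtype (every subtype must
#'   have >= 2 samples).
#' @return object of class `subtype_centroids`: `centroids` (subtypes x
#'   signatures), `mean`, `sd` (training standardization per signature).
#' @export
compute_centroids <- function(scores, labels) {
  validate_scores(scores)
  labels <- validate_assignment(labels)
  common <- intersect(colnames(scores), names(labels))
  if (length(common) < 4) stop("too few labeled samples")
  scores <- scores[, common, drop = FALSE]
  labels <- labels[common]
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("singleton subtype(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  st <- standardize_rows(scores)
  cent <- t(vapply(sort(names(sizes)), function(l) {
    rowMeans(st$z[, labels == l, drop = FALSE])
  }, numeric(nrow(scores))))
  structure(list(centroids = cent, mean = st$mean, sd = st$sd),
            class = "subtype_centroids")
}

#' @export
print.subtype_centroids <- function(x, ...) {
  cat(sprintf("Subtype centroids: %d subtypes x %d signatures\n",
              nrow(x$centroids), ncol(x$centroids)))
  invisible(x)
}

#' Assign subtypes to a new cohort by nearest-centroid correlation
#'
#' The new cohort's scores are z-scored per signature within itself
#' (cohort-wise standardization, which makes the projection invariant to any
#' per-signature affine rescaling, e.g. platform shifts between microarray
#' and RNA-seq), and each sample is assigned the centroid with the highest
#' Pearson correlation over the shared signatures (ties to the smallest
#' subtype index). The per-sample best correlation is returned for QC.
#'
#' @param new_scores signatures x samples score matrix of the new cohort.
#' @param centroids a `subtype_centroids` object.
#' @param min_overlap minimum fraction of centroid signatures that must be
#'   present (and non-degenerate) in the new cohort.
#' @return list with `assignment` (named labels), `correlation` (named
#'   per-sample best correlation), `correlations` (samples x subtypes).
#' @export
assign_subtype <- function(new_scores, centroids, min_overlap = 0.8) {
  validate_scores(new_scores)
  stopifnot(inherits(centroids, "subtype_centroids"))
  sig_all <- colnames(centroids$centroids)
  shared <- intersect(sig_all, rownames(new_scores))
  sdv <- apply(new_scores[shared, , drop = FALSE], 1L, sd)
  if (any(sdv == 0)) {
    tme_log("dropping zero-variance signature(s) in new cohort: ",
            paste(shared[sdv == 0], collapse = ", "))
    shared <- shared[sdv > 0]
  }
  if (length(shared) < min_overlap * length(sig_all)) {
    stop("only ", length(shared), "/", length(sig_all),
         " centroid signatures usable in the new cohort; missing: ",
         paste(head(setdiff(sig_all, shared), 10L), collapse = ", "))
  }
  z <- standardize_rows(new_scores[shared, , drop = FALSE])$z
  cent <- centroids$centroids[, shared, drop = FALSE]
  cors <- cor(z, t(cent))                # samples x subtypes
  idx <- apply(cors, 1L, which.max)      # first (smallest index) on ties
  assignment <- setNames(rownames(cent)[idx], colnames(new_scores))
  best <- cors[cbind(seq_len(nrow(cors)), idx)]
  list(assignment = assignment,
       correlation = setNames(best, colnames(new_scores)),
       correlations = cors)
}

#' Project a fitted subtype model onto a new cohort
#'
#' @param object a `tmes_fit`.
#' @param newdata signatures x samples score matrix of the new cohort.
#' @param min_overlap forwarded to [assign_subtype()].
#' @param ... unused.
#' @return as [assign_subtype()].
#' @export
predict.tmes_fit <- function(object, newdata, min_overlap = 0.8, ...) {
  assign_subtype(newdata, object$centroids, min_overlap = min_overlap)
}
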