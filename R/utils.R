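#' Derive reproducible child seeds from a master seed
#'
#' Every stochastic stage in the package receives an explicit seed derived
#' deterministically from one master seed, so a whole pipeline run is
#' replayable from a single integer.
#'
#' @param seed master integer seed.
#' @param n number of child seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max, n, replace = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

# Lightweight logging: messages routed through one hook so pipeline runs can
# capture them. Suppress with options(tmesuite.quiet = TRUE).
tme_log <- function(...) {
  if (!isTRUE(getOption("tmesuite.quiet", FALSE))) {
    message("[tmesuite] ", ...)
  }
  invisible(NULL)
}

# --- validators for the core containers -------------------------------------

# genes x samples numeric matrix with unique, non-empty dimnames
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes x samples)")
  }
  if (nrow(expr) == 0L || ncol(expr) == 0L) stop("expression matrix is empty")
  g <- rownames(expr); s <- colnames(expr)
  if (is.null(g) || is.null(s)) stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(g)) stop("duplicated gene symbols in expression matrix")
  if (anyDuplicated(s)) stop("duplicated sample ids in expression matrix")
  if (any(!nzchar(g))) stop("empty gene symbol in expression matrix")
  if (!all(is.finite(expr))) stop("non-finite values in expression matrix")
  invisible(expr)
}

# named list of unique, non-empty character vectors
validate_signatures <- function(sigs) {
  if (!is.list(sigs) || is.null(names(sigs))) stop("signatures must be a named list")
  if (anyDuplicated(names(sigs))) stop("duplicated signature names")
  for (nm in names(sigs)) {
    g <- sigs[[nm]]
    if (!is.character(g) || length(g) == 0L) {
      stop("signature '", nm, "' is empty or not a character vector")
    }
    if (anyDuplicated(g)) stop("signature '", nm, "' contains duplicated genes")
  }
  invisible(sigs)
}

# data.frame with sample_id, time (months, >= 0), event (0/1)
validate_survival <- function(surv) {
  if (!is.data.frame(surv)) stop("survival table must be a data.frame")
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(surv))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(surv$sample_id)) stop("duplicated sample_id in survival table")
  if (any(!is.finite(surv$time)) || any(surv$time < 0)) {
    stop("survival time must be finite and >= 0")
  }
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  invisible(surv)
}

# signatures x samples score matrix
validate_scores <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("scores must be a numeric matrix (signatures x samples)")
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("score matrix needs signature rownames and sample colnames")
  }
  if (!all(is.finite(scores))) stop("non-finite values in score matrix")
  invisible(scores)
}

# subtype/cluster assignment: named character (or factor) vector
validate_assignment <- function(labels) {
  if (is.factor(labels)) labels <- setNames(as.character(labels), names(labels))
  if (!is.character(labels) || is.null(names(labels))) {
    stop("assignment must be a named character vector (sample -> label)")
  }
  if (anyDuplicated(names(labels))) stop("duplicated sample ids in assignment")
  labels
}

# match a survival table to a set of sample ids, preserving id order
align_survival <- function(surv, sample_ids) {
  validate_survival(surv)
  idx <- match(sample_ids, surv$sample_id)
  if (anyNA(idx)) {
    stop("survival table is missing samples: ",
         paste(head(sample_ids[is.na(idx)], 5L), collapse = ", "))
  }
  surv[idx, , drop = FALSE]
}

# row-wise z-scoring of a signatures x samples matrix; errors on zero variance
standardize_rows <- function(m, what = "signature") {
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, sd)
  if (any(sdv == 0)) {
    stop("zero-variance ", what, "(s): ",
         paste(head(rownames(m)[sdv == 0], 5L), collapse = ", "))
  }
  list(z = (m - mu) / sdv, mean = mu, sd = sdv)
}
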