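#' Kaplan-Meier product-limit curves per group
#'
#' Computes the product-limit estimator for each group of samples. Censored
#' times reduce the risk set without producing a step; at equal times events
#' precede censorings, so a subject censored at an event time is still at
#' risk for that event.
#'
#' @param surv survival data.frame (sample_id, time, event).
#' @param groups named character vector sample -> group label, or `NULL` for
#'   a single pooled curve.
#' @return object of class `km_curves`: named list of data.frames with
#'   columns `time`, `n_risk`, `n_event`, `surv` (rows at observed event
#'   times only).
#' @export
km_estimate <- function(surv, groups = NULL) {
  validate_survival(surv)
  if (is.null(groups)) {
    groups <- setNames(rep("all", nrow(surv)), surv$sample_id)
  }
  groups <- validate_assignment(groups)
  surv <- align_survival(surv, names(groups))
  out <- lapply(split(seq_len(nrow(surv)), groups), function(idx) {
    tm <- surv$time[idx]; ev <- surv$event[idx]
    if (sum(ev) == 0) {
      tme_log("group with zero events: flat survival curve")
      return(data.frame(time = numeric(0), n_risk = integer(0),
                        n_event = integer(0), surv = numeric(0)))
    }
    tt <- sort(unique(tm[ev == 1]))
    n_risk <- vapply(tt, function(t) sum(tm >= t), numeric(1))
    n_event <- vapply(tt, function(t) sum(tm == t & ev == 1), numeric(1))
    data.frame(time = tt, n_risk = n_risk, n_event = n_event,
               surv = cumprod(1 - n_event / n_risk))
  })
  structure(out, class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  cat("Kaplan-Meier curves for", length(x), "group(s)\n")
  for (g in names(x)) {
    k <- x[[g]]
    if (nrow(k) == 0) {
      cat(sprintf("  %s: no events (S = 1 throughout)\n", g))
    } else {
      cat(sprintf("  %s: %d event times, median survival %.3g\n", g, nrow(k),
                  if (any(k$surv <= 0.5)) k$time[which(k$surv <= 0.5)[1]] else NA))
    }
  }
  invisible(x)
}

#' K-sample log-rank test
#'
#' Standard log-rank chi-square over the pooled event times: per group the
#' observed minus expected event counts under the hypergeometric null, with
#' the full variance-covariance matrix; the statistic is
#' `U' V^{-1} U` on the first K-1 groups with K-1 degrees of freedom.
#'
#' @param surv survival data.frame.
#' @param groups named character vector sample -> group label (>= 2 groups).
#' @return object of class `logrank_test`: `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` per group.
#' @export
logrank_test <- function(surv, groups) {
  groups <- validate_assignment(groups)
  surv <- align_survival(surv, names(groups))
  if (sum(surv$event) < 1) stop("log-rank test needs at least one event")
  g <- factor(groups)
  K <- nlevels(g)
  if (K < 2) stop("log-rank test needs at least 2 groups")
  tm <- surv$time; ev <- surv$event
  tt <- sort(unique(tm[ev == 1]))
  O <- E <- setNames(numeric(K), levels(g))
  V <- matrix(0, K, K)
  for (t in tt) {
    at_risk <- tm >= t
    n <- sum(at_risk)
    d <- sum(tm == t & ev == 1)
    nk <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    dk <- vapply(levels(g), function(l) sum(tm == t & ev == 1 & g == l),
                 numeric(1))
    O <- O + dk
    E <- E + d * nk / n
    if (n > 1) {
      # hypergeometric covariance of event counts at this time
      V <- V + d * (n - d) / (n - 1) *
        (diag(nk / n, K) - tcrossprod(nk / n))
    }
  }
  U <- (O - E)[-K]
  Vm <- V[-K, -K, drop = FALSE]
  chi <- tryCatch(as.numeric(t(U) %*% solve(Vm, U)),
                  error = function(e) {
                    as.numeric(t(U) %*% MASS_ginv(Vm) %*% U)
                  })
  df <- K - 1L
  structure(list(chi_square = chi, df = df,
                 p_value = pchisq(chi, df, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank_test")
}

# Moore-Penrose pseudoinverse via SVD (for a singular log-rank variance
# matrix, e.g. a group whose risk set never overlaps an event time).
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.3g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Maximally selected log-rank cutpoint for a continuous covariate
#'
#' Evaluates every distinct value of `x` inside the quantile band as a
#' dichotomizing threshold (high = `x > cutpoint`), computes the two-group
#' log-rank statistic for each, and returns the maximizing cutpoint (ties
#' resolved to the lower cutpoint). The reported p-value is the naive
#' log-rank p at the chosen cutpoint and is not adjusted for the selection
#' over candidate thresholds; a warning is logged to that effect.
#'
#' @param x per-sample numeric covariate, named by sample id.
#' @param surv survival data.frame.
#' @param quantile_band numeric length-2: candidate cutpoints are restricted
#'   to values of `x` within these quantiles.
#' @return object of class `tme_cutpoint`: `cutpoint`, `assignment` (named
#'   "high"/"low"), `logrank` (a `logrank_test`), `candidates` (data.frame of
#'   cutpoint and chi-square).
#' @export
optimal_cutpoint <- function(x, surv, quantile_band = c(0.1, 0.9)) {
  if (is.null(names(x))) stop("x must be named by sample id")
  if (length(x) < 20) stop("optimal_cutpoint needs at least 20 samples")
  surv <- align_survival(surv, names(x))
  qs <- quantile(x, quantile_band, names = FALSE)
  cand <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
  # a threshold must leave both sides non-empty
  cand <- cand[cand < max(x)]
  if (length(cand) < 2) stop("fewer than 2 distinct candidate cutpoints in band")
  chi <- vapply(cand, function(ct) {
    grp <- setNames(ifelse(x > ct, "high", "low"), names(x))
    logrank_test(surv, grp)$chi_square
  }, numeric(1))
  best <- cand[which.max(chi)]   # which.max -> first (lowest) on ties
  grp <- setNames(ifelse(x > best, "high", "low"), names(x))
  lr <- logrank_test(surv, grp)
  tme_log("cutpoint p-value is the naive log-rank p, not adjusted for ",
          "threshold selection")
  structure(list(cutpoint = best, assignment = grp, logrank = lr,
                 candidates = data.frame(cutpoint = cand, chi_square = chi)),
            class = "tme_cutpoint")
}

#' @export
print.tme_cutpoint <- function(x, ...) {
  cat(sprintf("Maximally selected cutpoint: %.4g (high: n = %d, low: n = %d)\n",
              x$cutpoint, sum(x$assignment == "high"),
              sum(x$assignment == "low")))
  cat(sprintf("  log-rank chi-square %.4g, naive p = %.3g (selection-unadjusted)\n",
              x$logrank$chi_square, x$logrank$p_value))
  invisible(x)
}
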