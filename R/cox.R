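# Univariate Cox proportional-hazards fit: Newton maximization of the Breslow
# partial likelihood. Ties handled by the Breslow approximation; at equal
# times events precede censorings (censored subjects stay in the risk set for
# an event at the same time). Single covariate only -- the screening use case.
cox_fit_newton <- function(x, time, event, max_iter = 100, tol = 1e-9) {
  stopifnot(length(x) == length(time), length(time) == length(event))
  keep <- is.finite(x) & is.finite(time)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  n <- length(x)
  if (sum(event) < 1 || n < 2 || var(x) == 0) {
    return(list(beta = 0, se = NA_real_, p = 1, converged = TRUE,
                degenerate = TRUE))
  }
  ord <- order(time)            # risk set at t = {i : time_i >= t}
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  tt <- unique(time)            # sorted unique times (level order below)
  ft <- factor(time, levels = tt)
  d_all <- as.vector(rowsum(as.numeric(event), ft))   # events per unique time
  dx_all <- as.vector(rowsum(x * event, ft))
  first_all <- match(tt, time)  # first subject index at risk at each time
  ev <- d_all > 0
  d <- d_all[ev]; dsum_x <- dx_all[ev]; first <- first_all[ev]

  # Breslow partial log-likelihood, gradient, information for scalar beta
  deriv <- function(beta) {
    r <- exp(beta * x)
    # reverse cumulative sums: S0(t) = sum_{time >= t} r, similarly S1, S2
    s0 <- rev(cumsum(rev(r)))
    s1 <- rev(cumsum(rev(r * x)))
    s2 <- rev(cumsum(rev(r * x^2)))
    ll <- sum(dsum_x * beta - d * log(s0[first]))
    grad <- sum(dsum_x - d * s1[first] / s0[first])
    info <- sum(d * (s2[first] / s0[first] - (s1[first] / s0[first])^2))
    list(ll = ll, grad = grad, info = info)
  }

  beta <- 0
  d0 <- deriv(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (d0$info <= 0) break
    step <- d0$grad / d0$info
    # step halving if the likelihood would decrease or beta runs away
    new_beta <- beta + step
    d1 <- deriv(new_beta)
    h <- 0
    while ((!is.finite(d1$ll) || d1$ll < d0$ll) && h < 30) {
      step <- step / 2
      new_beta <- beta + step
      d1 <- deriv(new_beta)
      h <- h + 1
    }
    if (abs(new_beta - beta) < tol * (abs(beta) + tol)) {
      beta <- new_beta; d0 <- d1; converged <- TRUE; break
    }
    beta <- new_beta; d0 <- d1
    if (abs(beta) > 50) break   # monotone likelihood / separation
  }
  se <- if (d0$info > 0) 1 / sqrt(d0$info) else NA_real_
  p <- if (is.finite(se)) 2 * pnorm(-abs(beta / se)) else NA_real_
  list(beta = beta, se = se, p = p, converged = converged, degenerate = FALSE)
}

#' Univariate Cox proportional-hazards regression
#'
#' Fits a single-covariate Cox model by Newton maximization of the Breslow
#' partial likelihood and returns the log hazard ratio with Wald 95%
#' confidence interval and p-value. A zero-variance covariate yields log
#' HR 0 (neutral).
#'
#' @param x per-sample numeric covariate, named by sample id (names optional
#'   if `surv` rows align with `x`).
#' @param surv survival data.frame (sample_id, time, event).
#' @param conf_level confidence level for the Wald interval.
#' @return object of class `tme_cox`: list with `log_hr`, `hr`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `converged`, `n`, `n_events`.
#' @export
cox_univariate <- function(x, surv, conf_level = 0.95) {
  validate_survival(surv)
  if (!is.null(names(x))) {
    surv <- align_survival(surv, names(x))
  } else if (length(x) != nrow(surv)) {
    stop("x and survival table lengths differ and x is unnamed")
  }
  if (sum(surv$event) < 2) stop("need at least 2 observed events")
  fit <- cox_fit_newton(x, surv$time, surv$event)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.finite(fit$se)) fit$beta + c(-1, 1) * zq * fit$se else c(NA, NA)
  structure(list(log_hr = fit$beta, hr = exp(fit$beta), se = fit$se,
                 ci_low = exp(ci[1]), ci_high = exp(ci[2]),
                 p_value = fit$p, converged = fit$converged,
                 n = nrow(surv), n_events = sum(surv$event)),
            class = "tme_cox")
}

#' @export
print.tme_cox <- function(x, ...) {
  cat(sprintf("Univariate Cox fit (n = %d, events = %d)\n", x$n, x$n_events))
  cat(sprintf("  HR %.4g (95%% CI %.4g-%.4g), log HR %.4g, p = %.3g\n",
              x$hr, x$ci_low, x$ci_high, x$log_hr, x$p_value))
  if (!x$converged) cat("  warning: Newton iteration did not converge\n")
  invisible(x)
}
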