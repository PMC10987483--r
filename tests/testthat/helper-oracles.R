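# Independent brute-force oracles used across tests. These deliberately avoid
# the package's implementation paths (and stats::hclust/cophenetic) so that
# agreement is a genuine two-route check.

# Consensus matrix by direct double loop over sample pairs and runs.
oracle_consensus <- function(labelings) {
  ids <- names(labelings[[1]])
  n <- length(ids)
  C <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- mean(vapply(labelings,
                             function(l) l[[ids[i]]] == l[[ids[j]]],
                             logical(1)))
    }
  }
  C
}

# Naive average-linkage agglomeration on a distance matrix; returns the
# cophenetic distance matrix (merge height at which two points first join).
oracle_cophenetic_dist <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  cd <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  repeat {
    idx <- which(active)
    if (length(idx) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        ca <- clusters[[idx[a]]]; cb <- clusters[[idx[b]]]
        d <- mean(D[ca, cb])                 # average linkage
        if (d < best_d) { best_d <- d; best <- c(idx[a], idx[b]) }
      }
    }
    ca <- clusters[[best[1]]]; cb <- clusters[[best[2]]]
    cd[ca, cb] <- best_d; cd[cb, ca] <- best_d
    clusters[[best[1]]] <- c(ca, cb)
    active[best[2]] <- FALSE
  }
  cd
}

oracle_cophenetic_coefficient <- function(C) {
  D <- 1 - C
  cd <- oracle_cophenetic_dist(D)
  ut <- upper.tri(D)
  cor(D[ut], cd[ut])
}

# K-sample log-rank by direct observed/expected/variance summation over the
# pooled event times (loop-per-subject, no vectorized shortcuts).
oracle_logrank_chisq <- function(time, event, group) {
  g <- sort(unique(group))
  K <- length(g)
  O <- E <- rep(0, K)
  V <- matrix(0, K, K)
  for (t in sort(unique(time[event == 1]))) {
    n <- 0; d <- 0
    nk <- dk <- rep(0, K)
    for (i in seq_along(time)) {
      if (time[i] >= t) {
        n <- n + 1
        ki <- match(group[i], g)
        nk[ki] <- nk[ki] + 1
        if (time[i] == t && event[i] == 1) {
          d <- d + 1
          dk[ki] <- dk[ki] + 1
        }
      }
    }
    O <- O + dk
    E <- E + d * nk / n
    if (n > 1) {
      for (a in seq_len(K)) {
        for (b in seq_len(K)) {
          V[a, b] <- V[a, b] + d * (n - d) / (n - 1) *
            (as.numeric(a == b) * nk[a] / n - nk[a] * nk[b] / n^2)
        }
      }
    }
  }
  U <- (O - E)[-K]
  as.numeric(t(U) %*% solve(V[-K, -K, drop = FALSE], U))
}

# Kaplan-Meier product-limit by hand for one group.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = tt, surv = out)
}

# Rank-1 KL NMF optimum: the independence model (row sums x col sums / total)
# minimizes generalized KL among rank-1 non-negative factorizations.
oracle_rank1_kl <- function(V) {
  WH <- outer(rowSums(V), colSums(V)) / sum(V)
  sum(ifelse(V > 0, V * log(V / WH), 0) - V + WH)
}

kl_div <- function(V, WH) {
  sum(ifelse(V > 0, V * log(V / WH), 0) - V + WH)
}

# Adjusted Rand index via mclust (independent of the package).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# A small separable scored cohort used by several tests.
small_cohort <- function(seed = 1, k_true = 3, n_per = 15, n_sig = 9,
                         effect = 3, noise = 0.5) {
  co <- gen_bulk_cohort(bulk_sim_config(
    k_true = k_true, n_per_subtype = n_per, n_signatures = n_sig,
    genes_per_signature = 5, effect_size = effect, noise_sd = noise,
    seed = seed))
  co$scores <- score_signatures(co$expr, co$signatures)
  co
}
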