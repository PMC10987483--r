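test_that("KL objective is non-increasing at every multiplicative update", {
  set.seed(21)
  for (r in 1:5) {
    V <- matrix(runif(20 * 12, 0.1, 5), 20, 12)
    m <- nmf_run(V, k = 3, seed = r, obj_every = 1)
    expect_true(all(diff(m$objective_trace) <= 1e-8 * abs(m$objective_trace[-1])))
  }
})

test_that("a planted exact factorization is recovered to near-zero divergence", {
  set.seed(22)
  W0 <- matrix(runif(15 * 3), 15, 3)
  H0 <- matrix(runif(3 * 10), 3, 10)
  V <- W0 %*% H0
  m <- nmf_run(V, k = 3, seed = 1, max_iter = 5000, tol = 1e-12)
  expect_lt(m$objective, 1e-4 * sum(V))
})

test_that("rank-1 fits attain the closed-form KL optimum (independence model)", {
  set.seed(23)
  V <- matrix(runif(8 * 6, 0.5, 4), 8, 6)
  m <- nmf_run(V, k = 1, seed = 2, max_iter = 5000, tol = 1e-12)
  expect_equal(m$objective, oracle_rank1_kl(V), tolerance = 1e-6)
  # W proportional to row sums
  expect_equal(m$W[, 1] / sum(m$W[, 1]), rowSums(V) / sum(V), tolerance = 1e-4)
})

test_that("nmf_run enforces input contracts", {
  V <- matrix(runif(12), 4, 3)
  Vneg <- V; Vneg[1, 1] <- -1
  expect_error(nmf_run(Vneg, 2), "negative")
  Vzero <- V; Vzero[2, ] <- 0
  rownames(Vzero) <- letters[1:4]
  expect_error(nmf_run(Vzero, 2), "b")
})

test_that("labels come from scaled-H argmax with smallest-index ties and size ordering", {
  m <- structure(list(W = matrix(1, 2, 2),
                      H = matrix(c(0.9, 0.1,   # -> factor 1
                                   0.5, 0.5,   # tie -> factor 1
                                   0.2, 0.8,   # -> factor 2
                                   0.1, 0.9,
                                   0.3, 0.7),
                                 nrow = 2,
                                 dimnames = list(NULL, sprintf("s%d", 1:5))),
                      k = 2L),
                 class = "nmf_model")
  lab <- run_labels(m)
  # factor 2 holds 3 samples -> becomes TMES1 after size ordering
  expect_identical(unname(lab), c("TMES2", "TMES2", "TMES1", "TMES1", "TMES1"))
  m$H[, 3] <- 0
  expect_error(run_labels(m), "all-zero H column")
})

test_that("consensus matrix equals the brute-force co-clustering fraction", {
  labs <- list(c(a = "x", b = "x", c = "y", d = "y"),
               c(a = "x", b = "y", c = "y", d = "y"),
               c(a = "z", b = "z", c = "z", d = "y"))
  C <- consensus_from_runs(labs)
  expect_equal(C, oracle_consensus(labs))
  expect_true(all(diag(C) == 1))
  expect_equal(C, t(C))
  # 2 runs, together in exactly 1 -> 0.5
  C2 <- consensus_from_runs(labs[1:2])
  expect_equal(C2["a", "b"], 0.5)
  expect_error(consensus_from_runs(list(labs[[1]], c(a = "x", q = "y"))),
               "different sample sets")
})

test_that("identical runs give a binary consensus; random labels hover at 1/k", {
  lab <- c(a = "1", b = "1", c = "2", d = "2", e = "2")
  C <- consensus_from_runs(list(lab, lab, lab))
  expect_true(all(C %in% c(0, 1)))
  set.seed(24)
  rand <- lapply(1:400, function(i) {
    setNames(sample(c("1", "2"), 8, replace = TRUE), letters[1:8])
  })
  Cr <- consensus_from_runs(rand)
  off <- Cr[upper.tri(Cr)]
  expect_lt(max(abs(off - 0.5)), 0.12)   # binomial fluctuation around 1/2
})

test_that("cophenetic coefficient matches a brute-force agglomeration oracle", {
  set.seed(25)
  for (r in 1:5) {
    n <- sample(6:12, 1)
    M <- matrix(runif(n * n), n, n)
    C <- (M + t(M)) / 2
    diag(C) <- 1
    dimnames(C) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
    expect_equal(cophenetic_coefficient(C), oracle_cophenetic_coefficient(C),
                 tolerance = 1e-10)
  }
})

test_that("cophenetic is 1 on block consensus and NaN on degenerate consensus", {
  C <- matrix(0, 6, 6); C[1:3, 1:3] <- 1; C[4:6, 4:6] <- 1
  dimnames(C) <- list(letters[1:6], letters[1:6])
  expect_equal(cophenetic_coefficient(C), 1)
  I <- diag(5)
  dimnames(I) <- list(letters[1:5], letters[1:5])
  expect_warning(v <- cophenetic_coefficient(I), "undefined")
  expect_true(is.nan(v))
})

test_that("dispersion follows the hand formula and its bounds", {
  expect_equal(dispersion_coefficient(matrix(c(1, 0.5, 0.5, 1), 2, 2)), 0.5)
  C <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3, 3)
  expect_equal(dispersion_coefficient(C), 1)
  set.seed(26)
  M <- matrix(runif(49), 7, 7); C <- (M + t(M)) / 2; diag(C) <- 1
  d <- dispersion_coefficient(C)
  expect_gte(d, 0); expect_lte(d, 1)
})

test_that("rank survey recovers the planted number of subtypes", {
  co <- small_cohort(seed = 27, k_true = 4, n_per = 20, n_sig = 12,
                     effect = 3, noise = 0.5)
  rs <- rank_survey(co$scores, k_range = 3:6, n_runs = 15, seed = 5)
  expect_equal(rs$chosen_k, 4)
  expect_gt(rs$table$cophenetic[rs$table$k == 4], 0.99)
})

test_that("zero-noise cohorts give crisp consensus at the true rank, k in 3..5", {
  for (k_true in 3:5) {
    co <- gen_bulk_cohort(bulk_sim_config(
      k_true = k_true, n_per_subtype = 8, n_signatures = 3 * k_true,
      genes_per_signature = 3, effect_size = 3, noise_sd = 0,
      seed = 30 + k_true))
    sc <- score_signatures(co$expr, co$signatures)
    rs <- rank_survey(sc, k_range = 3:6, n_runs = 10, seed = k_true)
    expect_equal(rs$chosen_k, k_true)
    coph <- rs$table$cophenetic[rs$table$k == k_true]
    if (k_true <= 4) {
      expect_lt(abs(coph - 1), 1e-9)
    } else {
      # at k = 5 an occasional restart lands in a local KL optimum, leaving
      # the consensus crisp but not perfectly binary
      expect_gt(coph, 0.995)
    }
  }
})

test_that("final subtypes recover planted blocks and are seed-deterministic", {
  co <- small_cohort(seed = 28, k_true = 3, n_per = 20, n_sig = 9)
  fin1 <- final_subtypes(co$scores, k = 3, n_runs = 30, seed = 2)
  fin2 <- final_subtypes(co$scores, k = 3, n_runs = 30, seed = 2)
  expect_identical(fin1$assignment, fin2$assignment)
  expect_gte(ari(fin1$assignment, co$truth$subtype), 0.99)
  # consensus is crisper than a shuffled-label consensus of the same data
  set.seed(29)
  shuffled <- lapply(1:30, function(i) {
    setNames(sample(fin1$assignment), names(fin1$assignment))
  })
  expect_gt(dispersion_coefficient(fin1$consensus),
            dispersion_coefficient(consensus_from_runs(shuffled)))
})

test_that("subtype labels are invariant to sample permutation of the input", {
  co <- small_cohort(seed = 33, k_true = 3, n_per = 12, n_sig = 9)
  fit1 <- final_subtypes(co$scores, k = 3, n_runs = 10, seed = 4)
  set.seed(35)
  perm <- sample(colnames(co$scores))
  fit2 <- final_subtypes(co$scores[, perm], k = 3, n_runs = 10, seed = 4)
  # same partition up to the deterministic size-ordered relabeling
  expect_gte(ari(fit1$assignment[perm], fit2$assignment[perm]), 0.99)
})

test_that("tmes_fit wraps survey, final fit, centroids and predict", {
  co <- small_cohort(seed = 34, k_true = 3, n_per = 15, n_sig = 9)
  fit <- tmes_fit(co$scores, k_range = 2:4, n_runs_survey = 8,
                  n_runs_final = 15, seed = 6)
  expect_s3_class(fit, "tmes_fit")
  expect_equal(fit$k, 3L)
  expect_gte(ari(fit$assignment, co$truth$subtype), 0.99)
  pr <- predict(fit, co$scores)
  expect_gte(mean(pr$assignment == fit$assignment), 0.9)
  expect_identical(dim(coef(fit)), c(nrow(co$scores), 3L))
})
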