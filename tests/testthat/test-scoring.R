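test_that("signature scores are means over matched genes, with drop threshold", {
  expr <- matrix(c(2, 4, 6, 1, 3, 5), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  sigs <- list(full = c("A", "B"),          # both present: mean(2,4) = 3
               partial = c("A", "B", "ZZZ"),# missing gene ignored
               thin = c("C", "MISSING"))    # only 1 matched -> dropped
  sc <- suppressMessages(score_signatures(expr, sigs, min_genes_found = 2))
  expect_identical(rownames(sc), c("full", "partial"))
  expect_equal(unname(sc["full", "s1"]), 3)
  expect_equal(unname(sc["partial", ]), unname(colMeans(expr[c("A", "B"), ])))
  expect_error(score_signatures(expr, list(x = "nope")), "no signature matched")
})

test_that("scoring is sample-permutation equivariant and gene-order invariant", {
  co <- small_cohort(seed = 2, n_per = 8)
  perm <- sample(colnames(co$expr))
  sc1 <- score_signatures(co$expr, co$signatures)
  sc2 <- score_signatures(co$expr[, perm], co$signatures)
  expect_equal(sc2, sc1[, perm])
  sc3 <- score_signatures(co$expr[rev(rownames(co$expr)), ], co$signatures)
  expect_equal(sc3, sc1)
})

test_that("planted outlier samples are recovered exactly", {
  co <- small_cohort(seed = 4, k_true = 2, n_per = 200, n_sig = 10,
                     effect = 1, noise = 0.5)
  # one shared activation pattern: samples of a single planted subtype
  sc <- co$scores[, names(co$truth$subtype)[co$truth$subtype == 1]]
  # plant 3 wildly aberrant profiles (1.5% of 200, under the 2% minority cap):
  # scaled x10 and sign-flipped, so they anti-correlate with the cohort
  bad <- c("S0003", "S0050", "S0099")
  sc[, bad] <- -10 * sc[, bad]
  out <- detect_outlier_samples(sc)
  expect_setequal(out, bad)
  # homogeneous cohort: nothing flagged
  expect_length(detect_outlier_samples(co$scores[, co$truth$subtype == 1]), 0)
})

test_that("constant-profile samples are flagged directly", {
  co <- small_cohort(seed = 5, n_per = 10)
  sc <- co$scores
  sc[, "S0001"] <- 7
  expect_true("S0001" %in% suppressMessages(detect_outlier_samples(sc)))
})

test_that("correlation filter keeps correlated signatures and drops noise", {
  set.seed(11)
  n <- 500
  base <- rnorm(n)
  sc <- rbind(a = base + rnorm(n, sd = 0.3),
              b = base + rnorm(n, sd = 0.3),
              c = -base + rnorm(n, sd = 0.3),
              noise = rnorm(n))
  colnames(sc) <- sprintf("s%03d", seq_len(n))
  kept <- filter_signatures_by_correlation(sc, min_abs_cor = 0.3)
  expect_setequal(kept, c("a", "b", "c"))   # anti-correlation counts via |cor|
  # two identical signatures are retained at any threshold <= 1
  dup <- rbind(x = base, y = base)
  colnames(dup) <- colnames(sc)
  expect_setequal(filter_signatures_by_correlation(dup, 1), c("x", "y"))
  # monotonicity: lower threshold retains a superset
  kept_lo <- filter_signatures_by_correlation(sc, min_abs_cor = 0.05)
  expect_true(all(kept %in% kept_lo))
  expect_error(filter_signatures_by_correlation(sc[1, , drop = FALSE]),
               "at least 2")
})

test_that("Cox screen directions follow the hazard-ratio/p contract", {
  co <- small_cohort(seed = 6, k_true = 2, n_per = 150, n_sig = 4)
  sc <- co$scores
  sc <- rbind(sc, flat = rep(5, ncol(sc)))
  res <- suppressMessages(cox_screen(sc, co$survival))
  expect_s3_class(res, "cox_screen")
  expect_equal(res$hazard_ratio[res$signature == "flat"], 1)
  expect_equal(res$direction[res$signature == "flat"], "neutral")
  sig <- res$p_value < 0.05 & res$signature != "flat"
  expect_true(all(res$direction[sig] %in% c("protective", "unfavorable")))
  expect_true(all((res$hazard_ratio[sig] < 1) ==
                    (res$direction[sig] == "protective")))
  expect_true(all(res$ci_low[sig] <= res$hazard_ratio[sig] &
                    res$hazard_ratio[sig] <= res$ci_high[sig]))
})

test_that("Cox fit recovers a planted log hazard ratio", {
  cfg <- bulk_sim_config(k_true = 2, n_per_subtype = 1000, n_signatures = 4,
                         genes_per_signature = 10, effect_size = 1,
                         noise_sd = 1, censor_rate = 0.3,
                         subtype_log_hazards = c(0, 0),
                         prognostic_signatures = 1L,
                         prognostic_log_hazards = 0.7, seed = 9)
  co <- gen_bulk_cohort(cfg)
  sc <- score_signatures(co$expr, co$signatures)
  z <- scale(sc["SIG01", ])[, 1]
  fit <- cox_univariate(setNames(z, colnames(sc)), co$survival)
  expect_lt(abs(fit$log_hr - 0.7), 0.1)
})

test_that("Cox log-HR matches the reference implementation under Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (r in 1:20) {
    n <- sample(20:50, 1)
    x <- rnorm(n)
    time <- round(rexp(n, 0.2), if (r %% 2 == 0) 1 else 6)  # half with ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 3) event[1:3] <- 1
    mine <- cox_univariate(setNames(x, sprintf("s%d", 1:n)),
                           data.frame(sample_id = sprintf("s%d", 1:n),
                                      time = time, event = event))
    ref <- survival::coxph(survival::Surv(time, event) ~ x,
                           ties = "breslow")
    expect_lt(abs(mine$log_hr - unname(coef(ref))), 1e-6)
  }
})

test_that("sign flip of the covariate flips the log hazard ratio exactly", {
  co <- small_cohort(seed = 12, n_per = 40)
  x <- setNames(co$scores[1, ], colnames(co$scores))
  f1 <- cox_univariate(x, co$survival)
  f2 <- cox_univariate(-x, co$survival)
  expect_equal(f1$log_hr, -f2$log_hr, tolerance = 1e-8)
})

test_that("null covariates give a calibrated Cox type-I error", {
  reps <- 500
  set.seed(17)
  rejected <- vapply(seq_len(reps), function(r) {
    n <- 100
    time <- rexp(n)
    event <- rbinom(n, 1, 0.7)
    x <- setNames(rnorm(n), sprintf("s%d", 1:n))
    fit <- cox_univariate(x, data.frame(sample_id = names(x), time = time,
                                        event = event))
    fit$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.03)
  expect_lt(mean(rejected), 0.07)
})
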