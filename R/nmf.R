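#' Single NMF factorization under generalized Kullback-Leibler divergence
#'
#' Factorizes a non-negative matrix `V ~ W H` (rank `k`) by multiplicative
#' updates minimizing the generalized KL divergence `D(V || WH)` (the Brunet
#' variant classically used for expression subtyping). Entries of `W` and `H`
#' are initialized `Uniform(0, 1)` scaled so that `WH` matches the mean of
#' `V`, from `seed`. Iteration stops when the relative objective change drops
#' below `tol` or after `max_iter` updates. On return the columns of `W` are
#' normalized to sum 1, with the compensation absorbed into `H`.
#'
#' @param V non-negative numeric matrix (no all-zero rows or columns).
#' @param k factorization rank.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum multiplicative updates.
#' @param tol stopping tolerance on the mean per-iteration relative objective
#'   change between evaluations.
#' @param obj_every evaluate the KL objective every this many updates
#'   (1 records the full per-iteration trace; the default trades trace
#'   resolution for speed, the updates themselves are identical).
#' @return object of class `nmf_model`: `W`, `H`, `k`, `objective` (KL at
#'   convergence), `objective_trace` (with `trace_iter` giving the update
#'   index of each entry), `n_iter`, `seed`.
#' @export
nmf_run <- function(V, k, seed = 1, max_iter = 2000, tol = 1e-6,
                    obj_every = 10) {
  if (!is.matrix(V) || !is.numeric(V)) stop("V must be a numeric matrix")
  if (any(V < 0)) stop("V has negative entries; NMF input must be non-negative")
  zr <- which(rowSums(V) == 0)
  if (length(zr)) {
    stop("all-zero row(s) in V: ",
         paste(head(if (is.null(rownames(V))) zr else rownames(V)[zr], 5L),
               collapse = ", "))
  }
  if (any(colSums(V) == 0)) stop("all-zero column(s) in V")
  if (k < 1 || k > min(dim(V))) stop("rank k out of range")
  set.seed(as.integer(seed))
  scale_c <- 2 * sqrt(mean(V) / k)     # E[WH] ~ mean(V) for U(0,1)*c factors
  W <- matrix(runif(nrow(V) * k), nrow(V), k) * scale_c
  H <- matrix(runif(k * ncol(V)), k, ncol(V)) * scale_c
  fit <- .nmf_kl_cpp(V, W, H, as.integer(max_iter), tol,
                     as.integer(obj_every))
  W <- fit$W; H <- fit$H
  csum <- colSums(W)
  W <- sweep(W, 2L, csum, "/")
  H <- H * csum
  dimnames(W) <- list(rownames(V), NULL)
  dimnames(H) <- list(NULL, colnames(V))
  structure(list(W = W, H = H, k = as.integer(k), objective = fit$objective,
                 objective_trace = fit$objective_trace,
                 trace_iter = fit$trace_iter, n_iter = fit$n_iter,
                 seed = as.integer(seed)),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("NMF model: rank %d, %d x %d, KL objective %.6g after %d iterations\n",
              x$k, nrow(x$W), ncol(x$H), x$objective, x$n_iter))
  invisible(x)
}

#' Subtype labels from an NMF model
#'
#' Each row of `H` is scaled by its maximum; sample `i` is assigned to the
#' factor with the largest scaled coefficient (ties to the smallest factor
#' index). Labels are then renamed `TMES1..TMESk` in order of decreasing
#' subtype size so repeated runs are comparable.
#'
#' @param model an `nmf_model`.
#' @return named character vector sample -> `TMES<j>`.
#' @export
run_labels <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  H <- model$H
  if (any(colSums(H) == 0)) stop("all-zero H column: sample has no factor loading")
  rmax <- apply(H, 1L, max)
  Hs <- H / pmax(rmax, .Machine$double.xmin)
  raw <- apply(Hs, 2L, which.max)      # first (smallest) index on ties
  relabel_by_size(raw, colnames(H))
}

# deterministic relabeling: subtype 1 = largest, ties by first occurrence of
# the original factor index
relabel_by_size <- function(raw, sample_ids) {
  counts <- tabulate(raw, nbins = max(raw))
  ord <- order(-counts, seq_along(counts))
  new_idx <- match(raw, ord)
  setNames(sprintf("TMES%d", new_idx), sample_ids)
}

#' Consensus matrix from repeated subtype assignments
#'
#' `C[i, j]` is the fraction of runs in which samples `i` and `j` received
#' the same label.
#'
#' @param labelings list (length >= 2) of named label vectors over identical
#'   samples.
#' @return symmetric samples x samples matrix in `[0, 1]` with unit diagonal.
#' @export
consensus_from_runs <- function(labelings) {
  if (length(labelings) < 2) stop("need at least 2 labelings")
  ids <- names(labelings[[1L]])
  C <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (lab in labelings) {
    if (!setequal(names(lab), ids)) stop("labelings cover different sample sets")
    lab <- lab[ids]
    ind <- outer(lab, unique(lab), "==") + 0   # samples x labels indicator
    C <- C + tcrossprod(ind)
  }
  C / length(labelings)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Average-linkage hierarchical clustering of `D = 1 - C` and the Pearson
#' correlation between the tree's cophenetic distances and `D` (upper
#' triangle). Values near 1 indicate that the consensus is well represented
#' by a tree, i.e. stable clustering. Returns `NaN` with a warning when `D`
#' is constant (correlation undefined).
#'
#' @param C consensus matrix (>= 3 samples).
#' @return scalar in `[-1, 1]`, or `NaN` for degenerate input.
#' @export
cophenetic_coefficient <- function(C) {
  if (nrow(C) < 3) stop("cophenetic coefficient needs >= 3 samples")
  D <- as.dist(1 - C)
  if (sd(D) == 0) {
    warning("constant consensus distances: cophenetic correlation undefined")
    return(NaN)
  }
  hc <- hclust(D, method = "average")
  cd <- cophenetic(hc)
  if (sd(cd) == 0) {
    warning("constant cophenetic distances: correlation undefined")
    return(NaN)
  }
  cor(as.vector(D), as.vector(cd))
}

#' Dispersion coefficient of a consensus matrix
#'
#' `mean(4 (C - 1/2)^2)` over all entries: 1 iff the consensus is perfectly
#' crisp (all entries 0 or 1), smaller when co-clustering is ambiguous.
#'
#' @param C consensus matrix.
#' @return scalar in `[0, 1]`.
#' @export
dispersion_coefficient <- function(C) {
  mean(4 * (C - 0.5)^2)
}

#' Survey NMF ranks by consensus cophenetic and dispersion coefficients
#'
#' For each candidate rank `k`, runs `n_runs` NMF restarts (distinct derived
#' seeds), labels each run, forms the consensus matrix, and computes the
#' cophenetic and dispersion coefficients. The chosen rank maximizes their
#' product (ties to the smallest `k`).
#'
#' @param V non-negative matrix (signatures x samples).
#' @param k_range candidate ranks.
#' @param n_runs NMF restarts per rank.
#' @param seed master seed.
#' @param max_iter,tol forwarded to [nmf_run()].
#' @return object of class `rank_survey`: `table` (data.frame k, cophenetic,
#'   dispersion, product), `chosen_k`.
#' @export
rank_survey <- function(V, k_range = 3:8, n_runs = 50, seed = 1,
                        max_iter = 2000, tol = 1e-6) {
  if (n_runs == 1) {
    tme_log("rank survey with a single run: consensus is binary and ",
            "dispersion is 1 for every k")
  }
  seeds <- matrix(derive_seeds(seed, length(k_range) * n_runs),
                  nrow = length(k_range))
  rows <- lapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    labelings <- lapply(seq_len(n_runs), function(r) {
      run_labels(nmf_run(V, k, seed = seeds[i, r], max_iter = max_iter,
                         tol = tol))
    })
    C <- if (n_runs >= 2) consensus_from_runs(labelings) else {
      consensus_from_runs(c(labelings, labelings))
    }
    coph <- suppressWarnings(cophenetic_coefficient(C))
    disp <- dispersion_coefficient(C)
    data.frame(k = k, cophenetic = coph, dispersion = disp,
               product = coph * disp)
  })
  tab <- do.call(rbind, rows)
  prod_ok <- ifelse(is.finite(tab$product), tab$product, -Inf)
  chosen <- tab$k[which.max(prod_ok)]   # first (smallest k) on ties
  structure(list(table = tab, chosen_k = chosen, k_range = k_range,
                 n_runs = n_runs, seed = seed),
            class = "rank_survey")
}

#' @export
print.rank_survey <- function(x, ...) {
  cat(sprintf("NMF rank survey (%d runs per k):\n", x$n_runs))
  print(x$table, row.names = FALSE, digits = 4)
  cat("chosen k =", x$chosen_k, "(max cophenetic x dispersion)\n")
  invisible(x)
}

#' Final subtype assignment at a fixed rank
#'
#' Runs `n_runs` NMF restarts at rank `k`, keeps the model with the best
#' (lowest) KL objective, and labels samples from that model; the consensus
#' matrix over all restarts is returned for stability assessment.
#'
#' @param V non-negative matrix.
#' @param k rank (from [rank_survey()] or fixed by the user).
#' @param n_runs restarts.
#' @param seed master seed.
#' @param max_iter,tol forwarded to [nmf_run()].
#' @return list with `assignment` (named labels), `model` (best `nmf_model`),
#'   `consensus`.
#' @export
final_subtypes <- function(V, k, n_runs = 500, seed = 1, max_iter = 2000,
                           tol = 1e-6) {
  seeds <- derive_seeds(seed, n_runs)
  best <- NULL
  labelings <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    m <- nmf_run(V, k, seed = seeds[r], max_iter = max_iter, tol = tol)
    labelings[[r]] <- run_labels(m)
    if (is.null(best) || m$objective < best$objective) best <- m
  }
  C <- if (n_runs >= 2) consensus_from_runs(labelings) else {
    consensus_from_runs(c(labelings, labelings))
  }
  list(assignment = run_labels(best), model = best, consensus = C)
}

# Validate / repair a user-supplied matrix for NMF: rows containing negative
# values are shifted up by their minimum (logged), the convention for
# centered signature scores.
prepare_nmf_input <- function(V) {
  if (any(V < 0)) {
    tme_log("input has negative entries; shifting each affected row by its minimum")
    shift <- pmin(apply(V, 1L, min), 0)
    V <- V - shift
  }
  V
}
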