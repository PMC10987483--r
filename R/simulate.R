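#' Configuration for a synthetic bulk cohort
#'
#' Describes a cohort drawn from `k_true` latent tumor-microenvironment
#' subtypes. Each subtype activates a distinct subset of signatures
#' (round-robin assignment of signatures to subtypes); expression of gene `g`
#' in sample `s` is
#' `baseline_mean + effect_size * [g in an active signature of subtype(s)] + N(0, noise_sd)`,
#' truncated at 0 so non-negativity holds for NMF. Survival is exponential
#' with per-sample rate
#' `exp(subtype_log_hazard + sum_j prognostic_log_hazards[j] * z_j)` where
#' `z_j` is the cohort-standardized true score of the j-th prognostic
#' signature; censoring is an independent exponential tuned so each sample is
#' censored with probability `censor_rate`.
#'
#' @param k_true number of planted subtypes (>= 2).
#' @param n_per_subtype samples per subtype.
#' @param n_signatures number of signatures (>= k_true).
#' @param genes_per_signature genes in each signature (signatures partition
#'   the gene catalogue).
#' @param effect_size mean log2-expression shift of active-signature genes
#'   (> 0).
#' @param noise_sd per-gene Gaussian noise SD (log2 units).
#' @param baseline_mean baseline log2 expression (>= 0).
#' @param censor_rate probability a sample is censored, in `[0, 1)`.
#' @param subtype_log_hazards length-`k_true` vector of subtype log hazards;
#'   default spreads evenly over `[-0.5, 0.5]`.
#' @param prognostic_signatures integer indices of signatures whose scores
#'   drive hazard (may be empty).
#' @param prognostic_log_hazards per-SD log hazard ratios matching
#'   `prognostic_signatures`.
#' @param seed integer seed.
#' @return a `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(k_true = 5, n_per_subtype = 60, n_signatures = 20,
                            genes_per_signature = 10, effect_size = 3,
                            noise_sd = 0.5, baseline_mean = 5,
                            censor_rate = 0.3, subtype_log_hazards = NULL,
                            prognostic_signatures = integer(0),
                            prognostic_log_hazards = numeric(0), seed = 1) {
  if (k_true < 2) stop("k_true must be >= 2")
  if (k_true > n_signatures) stop("k_true exceeds n_signatures")
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (baseline_mean < 0) stop("baseline_mean must be >= 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (is.null(subtype_log_hazards)) {
    subtype_log_hazards <- seq(-0.5, 0.5, length.out = k_true)
  }
  if (length(subtype_log_hazards) != k_true) {
    stop("subtype_log_hazards must have length k_true")
  }
  if (length(prognostic_signatures) != length(prognostic_log_hazards)) {
    stop("prognostic_signatures and prognostic_log_hazards lengths differ")
  }
  if (length(prognostic_signatures) &&
      (any(prognostic_signatures < 1) || any(prognostic_signatures > n_signatures))) {
    stop("prognostic_signatures out of range")
  }
  structure(list(k_true = k_true, n_per_subtype = n_per_subtype,
                 n_signatures = n_signatures,
                 genes_per_signature = genes_per_signature,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, censor_rate = censor_rate,
                 subtype_log_hazards = subtype_log_hazards,
                 prognostic_signatures = as.integer(prognostic_signatures),
                 prognostic_log_hazards = prognostic_log_hazards,
                 seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Generate a synthetic bulk cohort with planted subtypes and survival
#'
#' @param cfg a [bulk_sim_config()].
#' @return list with `expr` (genes x samples matrix), `signatures` (named
#'   list), `survival` (data.frame sample_id/time/event) and `truth` (planted
#'   subtype per sample, active signatures per subtype, prognostic plant).
#' @export
gen_bulk_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  if (cfg$k_true > cfg$n_signatures) stop("k_true exceeds n_signatures")
  set.seed(cfg$seed)
  k <- cfg$k_true
  n <- k * cfg$n_per_subtype
  sig_names <- sprintf("SIG%02d", seq_len(cfg$n_signatures))
  sigs <- lapply(seq_len(cfg$n_signatures), function(i) {
    sprintf("SIG%02d_G%02d", i, seq_len(cfg$genes_per_signature))
  })
  names(sigs) <- sig_names
  genes <- unlist(sigs, use.names = FALSE)
  samples <- sprintf("S%04d", seq_len(n))
  subtype <- rep(seq_len(k), each = cfg$n_per_subtype)

  # round-robin: subtype j activates signatures i with (i-1) mod k == j-1
  sig_subtype <- ((seq_len(cfg$n_signatures) - 1L) %% k) + 1L
  active_sets <- split(sig_names, sig_subtype)

  gene_sig <- rep(seq_len(cfg$n_signatures), each = cfg$genes_per_signature)
  active <- outer(sig_subtype[gene_sig], subtype, "==")  # genes x samples
  expr <- cfg$baseline_mean + cfg$effect_size * active
  if (cfg$noise_sd > 0) {
    expr <- expr + matrix(rnorm(length(genes) * n, sd = cfg$noise_sd),
                          nrow = length(genes))
  }
  expr <- pmax(expr, 0)
  dimnames(expr) <- list(genes, samples)

  log_rate <- cfg$subtype_log_hazards[subtype]
  if (length(cfg$prognostic_signatures)) {
    for (j in seq_along(cfg$prognostic_signatures)) {
      sc <- colMeans(expr[sigs[[cfg$prognostic_signatures[j]]], , drop = FALSE])
      z <- (sc - mean(sc)) / sd(sc)
      log_rate <- log_rate + cfg$prognostic_log_hazards[j] * z
    }
  }
  rate <- exp(log_rate)
  t_event <- rexp(n, rate = rate)
  if (cfg$censor_rate > 0) {
    # censoring rate mu = lambda * c/(1-c) gives P(censor) = c per sample
    t_cens <- rexp(n, rate = rate * cfg$censor_rate / (1 - cfg$censor_rate))
  } else {
    t_cens <- rep(Inf, n)
  }
  surv <- data.frame(sample_id = samples,
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)
  truth <- list(subtype = setNames(subtype, samples),
                active_signatures = active_sets,
                prognostic_signatures = sig_names[cfg$prognostic_signatures],
                prognostic_log_hazards = cfg$prognostic_log_hazards)
  list(expr = expr, signatures = sigs, survival = surv, truth = truth)
}

#' Configuration for a synthetic single-cell cohort
#'
#' Negative-binomial background counts with planted cell types (disjoint
#' marker sets up-weighted by `marker_fold`), designated mitochondrial genes
#' (names prefixed `MT-`) contributing a target fraction of each cell's
#' counts in expectation, planted low-quality cells (high mitochondrial
#' fraction, fewer than 100 expressed genes), and planted ligand-receptor
#' co-expression between chosen sender/receiver cell types.
#'
#' @param n_cell_types number of planted cell types.
#' @param cells_per_type good cells per type.
#' @param n_genes total genes including markers, mito and LR genes.
#' @param markers_per_type marker genes per type (disjoint across types).
#' @param nb_mean,nb_dispersion background negative-binomial mean and size.
#' @param marker_fold fold up-weighting of a type's markers in that type (> 1).
#' @param mito_fraction_good,mito_fraction_bad expected mitochondrial count
#'   fraction for good and low-quality cells.
#' @param n_lowquality_cells planted low-quality cells.
#' @param n_mito_genes number of `MT-` genes.
#' @param lowquality_expressed_genes non-mito genes a low-quality cell may
#'   express (must keep it under the 100-gene QC threshold).
#' @param planted_pairs data.frame with columns ligand, receptor, sender,
#'   receiver (type indices), fold.
#' @param seed integer seed.
#' @return an `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_cell_types = 4, cells_per_type = 100,
                          n_genes = 500, markers_per_type = 10,
                          nb_mean = 1, nb_dispersion = 2, marker_fold = 8,
                          mito_fraction_good = 0.01, mito_fraction_bad = 0.3,
                          n_lowquality_cells = 10, n_mito_genes = 10,
                          lowquality_expressed_genes = 60,
                          planted_pairs = NULL, seed = 1) {
  if (marker_fold <= 1) stop("marker_fold must be > 1")
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(ligand = "LIG1", receptor = "REC1",
                                sender = 1L, receiver = 2L, fold = 8,
                                stringsAsFactors = FALSE)
  }
  if (nrow(planted_pairs) &&
      (any(planted_pairs$sender < 1) || any(planted_pairs$sender > n_cell_types) ||
       any(planted_pairs$receiver < 1) || any(planted_pairs$receiver > n_cell_types))) {
    stop("planted pair references an unknown cell type")
  }
  n_lr <- length(unique(c(planted_pairs$ligand, planted_pairs$receptor)))
  n_special <- n_cell_types * markers_per_type + n_mito_genes + n_lr
  if (n_genes <= n_special) stop("n_genes too small for markers/mito/LR genes")
  if (lowquality_expressed_genes + n_mito_genes >= 100) {
    stop("low-quality cells would express >= 100 genes")
  }
  structure(list(n_cell_types = n_cell_types, cells_per_type = cells_per_type,
                 n_genes = n_genes, markers_per_type = markers_per_type,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 marker_fold = marker_fold,
                 mito_fraction_good = mito_fraction_good,
                 mito_fraction_bad = mito_fraction_bad,
                 n_lowquality_cells = n_lowquality_cells,
                 n_mito_genes = n_mito_genes,
                 lowquality_expressed_genes = lowquality_expressed_genes,
                 planted_pairs = planted_pairs, seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Generate a synthetic single-cell cohort with planted structure
#'
#' @param cfg an [sc_sim_config()].
#' @return list with `counts` (sparse genes x cells), `truth` (cell type per
#'   cell, low-quality flags, marker sets per type, planted pair table).
#' @export
gen_sc_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  set.seed(cfg$seed)
  K <- cfg$n_cell_types
  marker_sets <- lapply(seq_len(K), function(t) {
    sprintf("T%dM%02d", t, seq_len(cfg$markers_per_type))
  })
  names(marker_sets) <- sprintf("TYPE%d", seq_len(K))
  lr_genes <- unique(c(cfg$planted_pairs$ligand, cfg$planted_pairs$receptor))
  mito_genes <- sprintf("MT-%d", seq_len(cfg$n_mito_genes))
  n_bg <- cfg$n_genes - K * cfg$markers_per_type - length(lr_genes) -
    cfg$n_mito_genes
  bg_genes <- sprintf("BG%04d", seq_len(n_bg))
  genes <- c(unlist(marker_sets, use.names = FALSE), lr_genes, bg_genes,
             mito_genes)

  # per-type mean for non-mito genes
  non_mito <- setdiff(genes, mito_genes)
  mu_type <- matrix(cfg$nb_mean, nrow = length(non_mito), ncol = K,
                    dimnames = list(non_mito, NULL))
  for (t in seq_len(K)) mu_type[marker_sets[[t]], t] <- cfg$nb_mean * cfg$marker_fold
  if (nrow(cfg$planted_pairs)) {
    for (r in seq_len(nrow(cfg$planted_pairs))) {
      p <- cfg$planted_pairs[r, ]
      mu_type[p$ligand, p$sender] <- cfg$nb_mean * p$fold
      mu_type[p$receptor, p$receiver] <- cfg$nb_mean * p$fold
    }
  }

  n_good <- K * cfg$cells_per_type
  n_all <- n_good + cfg$n_lowquality_cells
  cell_type <- c(rep(seq_len(K), each = cfg$cells_per_type),
                 rep_len(seq_len(K), cfg$n_lowquality_cells))
  low_quality <- c(rep(FALSE, n_good), rep(TRUE, cfg$n_lowquality_cells))
  cells <- sprintf("C%04d", seq_len(n_all))

  counts <- matrix(0, nrow = length(genes), ncol = n_all,
                   dimnames = list(genes, cells))
  for (i in seq_len(n_all)) {
    mu <- mu_type[, cell_type[i]]
    if (low_quality[i]) {
      keep <- sample(non_mito, cfg$lowquality_expressed_genes)
      mu[!(non_mito %in% keep)] <- 0
    }
    cnt <- numeric(length(non_mito))
    pos <- mu > 0
    cnt[pos] <- rnbinom(sum(pos), mu = mu[pos], size = cfg$nb_dispersion)
    # mito genes: expected fraction f of total counts -> total mito mean
    # f/(1-f) * (non-mito mean total), split evenly over the MT- genes
    f <- if (low_quality[i]) cfg$mito_fraction_bad else cfg$mito_fraction_good
    mito_mu <- f / (1 - f) * sum(mu) / cfg$n_mito_genes
    mito_cnt <- if (mito_mu > 0) {
      rnbinom(cfg$n_mito_genes, mu = mito_mu, size = cfg$nb_dispersion)
    } else rep(0L, cfg$n_mito_genes)
    counts[, i] <- c(cnt, mito_cnt)
  }
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  truth <- list(cell_type = setNames(sprintf("TYPE%d", cell_type), cells),
                low_quality = setNames(low_quality, cells),
                marker_sets = marker_sets,
                planted_pairs = cfg$planted_pairs)
  list(counts = counts, truth = truth)
}
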