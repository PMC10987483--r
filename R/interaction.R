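#' Ligand-receptor interaction score between two cell groups
#'
#' `score = (mean ligand expression in the sender cluster + mean receptor
#' expression in the receiver cluster) / 2`, on log-normalized values, with
#' the fraction of expressing cells (> 0) in each group reported. A missing
#' gene yields an untested record carrying the reason.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param clustering named vector cell -> cluster.
#' @param ligand,receptor gene names.
#' @param sender,receiver cluster labels.
#' @return list with `score`, `frac_ligand`, `frac_receptor`, `tested`,
#'   `reason`.
#' @export
interaction_score <- function(norm, clustering, ligand, receptor, sender,
                              receiver) {
  clustering <- clustering[intersect(colnames(norm), names(clustering))]
  s_cells <- names(clustering)[clustering == sender]
  r_cells <- names(clustering)[clustering == receiver]
  if (length(s_cells) == 0 || length(r_cells) == 0) {
    stop("empty sender or receiver cluster")
  }
  missing <- setdiff(c(ligand, receptor), rownames(norm))
  if (length(missing)) {
    return(list(score = NA_real_, frac_ligand = NA_real_,
                frac_receptor = NA_real_, tested = FALSE,
                reason = paste("missing gene(s):",
                               paste(missing, collapse = ", "))))
  }
  lig <- norm[ligand, s_cells]
  rec <- norm[receptor, r_cells]
  list(score = (mean(lig) + mean(rec)) / 2,
       frac_ligand = mean(lig > 0), frac_receptor = mean(rec > 0),
       tested = TRUE, reason = NA_character_)
}

#' Permutation test for ligand-receptor interactions across cluster pairs
#'
#' For every (pair, sender, receiver) triple whose ligand and receptor are
#' each expressed in at least `min_fraction` of the respective cluster's
#' cells, cluster labels are permuted `n_perm` times (the same permutations
#' reused across all pairs, derived from `seed`) and the interaction score
#' recomputed; the add-one p-value is
#' `(1 + #\{permuted score >= observed\}) / (1 + n_perm)`, so the smallest
#' attainable p is `1/(1 + n_perm)`. Triples failing the expression gate (or
#' with missing genes) are reported untested.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param clustering named vector cell -> cluster (>= 2 clusters).
#' @param pairs data.frame with ligand, receptor, pair.
#' @param n_perm number of permutations (a warning is logged below 100).
#' @param min_fraction expressed-fraction gate per gene and cluster.
#' @param seed seed for the shared permutation set.
#' @return object of class `interaction_result`: data.frame with pair,
#'   sender, receiver, score, p_value, frac_ligand, frac_receptor, tested.
#' @export
lr_permutation_test <- function(norm, clustering, pairs, n_perm = 1000,
                                min_fraction = 0.1, seed = 1) {
  clustering <- clustering[intersect(colnames(norm), names(clustering))]
  cl_levels <- sort(unique(clustering))
  if (length(cl_levels) < 2) stop("need at least 2 clusters")
  if (n_perm < 100) {
    tme_log("n_perm < 100: p-value granularity is coarse")
  }
  genes <- unique(c(pairs$ligand, pairs$receptor))
  present <- intersect(genes, rownames(norm))
  X <- as.matrix(norm[present, names(clustering), drop = FALSE])
  lab <- as.character(clustering)
  K <- length(cl_levels)

  group_means <- function(labels) {
    ind <- outer(labels, as.character(cl_levels), "==") + 0
    sweep(X %*% ind, 2L, colSums(ind), "/")   # genes x clusters
  }
  obs_mean <- group_means(lab)
  frac <- sweep((X > 0) %*% (outer(lab, as.character(cl_levels), "==") + 0),
                2L, as.vector(table(factor(lab, levels = cl_levels))), "/")
  colnames(obs_mean) <- colnames(frac) <- as.character(cl_levels)

  grid <- expand.grid(pair_idx = seq_len(nrow(pairs)),
                      sender = cl_levels, receiver = cl_levels,
                      KEEP.OUT.ATTRS = FALSE)
  res <- data.frame(pair = pairs$pair[grid$pair_idx],
                    ligand = pairs$ligand[grid$pair_idx],
                    receptor = pairs$receptor[grid$pair_idx],
                    sender = grid$sender, receiver = grid$receiver,
                    score = NA_real_, p_value = NA_real_,
                    frac_ligand = NA_real_, frac_receptor = NA_real_,
                    tested = FALSE, stringsAsFactors = FALSE)
  ok_gene <- res$ligand %in% present & res$receptor %in% present
  li <- match(res$ligand, present); ri <- match(res$receptor, present)
  si <- match(as.character(res$sender), colnames(obs_mean))
  vi <- match(as.character(res$receiver), colnames(obs_mean))
  res$frac_ligand[ok_gene] <- frac[cbind(li, si)][ok_gene]
  res$frac_receptor[ok_gene] <- frac[cbind(ri, vi)][ok_gene]
  res$score[ok_gene] <- ((obs_mean[cbind(li, si)] +
                            obs_mean[cbind(ri, vi)]) / 2)[ok_gene]
  res$tested <- ok_gene & res$frac_ligand >= min_fraction &
    res$frac_receptor >= min_fraction

  if (any(res$tested)) {
    set.seed(as.integer(seed))
    exceed <- numeric(nrow(res))
    t_idx <- which(res$tested)
    for (p in seq_len(n_perm)) {
      pm <- group_means(sample(lab))
      perm_score <- (pm[cbind(li[t_idx], si[t_idx])] +
                       pm[cbind(ri[t_idx], vi[t_idx])]) / 2
      exceed[t_idx] <- exceed[t_idx] + (perm_score >= res$score[t_idx])
    }
    res$p_value[t_idx] <- (1 + exceed[t_idx]) / (1 + n_perm)
  }
  structure(res, class = c("interaction_result", "data.frame"))
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("Ligand-receptor permutation test: %d triples, %d tested, %d with p < 0.05\n",
              nrow(x), sum(x$tested), sum(x$tested & x$p_value < 0.05)))
  NextMethod()
}

#' Significant-interaction counts per cluster pair
#'
#' @param results an `interaction_result`.
#' @param alpha significance level.
#' @return data.frame sender, receiver, n_significant (tested triples with
#'   p < alpha).
#' @export
interaction_network_summary <- function(results, alpha = 0.05) {
  stopifnot(inherits(results, "interaction_result"))
  sig <- results$tested & !is.na(results$p_value) & results$p_value < alpha
  agg <- aggregate(sig, by = list(sender = results$sender,
                                  receiver = results$receiver), FUN = sum)
  names(agg)[3] <- "n_significant"
  agg[order(agg$sender, agg$receiver), , drop = FALSE]
}
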