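#' Quality-control filter for single-cell counts
#'
#' Filters in a fixed order so cell/gene counts are reproducible: (1) drop
#' cells whose mitochondrial count fraction (genes prefixed `MT-`) exceeds
#' `max_mito`, (2) drop cells expressing fewer than `min_genes` genes,
#' (3) drop genes expressed (count > 0) in fewer than `min_cells` cells.
#'
#' @param counts sparse genes x cells count matrix.
#' @param min_cells gene retention threshold.
#' @param min_genes cell complexity threshold.
#' @param max_mito maximum mitochondrial count fraction per cell.
#' @return filtered sparse count matrix.
#' @export
qc_filter <- function(counts, min_cells = 5, min_genes = 100,
                      max_mito = 0.05) {
  validate_sc_counts(counts)
  mito <- grepl("^MT-", rownames(counts))
  totals <- Matrix::colSums(counts)
  mito_frac <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1)
  } else rep(0, ncol(counts))
  keep_cells <- mito_frac <= max_mito
  n_expressed <- Matrix::colSums(counts > 0)
  keep_cells <- keep_cells & n_expressed >= min_genes
  if (!any(keep_cells)) stop("QC removed all cells")
  out <- counts[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(out > 0) >= min_cells
  out[keep_genes, , drop = FALSE]
}

#' Log-normalize single-cell counts
#'
#' `value = ln(1 + 1e4 * count / cell_total)`: each cell scaled to a common
#' total of 10,000 counts, then natural-log transformed with a pseudocount.
#'
#' @param counts sparse genes x cells count matrix (QC-filtered).
#' @param scale_factor library-size target (default 1e4).
#' @return sparse matrix of log-normalized expression.
#' @export
sc_normalize <- function(counts, scale_factor = 1e4) {
  validate_sc_counts(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("cell(s) with zero total counts; run qc_filter first")
  norm <- methods::as(counts, "CsparseMatrix")
  norm@x <- log1p(scale_factor * norm@x /
                    rep.int(totals, diff(norm@p)))
  norm
}

#' Select highly variable genes by binned standardized variance
#'
#' Genes are binned into 20 equal-occupancy bins of mean expression; each
#' gene's variance is standardized by its bin's median variance (the
#' mean-variance trend) and the top `n` genes by standardized variance are
#' returned. If fewer than `n` genes have positive variance, all of them are
#' returned with a warning.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param n number of genes to select.
#' @param n_bins mean-expression bins for the variance trend.
#' @return character vector of selected gene names.
#' @export
select_hvg <- function(norm, n = 2000, n_bins = 20) {
  mu <- Matrix::rowMeans(norm)
  # sparse-friendly variance: E[x^2] - mu^2, with n/(n-1) correction
  nc <- ncol(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- (ex2 - mu^2) * nc / (nc - 1)
  v[v < 0] <- 0
  pos <- v > 0
  if (sum(pos) <= n) {
    if (sum(pos) < n) warning("only ", sum(pos), " genes with positive variance")
    return(names(v)[pos])
  }
  mu_p <- mu[pos]; v_p <- v[pos]
  n_bins <- min(n_bins, max(1L, floor(sum(pos) / 2)))
  bin <- cut(rank(mu_p, ties.method = "first"),
             breaks = n_bins, labels = FALSE)
  trend <- tapply(v_p, bin, median)
  trend[trend <= 0] <- min(trend[trend > 0])
  std_var <- v_p / trend[bin]
  sel <- order(-std_var, seq_along(std_var))[seq_len(n)]
  names(v_p)[sel]
}

#' PCA embedding of cells on highly variable genes
#'
#' Genes are centered and unit-scaled over cells, cells are projected onto
#' the top principal directions. Each component's sign is fixed so that its
#' largest-magnitude gene loading is positive, making repeated runs
#' bit-identical.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param hvg genes to use.
#' @param n_pcs number of components.
#' @return cells x `n_pcs` embedding matrix (rownames = cell ids).
#' @export
pca_embed <- function(norm, hvg, n_pcs = 20) {
  hvg <- intersect(hvg, rownames(norm))
  if (n_pcs > min(length(hvg), ncol(norm))) {
    stop("n_pcs exceeds the number of genes or cells")
  }
  X <- t(as.matrix(norm[hvg, , drop = FALSE]))   # cells x genes
  X <- scale(X)
  if (any(!is.finite(X))) stop("zero-variance gene in HVG set")
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  emb <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2L, flip, "*")
  rownames(emb) <- colnames(norm)
  emb
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph (Euclidean distance on the embedding),
#' weights edges by the Jaccard similarity of the two cells' neighbor sets,
#' and partitions the graph by modularity-based (Louvain) community
#' detection at the given resolution. Clusters are renumbered from 0 by
#' decreasing size.
#'
#' @param embedding cells x dims matrix (rownames = cell ids).
#' @param k_neighbors neighbors per cell.
#' @param resolution modularity resolution.
#' @param seed seed for the community detection.
#' @return named integer vector cell -> cluster (0-based).
#' @export
cluster_cells <- function(embedding, k_neighbors = 20, resolution = 0.8,
                          seed = 1) {
  n <- nrow(embedding)
  if (n <= k_neighbors) stop("need more cells than k_neighbors")
  d <- as.matrix(dist(embedding))
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[2:(k_neighbors + 1L)]   # exclude self
    A[i, nn] <- 1L
  }
  shared <- tcrossprod(A)
  jac <- shared / (2 * k_neighbors - shared)   # Jaccard of the two kNN sets
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max",
                                           weighted = TRUE)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  ord <- names(sort(sizes, decreasing = TRUE))
  new_id <- setNames(seq_along(ord) - 1L, ord)
  setNames(as.integer(new_id[as.character(memb)]), rownames(embedding))
}

#' Per-cluster marker genes by rank-sum test
#'
#' For each cluster, each gene is tested cluster vs all other cells with a
#' two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction). `log2FC = log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`.
#' P-values are Benjamini-Hochberg adjusted across genes within each cluster,
#' and rows are retained when `fdr < fdr_max` and `|log2FC| > min_abs_log2fc`.
#' Singleton or too-small clusters are skipped with a warning.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param clustering named integer vector cell -> cluster.
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_abs_log2fc absolute log2 fold-change threshold (default 0.25).
#' @param min_cluster_size smallest testable cluster.
#' @return data.frame (class `marker_table`) with cluster, gene,
#'   log2_fold_change, p_value, fdr, pct_in, pct_out; only retained rows.
#'   Attribute `n_genes_tested` records the universe size for enrichment.
#' @export
find_markers <- function(norm, clustering, fdr_max = 0.05,
                         min_abs_log2fc = 0.25, min_cluster_size = 3) {
  clustering <- clustering[intersect(colnames(norm), names(clustering))]
  cl_levels <- sort(unique(clustering))
  if (length(cl_levels) < 2) stop("need at least 2 clusters")
  X <- as.matrix(norm[, names(clustering), drop = FALSE])
  E <- expm1(X)
  out <- list()
  for (cl in cl_levels) {
    inc <- clustering == cl
    if (sum(inc) < min_cluster_size) {
      warning("cluster ", cl, " has fewer than ", min_cluster_size,
              " cells; skipped")
      next
    }
    m_in <- rowMeans(E[, inc, drop = FALSE])
    m_out <- rowMeans(E[, !inc, drop = FALSE])
    lfc <- log2((m_in + 1) / (m_out + 1))
    p <- vapply(seq_len(nrow(X)), function(g) {
      xi <- X[g, inc]; xo <- X[g, !inc]
      if (all(xi == xi[1]) && all(xo == xi[1])) return(1)
      suppressWarnings(wilcox.test(xi, xo, exact = FALSE)$p.value)
    }, numeric(1))
    p[!is.finite(p)] <- 1
    fdr <- p.adjust(p, method = "BH")
    keep <- fdr < fdr_max & abs(lfc) > min_abs_log2fc
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, gene = rownames(X)[keep], log2_fold_change = lfc[keep],
        p_value = p[keep], fdr = fdr[keep],
        pct_in = rowMeans(X[keep, inc, drop = FALSE] > 0),
        pct_out = rowMeans(X[keep, !inc, drop = FALSE] > 0),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(cluster = integer(0), gene = character(0),
               log2_fold_change = numeric(0), p_value = numeric(0),
               fdr = numeric(0), pct_in = numeric(0), pct_out = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "n_genes_tested") <- nrow(X)
  attr(res, "clusters") <- cl_levels
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Annotate clusters by hypergeometric enrichment of reference marker sets
#'
#' Each cluster is labeled with the reference cell-type marker set showing
#' the strongest hypergeometric enrichment of the cluster's retained
#' positive markers (log2FC > 0). Ties are left unlabeled (`"unlabeled"`);
#' clusters with no retained positive markers are `"unknown"`.
#'
#' @param markers a `marker_table` from [find_markers()].
#' @param reference named list of cell-type marker gene sets.
#' @return named character vector cluster -> cell-type label.
#' @export
annotate_clusters <- function(markers, reference) {
  stopifnot(inherits(markers, "marker_table"))
  validate_signatures(reference)
  N <- attr(markers, "n_genes_tested")
  clusters <- attr(markers, "clusters")
  labels <- setNames(rep("unknown", length(clusters)), as.character(clusters))
  for (cl in clusters) {
    mk <- markers$gene[markers$cluster == cl & markers$log2_fold_change > 0]
    if (length(mk) == 0) next
    pvals <- vapply(reference, function(ref) {
      q <- length(intersect(mk, ref))
      phyper(q - 1, length(ref), N - length(ref), length(mk),
             lower.tail = FALSE)
    }, numeric(1))
    best <- min(pvals)
    hits <- names(pvals)[pvals == best]
    labels[as.character(cl)] <- if (length(hits) == 1) hits else "unlabeled"
  }
  labels
}
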