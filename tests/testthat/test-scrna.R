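library(Matrix)

toy_counts <- function(m) {
  as(Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("QC filter equals a hand-computed brute-force mask on a toy matrix", {
  # 6 genes (1 mito) x 8 cells: 2 high-mito cells, 1 low-complexity cell,
  # 1 rare gene
  m <- matrix(5, nrow = 6, ncol = 8,
              dimnames = list(c("G1", "G2", "G3", "G4", "RARE", "MT-1"),
                              sprintf("c%d", 1:8)))
  m["RARE", ] <- 0; m["RARE", 1] <- 2          # expressed in 1 cell only
  m["MT-1", ] <- 1                             # ~3.8% mito for normal cells
  m["MT-1", 7:8] <- 40                         # high-mito cells
  m[, 6] <- 0; m["G1", 6] <- 3                 # low-complexity cell (1 gene)
  cc <- toy_counts(m)
  out <- qc_filter(cc, min_cells = 2, min_genes = 3, max_mito = 0.1)

  # brute-force reference on the dense copy, same order of operations
  dense <- m
  mito_frac <- dense["MT-1", ] / colSums(dense)
  keep_cells <- mito_frac <= 0.1 & colSums(dense > 0) >= 3
  dense <- dense[, keep_cells]
  keep_genes <- rowSums(dense > 0) >= 2
  dense <- dense[keep_genes, ]
  expect_identical(as.matrix(out), dense)
  expect_identical(colnames(out), sprintf("c%d", 1:5))
  expect_false("RARE" %in% rownames(out))
})

test_that("no-op thresholds leave the matrix unchanged", {
  sim <- gen_sc_cohort(sc_sim_config(n_cell_types = 2, cells_per_type = 10,
                                     n_genes = 120, n_lowquality_cells = 2,
                                     seed = 71))
  out <- qc_filter(sim$counts, min_cells = 0, min_genes = 0, max_mito = 1)
  expect_identical(as.matrix(out), as.matrix(sim$counts))
})

test_that("QC removes exactly the planted low-quality cells at default thresholds", {
  sim <- gen_sc_cohort(sc_sim_config(seed = 72))
  qc <- qc_filter(sim$counts)
  removed <- setdiff(colnames(sim$counts), colnames(qc))
  expect_setequal(removed, names(which(sim$truth$low_quality)))
})

test_that("normalization follows ln(1 + 1e4 c/total) and its invariances", {
  m <- toy_counts(matrix(c(1, 0, 9999, 0, 2, 8), nrow = 3,
                         dimnames = list(c("A", "B", "C"), c("c1", "c2"))))
  norm <- sc_normalize(m)
  expect_equal(norm["A", "c1"], log(2))        # total 1e4, count 1 -> ln 2
  expect_equal(norm["B", "c1"], 0)             # count 0 -> 0
  # doubling a cell's counts leaves its normalized vector unchanged
  m2 <- m; m2[, 1] <- m[, 1] * 2
  expect_equal(as.matrix(sc_normalize(m2))[, 1], as.matrix(norm)[, 1])
})

test_that("HVG selection drops constant genes and saturates at all genes", {
  set.seed(73)
  # work on an already-normalized dense matrix so "constant" is exact
  norm <- matrix(abs(rnorm(200 * 30, 2, 1)), 200, 30,
                 dimnames = list(sprintf("g%d", 1:200), sprintf("c%d", 1:30)))
  norm[1, ] <- 5   # constant gene: zero variance, never selectable
  hv <- select_hvg(norm, n = 50)
  expect_false("g1" %in% hv)
  expect_length(hv, 50)
  all_hv <- suppressWarnings(select_hvg(norm, n = 10000))
  expect_false("g1" %in% all_hv)
  vars <- apply(as.matrix(norm), 1, var)
  expect_setequal(all_hv, rownames(norm)[vars > 0])
})

test_that("planted marker genes rank as highly variable", {
  sim <- gen_sc_cohort(sc_sim_config(n_lowquality_cells = 0, seed = 74))
  norm <- sc_normalize(qc_filter(sim$counts))
  hv <- suppressWarnings(select_hvg(norm))   # default n covers all genes here
  markers <- intersect(unlist(sim$truth$marker_sets), rownames(norm))
  expect_gte(mean(markers %in% hv), 0.9)
})

test_that("PCA embedding is variance-ordered, sign-fixed and separates planted types", {
  sim <- gen_sc_cohort(sc_sim_config(n_cell_types = 2, cells_per_type = 40,
                                     n_genes = 200, n_lowquality_cells = 0,
                                     marker_fold = 10, seed = 75))
  norm <- sc_normalize(qc_filter(sim$counts))
  hv <- suppressWarnings(select_hvg(norm, n = 100))
  emb <- pca_embed(norm, hv, n_pcs = 10)
  vars <- apply(emb, 2, var)
  expect_true(all(diff(vars) <= 1e-10))
  emb2 <- pca_embed(norm, hv, n_pcs = 10)
  expect_identical(emb, emb2)               # bit-identical reruns
  # PC1 linearly separates the two planted types
  type <- sim$truth$cell_type[rownames(emb)]
  r1 <- range(emb[type == "TYPE1", 1]); r2 <- range(emb[type == "TYPE2", 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
  expect_error(pca_embed(norm, hv, n_pcs = 1000), "n_pcs")
})

test_that("graph clustering recovers planted types, is deterministic, co-clusters duplicates", {
  sim <- gen_sc_cohort(sc_sim_config(n_lowquality_cells = 0, seed = 76))
  norm <- sc_normalize(qc_filter(sim$counts))
  emb <- pca_embed(norm, suppressWarnings(select_hvg(norm)), n_pcs = 20)
  cl <- cluster_cells(emb, seed = 5)
  expect_gte(ari(cl, sim$truth$cell_type[names(cl)]), 0.9)
  expect_identical(cl, cluster_cells(emb, seed = 5))
  # duplicated cells (zero distance) land in the same cluster
  emb_dup <- rbind(emb, dup1 = emb[1, ], dup2 = emb[1, ])
  cl_dup <- cluster_cells(emb_dup, seed = 5)
  expect_equal(cl_dup[["dup1"]], cl_dup[[rownames(emb)[1]]])
  expect_error(cluster_cells(emb[1:10, ], k_neighbors = 20), "more cells")
})

test_that("marker detection retains planted markers and controls the null", {
  sim <- gen_sc_cohort(sc_sim_config(n_cell_types = 2, cells_per_type = 60,
                                     n_genes = 300, n_lowquality_cells = 0,
                                     seed = 77))
  norm <- sc_normalize(qc_filter(sim$counts))
  truth <- sim$truth$cell_type[colnames(norm)]
  cl <- setNames(as.integer(truth == "TYPE2"), names(truth))
  mk <- find_markers(norm, cl)
  t1 <- intersect(sim$truth$marker_sets$TYPE1, rownames(norm))
  found <- mk$gene[mk$cluster == 0 & mk$log2_fold_change > 0.25]
  expect_gte(mean(t1 %in% found), 0.9)
  # a gene identical across cells is never retained
  expect_false(any(mk$pct_in == 1 & mk$log2_fold_change == 0))
  # shuffled labels: retained fraction stays near the FDR level
  set.seed(78)
  cl_sh <- setNames(sample(cl), names(cl))
  mk_sh <- find_markers(norm, cl_sh)
  expect_lte(nrow(mk_sh) / (2 * nrow(norm)), 0.05)
})

test_that("cluster annotation labels planted types and handles degenerate cases", {
  sim <- gen_sc_cohort(sc_sim_config(n_lowquality_cells = 0, seed = 79))
  norm <- sc_normalize(qc_filter(sim$counts))
  emb <- pca_embed(norm, suppressWarnings(select_hvg(norm)), n_pcs = 20)
  cl <- cluster_cells(emb, seed = 6)
  mk <- find_markers(norm, cl)
  ann <- annotate_clusters(mk, sim$truth$marker_sets)
  truth <- sim$truth$cell_type[names(cl)]
  expect_gte(mean(ann[as.character(cl)] == truth), 0.95)
  # single-set reference: every labeled cluster gets it or "unknown"
  ann1 <- annotate_clusters(mk, sim$truth$marker_sets["TYPE1"])
  expect_true(all(ann1 %in% c("TYPE1", "unknown")))
  # empty marker table -> all unknown
  empty <- mk[0, ]
  attr(empty, "n_genes_tested") <- attr(mk, "n_genes_tested")
  attr(empty, "clusters") <- attr(mk, "clusters")
  class(empty) <- class(mk)
  expect_true(all(annotate_clusters(empty, sim$truth$marker_sets) == "unknown"))
})
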