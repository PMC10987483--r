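#' Read a genes x samples expression matrix from TSV
#'
#' Expects tab-separated text with gene symbols in the first column and a
#' header row of sample identifiers (the first header cell is ignored).
#' Values are log2(TPM+1) for RNA-seq or normalized intensities for arrays.
#'
#' @param path path to the TSV file.
#' @param aggregate_duplicates collapse duplicated gene symbols by their mean;
#'   if `FALSE` (default) duplicated symbols are an error.
#' @return numeric matrix, genes x samples, with dimnames.
#' @export
read_expression_tsv <- function(path, aggregate_duplicates = FALSE) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    quote = "", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty expression matrix in ", path)
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) stop("duplicated sample ids in header of ", path)
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                 samples[bad[1L, 2L]]))
  }
  if (anyDuplicated(genes)) {
    if (!aggregate_duplicates) {
      stop("duplicated gene symbols (set aggregate_duplicates = TRUE to average): ",
           paste(head(unique(genes[duplicated(genes)]), 5L), collapse = ", "))
    }
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
    tme_log("collapsed duplicated gene symbols by mean")
  }
  dimnames(num) <- list(genes, samples)
  validate_expression(num)
}

#' Write an expression matrix as TSV
#'
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-set signatures from a GMT file
#'
#' Standard GMT: one signature per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description is discarded,
#' signature order is preserved, and genes repeated within one line are
#' deduplicated keeping their first occurrence.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (signature -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("GMT line ", i, " has fewer than 3 fields")
    nms[i] <- f[1L]
    out[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    stop("duplicated signature name in GMT: ", nms[duplicated(nms)][1L])
  }
  names(out) <- nms
  validate_signatures(out)
}

#' Write a signature collection to GMT
#' @param sigs named list of gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(sigs, path) {
  validate_signatures(sigs)
  lines <- vapply(names(sigs), function(nm) {
    paste(c(nm, "na", sigs[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Requires columns `sample_id`, `time` (months, non-negative) and `event`
#' (1 = death observed, 0 = censored).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns sample_id, time, event.
#' @export
read_survival_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_survival(df)
  df$sample_id <- as.character(df$sample_id)
  df[, c("sample_id", "time", "event")]
}

#' Write a survival table to TSV (full-precision round trip)
#' @param surv data.frame with sample_id, time, event.
#' @param path output path.
#' @export
write_survival_tsv <- function(surv, path) {
  validate_survival(surv)
  df <- data.frame(sample_id = surv$sample_id,
                   time = sprintf("%.17g", surv$time),
                   event = as.integer(surv$event),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sparse single-cell counts in MatrixMarket layout
#'
#' Reads `matrix.mtx` (genes x cells), `genes.tsv` and `barcodes.tsv` from a
#' directory, the plain-text layout used for droplet data exports.
#'
#' @param dir directory containing the three files.
#' @return `dgCMatrix` of counts with gene rownames and cell colnames.
#' @export
read_sc_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("MTX dimensions do not match genes.tsv/barcodes.tsv")
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  validate_sc_counts(m)
}

#' Write sparse single-cell counts in MatrixMarket layout
#' @param counts `dgCMatrix` genes x cells.
#' @param dir output directory (created if missing).
#' @export
write_sc_counts <- function(counts, dir) {
  validate_sc_counts(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

validate_sc_counts <- function(counts) {
  if (!methods::is(counts, "sparseMatrix")) stop("counts must be a sparse Matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts need gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicated gene or cell ids in counts")
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }
  counts
}

#' Read a ligand-receptor pair table from TSV
#'
#' Columns: `ligand`, `receptor`, `pair` (unique pair name such as
#' `"APP|CD74"`).
#'
#' @param path path to TSV.
#' @return data.frame with ligand, receptor, pair.
#' @export
read_lr_pairs <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "pair")
  if (!all(need %in% names(df))) {
    stop("ligand-receptor table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$pair)) stop("duplicated pair names in ", path)
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor))) {
    stop("empty ligand or receptor gene name")
  }
  df[, need]
}
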