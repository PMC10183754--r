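#' Simulate a sparse per-cell UMI count matrix with cell-type structure
#'
#' Each cell type contributes `n_cells` cells; every named gene's UMI count in
#' a cell is drawn `Poisson(mean)` from the type's per-gene mean, and a filler
#' gene `other` absorbs the remaining sequencing depth so per-cell totals are
#' close to `total_umi_mean`. Useful as ground-truth input to the ln(TPM+1)
#' harmonization stage.
#'
#' @param profiles named list, one element per cell type:
#'   `list(n_cells =, gene_means = c(geneA = ...), total_umi_mean =)`.
#' @param seed integer RNG seed; identical profiles + seed give identical
#'   matrices.
#' @return list with `counts` (a `dgCMatrix`, genes x cells) and
#'   `annotations` (data frame `cell_id`, `cell_type`).
#' @export
generate_umi_matrix <- function(profiles, seed = 1L) {
  if (length(profiles) == 0) stop("profiles must name at least one cell type")
  set.seed(as.integer(seed))
  genes <- unique(unlist(lapply(profiles, function(p) names(p$gene_means))))
  if (length(genes) == 0) stop("profiles name no genes")
  all_genes <- c(genes, "other")
  cols <- list(); ann <- list(); cid <- 0L
  for (ty in names(profiles)) {
    p <- profiles[[ty]]
    if (any(p$gene_means < 0) || p$total_umi_mean <= 0)
      stop("gene means must be >= 0 and total_umi_mean > 0")
    other_mean <- max(p$total_umi_mean - sum(p$gene_means), 0)
    means <- setNames(numeric(length(all_genes)), all_genes)
    means[names(p$gene_means)] <- p$gene_means
    means["other"] <- other_mean
    m <- matrix(rpois(length(all_genes) * p$n_cells, means),
                nrow = length(all_genes))
    cols[[ty]] <- m
    ann[[ty]] <- data.frame(
      cell_id = sprintf("cell_%05d", cid + seq_len(p$n_cells)),
      cell_type = ty, stringsAsFactors = FALSE)
    cid <- cid + p$n_cells
  }
  counts <- do.call(cbind, cols)
  ann <- do.call(rbind, ann)
  rownames(counts) <- all_genes
  colnames(counts) <- ann$cell_id
  rownames(ann) <- NULL
  list(counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                        "CsparseMatrix"), "generalMatrix"),
       annotations = ann)
}

#' Write a UMI matrix as MatrixMarket MTX plus gene/cell TSVs
#'
#' @param umi list as returned by [generate_umi_matrix()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_umi_matrix <- function(umi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(umi$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(umi$counts), file.path(dir, "genes.tsv"))
  write.table(umi$annotations, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a UMI matrix written by [write_umi_matrix()]
#'
#' @param dir directory with `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return list with `counts` (dgCMatrix) and `annotations`.
#' @export
read_umi_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  ann <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  rownames(counts) <- genes
  colnames(counts) <- ann$cell_id
  list(counts = counts, annotations = ann)
}
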