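#' Normalize a per-cell UMI count to the ln(TPM+1) scale
#'
#' `ln(gene_umi / total_umi * 1e6 + 1)`: the cell's UMI count for the gene is
#' divided by the cell's total UMIs, scaled to transcripts-per-million, and
#' natural-log transformed with a pseudocount of 1. Monotone increasing in
#' `gene_umi` for fixed `total_umi`; 0 exactly when `gene_umi` is 0.
#'
#' @param gene_umi non-negative UMI count(s) for the gene.
#' @param total_umi positive total UMI count(s) of the same cell(s).
#' @return numeric vector of ln(TPM+1) values.
#' @export
normalize_ln_tpm <- function(gene_umi, total_umi) {
  if (any(total_umi <= 0)) stop("total_umi must be > 0")
  if (any(gene_umi < 0)) stop("gene_umi must be >= 0")
  if (any(gene_umi > total_umi)) stop("gene_umi cannot exceed total_umi")
  log(gene_umi / total_umi * 1e6 + 1)
}

#' Per-dataset harmonization rules
#'
#' Datasets differ in granularity (per-cell or pre-aggregated subcluster
#' values) and in their detection rule: with a positive
#' `detection_threshold`, a gene counts as detected when its ln(TPM+1) value
#' is at or above the threshold (e.g. 1.1 for the dataset that gated at 3 on
#' its original transformed scale); with the default 0, any transcript
#' (`gene_umi >= 1`) counts.
#'
#' @param name dataset name.
#' @param granularity `"cell"` or `"subcluster"`.
#' @param detection_threshold detection gate on the ln(TPM+1) scale (>= 0).
#' @param join_key annotation column joining cells to types.
#' @return list of class `dataset_spec`.
#' @export
dataset_spec <- function(name, granularity = c("cell", "subcluster"),
                         detection_threshold = 0, join_key = "cell_id") {
  granularity <- match.arg(granularity)
  if (detection_threshold < 0) stop("detection_threshold must be >= 0")
  structure(list(name = name, granularity = granularity,
                 detection_threshold = detection_threshold,
                 join_key = join_key),
            class = "dataset_spec")
}

#' Build per-cell expression records for one gene
#'
#' @param counts genes x cells matrix (sparse or dense) of UMI counts.
#' @param gene row name of the focal gene.
#' @param annotations data frame with `cell_id` and `cell_type`; cells
#'   missing from it get `NA` type.
#' @return data frame `cell_id`, `cell_type`, `gene_umi`, `total_umi`,
#'   `tpm`, `ln_tpm1` (detection is applied separately).
#' @export
expression_records <- function(counts, gene, annotations = NULL) {
  if (!gene %in% rownames(counts)) stop("gene '", gene, "' not in matrix")
  total <- Matrix::colSums(counts)
  if (any(total <= 0)) stop("every cell must have total_umi > 0")
  g <- as.numeric(counts[gene, ])
  rec <- data.frame(cell_id = colnames(counts),
                    cell_type = NA_character_,
                    gene_umi = g, total_umi = as.numeric(total),
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    m <- match(rec$cell_id, annotations$cell_id)
    rec$cell_type <- annotations$cell_type[m]
  }
  rec$tpm <- rec$gene_umi / rec$total_umi * 1e6
  rec$ln_tpm1 <- log(rec$tpm + 1)
  rec
}

#' Flag detection according to a dataset's rule
#'
#' @param records data frame with `gene_umi` and `ln_tpm1` columns.
#' @param spec a [dataset_spec()].
#' @return `records` with a logical `detected` column; sub-threshold values
#'   are retained, only flagged.
#' @export
apply_detection <- function(records, spec = dataset_spec("default")) {
  records$detected <- if (spec$detection_threshold > 0)
    records$ln_tpm1 >= spec$detection_threshold
  else records$gene_umi >= 1
  records
}

#' Aggregate expression records by annotated cell type
#'
#' One row per cell type: number of cells, fraction detected, mean and
#' median ln(TPM+1), and quartiles. Unannotated cells are counted, excluded
#' with a warning. The per-type means recombine (weighted by n) to the global
#' mean exactly.
#'
#' @param records data frame from [expression_records()] (with `detected`
#'   from [apply_detection()]; computed with the any-transcript rule when
#'   absent).
#' @return data frame of per-type summaries; attribute `n_unannotated`
#'   carries the excluded count.
#' @export
aggregate_by_type <- function(records) {
  if (is.null(records$detected))
    records$detected <- records$gene_umi >= 1
  unann <- is.na(records$cell_type)
  if (any(unann))
    warning(sum(unann), " unannotated cells excluded from aggregation")
  r <- records[!unann, ]
  if (nrow(r) == 0) stop("no annotated cells to aggregate")
  groups <- split(r, r$cell_type)
  out <- do.call(rbind, lapply(names(groups), function(ty) {
    g <- groups[[ty]]
    q <- quantile(g$ln_tpm1, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(cell_type = ty, n = nrow(g),
               frac_detected = mean(g$detected),
               mean_ln_tpm1 = mean(g$ln_tpm1),
               median_ln_tpm1 = q[2], q25_ln_tpm1 = q[1],
               q75_ln_tpm1 = q[3], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- sum(unann)
  out
}

#' Harmonize one dataset end to end
#'
#' Per-cell granularity: builds expression records, applies the dataset's
#' detection rule and aggregates by type. Subcluster granularity: the input
#' is already one aggregated value per subcluster, so values are passed
#' through as-is (one weighted observation each) and flagged `"subcluster"`.
#'
#' @param counts genes x cells UMI matrix (per-cell granularity), or a data
#'   frame `cell_type`, `ln_tpm1`, `n` for subcluster granularity.
#' @param gene focal gene name.
#' @param annotations cell annotation data frame (`cell_id`, `cell_type`).
#' @param spec a [dataset_spec()].
#' @return list with `records` and `by_type` (summary data frame carrying a
#'   `granularity` column).
#' @export
harmonize_dataset <- function(counts, gene, annotations,
                              spec = dataset_spec("default")) {
  if (spec$granularity == "subcluster") {
    stopifnot(is.data.frame(counts),
              all(c("cell_type", "ln_tpm1") %in% names(counts)))
    by_type <- data.frame(cell_type = counts$cell_type,
                          n = if (is.null(counts$n)) 1L else counts$n,
                          frac_detected = NA_real_,
                          mean_ln_tpm1 = counts$ln_tpm1,
                          median_ln_tpm1 = counts$ln_tpm1,
                          q25_ln_tpm1 = NA_real_, q75_ln_tpm1 = NA_real_,
                          stringsAsFactors = FALSE)
    by_type$granularity <- "subcluster"
    return(list(records = counts, by_type = by_type))
  }
  rec <- expression_records(counts, gene, annotations)
  rec <- apply_detection(rec, spec)
  by_type <- aggregate_by_type(rec)
  by_type$granularity <- "cell"
  list(records = rec, by_type = by_type)
}
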