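#' Emit synthetic spliced-read evidence for a set of splice junctions
#'
#' Realizes exact junction read counts either as a text SAM file of gapped
#' alignments (one alignment per read, CIGAR `<flank>M<gap>N<flank>M` with the
#' N gap spanning exactly the requested intron) or as a junction count table
#' (TSV with columns `chrom`, `intron_start`, `intron_end`, `n_reads`,
#' 0-based half-open introns). Round-tripping through [extract_junctions()]
#' recovers the counts exactly.
#'
#' @param counts a data frame with columns `intron_start`, `intron_end`,
#'   `n_reads` (and optionally `chrom`), or a list of
#'   `list(c(start, end), n_reads)` pairs. Intron coordinates are 0-based
#'   half-open.
#' @param out output file path.
#' @param emit `"sam"` or `"tsv"`.
#' @param flank_len aligned block length on each side of the gap (SAM mode).
#' @param chrom reference name used when `counts` has no `chrom` column.
#' @return `out`, invisibly.
#' @export
generate_junction_reads <- function(counts, out, emit = c("sam", "tsv"),
                                    flank_len = 50L, chrom = "chr18") {
  emit <- match.arg(emit)
  counts <- as_junction_df(counts, chrom)
  if (any(counts$n_reads < 0)) stop("n_reads must be >= 0")
  if (any(counts$intron_end <= counts$intron_start))
    stop("introns must be non-empty half-open intervals (end > start)")
  if (any(counts$intron_start - flank_len < 0))
    stop("flank_len extends an alignment before position 0")

  if (emit == "tsv") {
    write.table(counts[, c("chrom", "intron_start", "intron_end", "n_reads")],
                out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }

  lines <- c("@HD\tVN:1.6\tSO:unsorted")
  for (ch in unique(counts$chrom)) {
    ln <- max(counts$intron_end[counts$chrom == ch]) + flank_len + 10L
    lines <- c(lines, sprintf("@SQ\tSN:%s\tLN:%d", ch, ln))
  }
  seqstr <- strrep("A", 2L * flank_len)
  for (i in seq_len(nrow(counts))) {
    n <- counts$n_reads[i]
    if (n == 0) next
    gap <- counts$intron_end[i] - counts$intron_start[i]
    pos1 <- counts$intron_start[i] - flank_len + 1L  # 1-based leftmost
    cigar <- sprintf("%dM%dN%dM", flank_len, gap, flank_len)
    lines <- c(lines,
               sprintf("jx%d_r%d\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                       i, seq_len(n), counts$chrom[i], pos1, cigar, seqstr))
  }
  writeLines(lines, out)
  invisible(out)
}

as_junction_df <- function(counts, chrom = "chr18") {
  if (length(counts) == 0)
    return(data.frame(chrom = character(0), intron_start = numeric(0),
                      intron_end = numeric(0), n_reads = numeric(0),
                      stringsAsFactors = FALSE))
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- do.call(rbind, lapply(counts, function(x)
      data.frame(intron_start = x[[1]][1], intron_end = x[[1]][2],
                 n_reads = x[[2]])))
  }
  counts <- as.data.frame(counts)
  if (is.null(counts$chrom)) counts$chrom <- rep(chrom, nrow(counts))
  stopifnot(all(c("chrom", "intron_start", "intron_end", "n_reads") %in%
                names(counts)))
  counts
}
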