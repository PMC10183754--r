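#' Exon model for a cassette-exon quantification
#'
#' Holds the ordered exon intervals of one transcript (0-based half-open) and
#' the index of the focal cassette exon, and derives the three junction
#' templates used for classification: `skip` (upstream-exon end to
#' downstream-exon start), `include_5p` (upstream-exon end to focal-exon
#' start) and `include_3p` (focal-exon end to downstream-exon start). For
#' NKCC1 (Slc12a2) exon-21 the cassette is 16 codons, i.e. 48 nt; pass
#' `expected_focal_length = 48` to enforce that.
#'
#' @param chrom chromosome name.
#' @param exons two-column matrix or data frame of `start`, `end`
#'   (0-based half-open), ordered, non-overlapping.
#' @param focal_exon 1-based index of the cassette exon within `exons`.
#' @param strand `"+"` or `"-"` (carried, not used for classification).
#' @param expected_focal_length optional length check on the focal exon (nt).
#' @return list of class `exon_model` with a `templates` element.
#' @export
exon_model <- function(chrom, exons, focal_exon, strand = "+",
                       expected_focal_length = NULL) {
  exons <- as.matrix(as.data.frame(exons)[, 1:2])
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "end")
  if (any(exons[, 2] <= exons[, 1])) stop("exons must have end > start")
  if (nrow(exons) >= 2 && any(diff(as.vector(t(exons))) < 0))
    stop("exons must be ordered and non-overlapping")
  if (focal_exon <= 1 || focal_exon >= nrow(exons))
    stop("the focal exon needs a neighbouring exon on both sides")
  if (!is.null(expected_focal_length)) {
    len <- exons[focal_exon, 2] - exons[focal_exon, 1]
    if (len != expected_focal_length)
      stop(sprintf("focal exon is %d nt, expected %d", len,
                   expected_focal_length))
  }
  templates <- list(
    skip = unname(c(exons[focal_exon - 1, 2], exons[focal_exon + 1, 1])),
    include_5p = unname(c(exons[focal_exon - 1, 2], exons[focal_exon, 1])),
    include_3p = unname(c(exons[focal_exon, 2], exons[focal_exon + 1, 1])))
  structure(list(chrom = chrom, strand = strand, exons = exons,
                 focal_exon = as.integer(focal_exon),
                 templates = templates),
            class = "exon_model")
}

#' Read an exon model from GTF or BED
#'
#' GTF: exon features of a single transcript (1-based closed, converted to
#' 0-based half-open). BED: one line per exon (already 0-based half-open).
#'
#' @param path GTF/GFF or BED file.
#' @param focal_exon 1-based cassette exon index in genomic order.
#' @param expected_focal_length optional focal-exon length check.
#' @return an [exon_model()].
#' @export
read_exon_model <- function(path, focal_exon, expected_focal_length = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_exon_model requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path))
  if (!is.null(gr$type)) gr <- gr[gr$type == "exon", ]
  gr <- gr[order(gr$start), ]
  exons <- cbind(start = gr$start - 1, end = gr$end)
  strand <- as.character(gr$strand)[1]
  if (is.na(strand) || strand == "*") strand <- "+"
  exon_model(as.character(gr$seqnames)[1], exons, focal_exon,
             strand = strand, expected_focal_length = expected_focal_length)
}

# Walk one CIGAR string; returns a matrix of N-gap (start, end) intervals in
# 0-based half-open reference coordinates given the 0-based alignment start.
cigar_gaps <- function(cigar, start0) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  if (m[[1]][1] == -1 || sum(attr(m[[1]], "match.length")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, m)[[1]]
  lens <- as.numeric(gsub("[A-Z=]", "", toks))
  typ <- gsub("\\d", "", toks)
  pos <- start0
  gaps <- NULL
  for (i in seq_along(typ)) {
    if (typ[i] == "N") {
      gaps <- rbind(gaps, c(pos, pos + lens[i]))
      pos <- pos + lens[i]
    } else if (typ[i] %in% c("M", "D", "=", "X")) {
      pos <- pos + lens[i]
    }
    # I, S, H, P consume no reference
  }
  gaps
}

#' Extract splice-junction counts from alignments or a junction table
#'
#' SAM/BAM mode: every N gap in a read's CIGAR contributes one count to the
#' junction spanning exactly that gap (reference coordinates obtained by
#' walking M/D/N/=/X operations from the alignment start). Table mode: rows
#' are aggregated per unique interval. All output intervals are 0-based
#' half-open introns.
#'
#' @param input a SAM file (text), BAM file, TSV file, or a data frame with
#'   columns `chrom`, `intron_start`, `intron_end`, `n_reads`.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"`, `"tsv"` (0-based
#'   half-open, columns as above) or `"star"` (SJ.out.tab-style: chrom,
#'   1-based first intron base, 1-based last intron base, ... , unique reads
#'   in column 7; converted on read).
#' @param region optional `list(chrom =, start =, end =)` filter (0-based
#'   half-open; junctions intersecting the window are kept).
#' @param sample_id tag stored on every row.
#' @return data frame `sample_id`, `chrom`, `intron_start`, `intron_end`,
#'   `n_reads`, one row per unique junction, with `jx_class` unset (`NA`).
#' @export
extract_junctions <- function(input, format = c("auto", "sam", "bam", "tsv",
                                                "star"),
                              region = NULL, sample_id = NA_character_) {
  format <- match.arg(format)
  if (is.data.frame(input)) {
    jx <- input
  } else {
    if (format == "auto") {
      ext <- tolower(tools::file_ext(input))
      format <- switch(ext, sam = "sam", bam = "bam",
                       tab = "star", "tsv")
    }
    jx <- switch(format,
      sam = junctions_from_sam(input),
      bam = junctions_from_bam(input),
      tsv = read.delim(input, stringsAsFactors = FALSE),
      star = {
        st <- read.delim(input, header = FALSE, stringsAsFactors = FALSE)
        data.frame(chrom = st[, 1], intron_start = st[, 2] - 1,
                   intron_end = st[, 3], n_reads = st[, 7],
                   stringsAsFactors = FALSE)
      })
  }
  need <- c("chrom", "intron_start", "intron_end", "n_reads")
  if (nrow(jx) == 0)
    jx <- data.frame(chrom = character(0), intron_start = numeric(0),
                     intron_end = numeric(0), n_reads = numeric(0))
  stopifnot(all(need %in% names(jx)))
  jx <- jx[jx$n_reads > 0, need]
  if (!is.null(region))
    jx <- jx[jx$chrom == region$chrom & jx$intron_end > region$start &
             jx$intron_start < region$end, ]
  if (nrow(jx)) {
    agg <- aggregate(n_reads ~ chrom + intron_start + intron_end, jx, sum)
    agg <- agg[order(agg$chrom, agg$intron_start, agg$intron_end), ]
  } else agg <- jx
  out <- data.frame(sample_id = rep(sample_id, nrow(agg)), agg,
                    jx_class = rep(NA_character_, nrow(agg)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

junctions_from_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) stop("malformed SAM line: ", ln)
    cigar <- f[6]
    if (cigar == "*" || !grepl("N", cigar)) next
    gaps <- cigar_gaps(cigar, as.numeric(f[4]) - 1)
    if (!is.null(gaps))
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = f[3], intron_start = gaps[, 1],
                   intron_end = gaps[, 2], n_reads = 1,
                   stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(0), intron_start = numeric(0),
                      intron_end = numeric(0), n_reads = numeric(0)))
  do.call(rbind, rows)
}

junctions_from_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  b <- Rsamtools::scanBam(path,
         param = Rsamtools::ScanBamParam(what = c("rname", "pos",
                                                  "cigar")))[[1]]
  keep <- !is.na(b$cigar) & grepl("N", b$cigar)
  rows <- list()
  for (i in which(keep)) {
    gaps <- cigar_gaps(b$cigar[i], b$pos[i] - 1)
    if (!is.null(gaps))
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = as.character(b$rname[i]),
                   intron_start = gaps[, 1], intron_end = gaps[, 2],
                   n_reads = 1, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(0), intron_start = numeric(0),
                      intron_end = numeric(0), n_reads = numeric(0)))
  do.call(rbind, rows)
}

#' Classify junctions against the cassette-exon templates
#'
#' Exact-coordinate matching (a configurable tolerance exists for noisy
#' aligners, default 0): the skip template marks exon-skipping (NKCC1b-type)
#' junctions, the two inclusion templates mark the flanking
#' exon-including (NKCC1a-type) junctions; everything else is `other`.
#'
#' @param junctions data frame from [extract_junctions()].
#' @param model an [exon_model()].
#' @param tolerance allowed coordinate deviation in nt (both ends).
#' @return `junctions` with `jx_class` set to one of
#'   `skip`, `include_5p`, `include_3p`, `other`.
#' @export
classify_junctions <- function(junctions, model, tolerance = 0) {
  if (nrow(junctions) == 0) return(junctions)
  cls <- rep("other", nrow(junctions))
  on_chrom <- junctions$chrom == model$chrom
  for (nm in names(model$templates)) {
    t <- model$templates[[nm]]
    hit <- on_chrom &
      abs(junctions$intron_start - t[1]) <= tolerance &
      abs(junctions$intron_end - t[2]) <= tolerance
    cls[hit & cls == "other"] <- nm
  }
  junctions$jx_class <- cls
  junctions
}

#' Skip/include tallies and variant fractions for a cassette exon
#'
#' Pools classified junction reads (optionally per sample) into a skip count
#' (exon-21-lacking, NKCC1b) and an include count (exon-21-containing,
#' NKCC1a), and reports the inclusion fraction `frac_a = inc / (inc + skip)`
#' with nearest-integer percentages reconciled to sum to 100
#' (`percent_b = 100 - percent_a`).
#'
#' @param junctions classified junction data frame.
#' @param inclusion_rule how to tally inclusion evidence: `"five_prime"`
#'   (upstream-flank junction only; default, avoids double counting one
#'   transcript), `"mean"` (rounded mean of both flanks) or `"sum"`.
#' @param by optional column name to compute fractions per group (e.g.
#'   `"sample_id"`); `NULL` pools everything.
#' @return data frame with columns `sample_id`, `n_skip`, `n_include`,
#'   `frac_a`, `frac_b`, `percent_a`, `percent_b`. Groups with no evidence
#'   are reported with `NA` fractions and a warning.
#' @export
compute_variant_fractions <- function(junctions,
                                      inclusion_rule = c("five_prime",
                                                         "mean", "sum"),
                                      by = NULL) {
  inclusion_rule <- match.arg(inclusion_rule)
  if (is.null(junctions$jx_class) || any(is.na(junctions$jx_class)))
    stop("junctions must be classified first (see classify_junctions)")
  groups <- if (is.null(by)) list(pooled = junctions) else
    split(junctions, junctions[[by]])
  rows <- lapply(names(groups), function(g) {
    j <- groups[[g]]
    n_skip <- sum(j$n_reads[j$jx_class == "skip"])
    n5 <- sum(j$n_reads[j$jx_class == "include_5p"])
    n3 <- sum(j$n_reads[j$jx_class == "include_3p"])
    n_include <- switch(inclusion_rule,
                        five_prime = n5,
                        mean = round((n5 + n3) / 2),
                        sum = n5 + n3)
    tot <- n_skip + n_include
    if (tot == 0) {
      warning("sample '", g, "' has no skip/include evidence; ",
              "fractions undefined")
      frac_a <- NA_real_; pa <- NA_integer_
    } else {
      frac_a <- n_include / tot
      pa <- as.integer(round(100 * frac_a))
    }
    data.frame(sample_id = g, n_skip = n_skip, n_include = n_include,
               frac_a = frac_a, frac_b = 1 - frac_a,
               percent_a = pa, percent_b = 100L - pa,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
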