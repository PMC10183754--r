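test_that("CIGAR N gaps are placed by walking reference-consuming ops", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chr1\tLN:1000",
               "r1\t0\tchr1\t101\t255\t20M100N20M\t*\t0\t0\t*\t*",
               "r2\t0\tchr1\t101\t255\t40M\t*\t0\t0\t*\t*",
               "r3\t0\tchr1\t101\t255\t10M50N10M60N10M\t*\t0\t0\t*\t*"),
             sam)
  jx <- extract_junctions(sam)
  # r1: 0-based start 100, 20M -> gap (120, 220)
  expect_equal(jx$n_reads[jx$intron_start == 120 & jx$intron_end == 220], 1)
  # r3: gaps (110, 160) and (170, 230); r2 contributes nothing
  expect_equal(jx$n_reads[jx$intron_start == 110 & jx$intron_end == 160], 1)
  expect_equal(jx$n_reads[jx$intron_start == 170 & jx$intron_end == 230], 1)
  expect_equal(sum(jx$n_reads), 3)
  expect_error(extract_junctions(
    withr::local_tempfile(fileext = ".sam", lines = c(
      "r\t0\tchr1\t10\t255\tN20M\t*\t0\t0\t*\t*"))), "CIGAR")
})

test_that("junction extraction agrees with an independent alignment parser", {
  sam <- withr::local_tempfile(fileext = ".sam")
  generate_junction_reads(list(list(c(200, 400), 5), list(c(200, 300), 3),
                               list(c(348, 400), 2)),
                          sam, emit = "sam")
  mine <- extract_junctions(sam)

  bam <- Rsamtools::asBam(sam, withr::local_tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  ga <- GenomicAlignments::readGAlignments(bam)
  ref <- as.data.frame(GenomicAlignments::junctions(ga, use.mcols = FALSE))
  agg <- aggregate(cnt ~ start + end, cbind(ref, cnt = 1), sum)
  for (i in seq_len(nrow(agg))) {
    # GenomicAlignments reports 1-based closed intron positions
    hit <- mine[mine$intron_start == agg$start[i] - 1 &
                mine$intron_end == agg$end[i], ]
    expect_equal(hit$n_reads, agg$cnt[i])
  }
  expect_equal(sum(mine$n_reads), sum(agg$cnt))
})

test_that("STAR-style junction tables are converted from 1-based closed", {
  tab <- withr::local_tempfile(fileext = ".tab")
  # chrom, first intron base (1-based), last intron base, strand, motif,
  # annotated, unique reads, multimapping, overhang
  writeLines(c("chr18\t201\t400\t1\t1\t1\t44\t0\t20",
               "chr18\t201\t300\t1\t1\t1\t14\t0\t20"), tab)
  jx <- extract_junctions(tab, format = "star")
  expect_equal(jx$n_reads[jx$intron_start == 200 & jx$intron_end == 400], 44)
  expect_equal(jx$n_reads[jx$intron_start == 200 & jx$intron_end == 300], 14)
})

test_that("junctions classify exactly against the cassette templates", {
  model <- toy_model()
  expect_equal(model$templates$skip, c(200, 400))
  expect_equal(model$templates$include_5p, c(200, 300))
  expect_equal(model$templates$include_3p, c(348, 400))
  jx <- data.frame(sample_id = "s", chrom = "chr18",
                   intron_start = c(200, 200, 348, 150),
                   intron_end = c(400, 300, 400, 450),
                   n_reads = c(5, 3, 2, 7), jx_class = NA_character_)
  out <- classify_junctions(jx, model)
  expect_equal(out$jx_class, c("skip", "include_5p", "include_3p", "other"))
  # count conservation: classification never drops reads
  expect_equal(sum(out$n_reads), sum(jx$n_reads))
})

test_that("the exon model enforces ordering and the 48-nt cassette check", {
  expect_error(exon_model("chr1", rbind(c(0, 100), c(50, 150), c(200, 300)),
                          2), "ordered")
  expect_error(exon_model("chr1", rbind(c(0, 100), c(200, 250), c(300, 400)),
                          2, expected_focal_length = 48), "48")
  expect_error(exon_model("chr1", rbind(c(0, 100), c(200, 250)), 1),
               "neighbouring")
})

test_that("variant fractions reproduce the printed cell-type percentages", {
  model <- toy_model()
  cases <- list(
    list(skip = 44, inc = 14, pct_a = 24, pct_b = 76),   # neurons
    list(skip = 116, inc = 291, pct_a = 71, pct_b = 29), # oligodendrocytes
    list(skip = 2, inc = 64, pct_a = 97, pct_b = 3))     # astrocytes
  for (cs in cases) {
    jx <- data.frame(sample_id = "pooled", chrom = "chr18",
                     intron_start = c(200, 200), intron_end = c(400, 300),
                     n_reads = c(cs$skip, cs$inc), jx_class = NA)
    vf <- compute_variant_fractions(classify_junctions(jx, model))
    expect_equal(vf$n_skip, cs$skip)
    expect_equal(vf$n_include, cs$inc)
    expect_equal(vf$percent_a, cs$pct_a)
    expect_equal(vf$percent_b, cs$pct_b)
    expect_equal(vf$frac_a + vf$frac_b, 1)
    expect_equal(vf$percent_a + vf$percent_b, 100L)
  }
})

test_that("inclusion rules: five_prime equals mean when flanks agree", {
  model <- toy_model()
  jx <- data.frame(sample_id = "s", chrom = "chr18",
                   intron_start = c(200, 200, 348),
                   intron_end = c(400, 300, 400),
                   n_reads = c(10, 7, 7), jx_class = NA)
  jx <- classify_junctions(jx, model)
  fp <- compute_variant_fractions(jx, "five_prime")
  mn <- compute_variant_fractions(jx, "mean")
  sm <- compute_variant_fractions(jx, "sum")
  expect_equal(fp$frac_a, mn$frac_a)
  expect_equal(fp$n_include, 7)
  expect_equal(sm$n_include, 14)
})

test_that("zero-evidence samples are flagged undefined with a warning", {
  jx <- data.frame(sample_id = "s", chrom = "chr18",
                   intron_start = 1, intron_end = 50, n_reads = 5,
                   jx_class = "other")
  expect_warning(vf <- compute_variant_fractions(jx), "undefined")
  expect_true(is.na(vf$frac_a))
})

test_that("exon models load from BED annotation", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr18\t100\t200\texon20\t0\t+",
               "chr18\t300\t348\texon21\t0\t+",
               "chr18\t400\t500\texon22\t0\t+"), bed)
  model <- read_exon_model(bed, focal_exon = 2, expected_focal_length = 48)
  expect_equal(model$templates$skip, c(200, 400))
  expect_equal(model$chrom, "chr18")
})
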