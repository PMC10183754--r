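test_that("an empty scene has no cells and a pure-noise DAPI channel", {
  sp <- small_scene_spec(n_cells = 0L, seed = 3L)
  sc <- generate_fish_scene(sp)
  expect_equal(nrow(sc$ground_truth$cells), 0)
  expect_equal(nrow(sc$ground_truth$spots), 0)
  # pure noise: clipped Gaussian, no structure anywhere near DAPI amplitude
  expect_lt(max(sc$images$DAPI), sp$dapi_amplitude / 2)
})

test_that("identical spec and seed give bit-identical scenes", {
  sp <- small_scene_spec(seed = 11L)
  a <- generate_fish_scene(sp)
  b <- generate_fish_scene(sp)
  expect_identical(a$images, b$images)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("per-cell speckle counts follow the requested Poisson rate", {
  sp <- scene_spec(channel_rates = c(KCC2 = 20), n_cells = 100L, seed = 7L)
  sc <- generate_fish_scene(sp)
  tc <- true_spot_counts(sc, "KCC2")
  se <- sqrt(20 / 100)
  expect_lt(abs(mean(tc) - 20), 3 * se)
  expect_equal(sum(tc),
               nrow(sc$ground_truth$spots[sc$ground_truth$spots$channel ==
                                          "KCC2", ]))
})

test_that("noiseless rendering puts the intensity maxima on the true spots", {
  sp <- scene_spec(image_height_px = 128L, image_width_px = 128L,
                   n_cells = 1L, channel_rates = c(KCC2 = 3),
                   noise_sd = 0, seed = 1L)
  sc <- generate_fish_scene(sp)
  gt <- sc$ground_truth$spots
  gt <- gt[gt$channel == "KCC2", ]
  expect_gt(nrow(gt), 0)
  found <- detect_spots(sc$images$KCC2, sp$spot_amplitude / 2,
                        min_spot_area_px = 1L)
  expect_equal(nrow(found), nrow(gt))
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((found$row - gt$row[i])^2 + (found$col - gt$col[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("spot coordinates lie inside the image and inside cell territory", {
  sp <- small_scene_spec(n_cells = 4L, seed = 5L, rates = c(KCC2 = 10))
  sc <- generate_fish_scene(sp)
  gt <- sc$ground_truth
  owned <- gt$spots[gt$spots$cell_id > 0, ]
  expect_true(all(owned$row >= 1 & owned$row <= sp$image_height_px))
  expect_true(all(owned$col >= 1 & owned$col <= sp$image_width_px))
  terr <- sp$nucleus_radius_px + sp$expansion_radius_px
  d <- sqrt((owned$row - gt$cells$row[owned$cell_id])^2 +
            (owned$col - gt$cells$col[owned$cell_id])^2)
  expect_true(all(d <= terr))
})

test_that("impossible nucleus packing fails naming the spacing constraint", {
  expect_error(generate_fish_scene(
    scene_spec(image_height_px = 128L, image_width_px = 128L,
               n_cells = 50L, min_center_spacing_px = 60, seed = 1L)),
    "min_center_spacing_px")
})

test_that("junction SAM emission uses the exact N-gap CIGAR arithmetic", {
  f <- withr::local_tempfile(fileext = ".sam")
  generate_junction_reads(list(list(c(200, 400), 1)), f, emit = "sam",
                          flank_len = 20L)
  lines <- readLines(f)
  aln <- strsplit(lines[!startsWith(lines, "@")], "\t")[[1]]
  expect_equal(as.integer(aln[4]), 181)       # 1-based leftmost: 200-20+1
  expect_equal(aln[6], "20M200N20M")          # gap length 400-200 = 200 nt
})

test_that("junction generation round-trips through extraction, both modes", {
  counts <- list(list(c(200, 400), 44), list(c(200, 300), 14))
  for (emit in c("sam", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", emit))
    generate_junction_reads(counts, f, emit = emit)
    jx <- extract_junctions(f)
    expect_equal(nrow(jx), 2)
    expect_equal(jx$n_reads[jx$intron_start == 200 & jx$intron_end == 400], 44)
    expect_equal(jx$n_reads[jx$intron_start == 200 & jx$intron_end == 300], 14)
  }
})

test_that("an empty junction list yields a valid empty file", {
  f <- withr::local_tempfile(fileext = ".sam")
  generate_junction_reads(list(), f, emit = "sam")
  expect_equal(nrow(extract_junctions(f)), 0)
})

test_that("UMI matrices honour zero means, determinism, and rate ordering", {
  p0 <- list(typeA = list(n_cells = 1L, gene_means = c(Slc12a2 = 0),
                          total_umi_mean = 1000))
  u0 <- generate_umi_matrix(p0, seed = 2L)
  expect_equal(as.numeric(u0$counts["Slc12a2", ]), 0)

  p <- list(OL = list(n_cells = 500L, gene_means = c(Slc12a2 = 5),
                      total_umi_mean = 5000),
            neuron = list(n_cells = 500L, gene_means = c(Slc12a2 = 0.5),
                          total_umi_mean = 5000))
  a <- generate_umi_matrix(p, seed = 3L)
  b <- generate_umi_matrix(p, seed = 3L)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))

  rec <- expression_records(a$counts, "Slc12a2", a$annotations)
  agg <- aggregate_by_type(apply_detection(rec))
  expect_gt(agg$mean_ln_tpm1[agg$cell_type == "OL"],
            agg$mean_ln_tpm1[agg$cell_type == "neuron"])
})

test_that("scenes and UMI matrices survive a disk round trip", {
  dir <- withr::local_tempdir()
  sp <- small_scene_spec(n_cells = 3L, seed = 9L)
  sc <- generate_fish_scene(sp)
  write_scene(sc, file.path(dir, "scene"))
  imgs <- read_scene_images(file.path(dir, "scene"))
  expect_setequal(names(imgs), names(sc$images))
  # 16-bit quantization: within one gray level on the 0..65535 scale
  expect_lt(max(abs(imgs$KCC2 - pmin(sc$images$KCC2, 65535))), 1.01)

  u <- generate_umi_matrix(list(t1 = list(n_cells = 4L,
                                          gene_means = c(g1 = 3),
                                          total_umi_mean = 100)), seed = 1L)
  write_umi_matrix(u, file.path(dir, "umi"))
  back <- read_umi_matrix(file.path(dir, "umi"))
  expect_equal(as.matrix(back$counts), as.matrix(u$counts))
  expect_equal(back$annotations$cell_type, u$annotations$cell_type)
})
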