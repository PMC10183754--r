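test_that("a blank channel yields no spots", {
  expect_equal(nrow(detect_spots(matrix(0, 32, 32), 100)), 0)
})

test_that("the 8-pixel minimum-area rule is enforced at its boundary", {
  img <- matrix(0, 32, 32)
  img[10, 11:17] <- 100                    # 7 suprathreshold pixels
  expect_equal(nrow(detect_spots(img, 50)), 0)
  img[10, 18] <- 100                       # 8th pixel
  spots <- detect_spots(img, 50)
  expect_equal(nrow(spots), 1)
  expect_equal(spots$area_px, 8)
})

test_that("speckle components are 8-connected (diagonals join)", {
  img <- matrix(0, 32, 32)
  for (i in 0:7) img[10 + i, 10 + i] <- 100   # 8 px diagonal line
  spots <- detect_spots(img, 50)
  expect_equal(nrow(spots), 1)
  expect_equal(spots$area_px, 8)
})

test_that("noiseless detection reconciles with ground truth one-to-one", {
  sp <- scene_spec(image_height_px = 256L, image_width_px = 256L,
                   n_cells = 4L, channel_rates = c(KCC2 = 6),
                   noise_sd = 0, seed = 13L)
  sc <- generate_fish_scene(sp)
  gt <- sc$ground_truth$spots
  gt <- gt[gt$channel == "KCC2", ]
  spots <- detect_spots(sc$images$KCC2, 200)
  expect_equal(nrow(spots), nrow(gt))
  for (i in seq_len(nrow(gt)))
    expect_lt(min(sqrt((spots$row - gt$row[i])^2 +
                       (spots$col - gt$col[i])^2)), 1)
})

test_that("spot pixel sets shrink as the threshold rises", {
  sp <- small_scene_spec(n_cells = 5L, seed = 17L, rates = c(KCC2 = 8))
  sc <- generate_fish_scene(sp)
  prev <- Inf
  for (t in c(150, 250, 400, 600, 900)) {
    n <- nrow(detect_spots(sc$images$KCC2, t, declump = FALSE))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("calibration picks the smallest threshold meeting the target", {
  # constructed: 100 cells, 30 dim speckles (peak 500) + 8 bright (peak 900)
  img <- matrix(0, 300, 300)
  set.seed(4)
  pos <- expand.grid(r = seq(10, 290, by = 20), c = seq(10, 290, by = 20))
  pos <- pos[sample(nrow(pos), 38), ]
  for (i in 1:30) img <- paint_disk(img, pos$r[i], pos$c[i], 2, 500)
  for (i in 31:38) img <- paint_disk(img, pos$r[i], pos$c[i], 2, 900)
  cal <- calibrate_threshold(list(img), list(grid_mask(100)),
                             target_rate = 0.1,
                             candidate_grid = c(400, 700, 1000))
  expect_equal(cal$threshold, 700)
  expect_equal(cal$achieved_rate, 0.08)
  expect_equal(cal$trace$rate, c(0.38, 0.08, 0))
  expect_true(all(diff(cal$trace$rate) <= 0))
})

test_that("calibration fails loudly when no candidate meets the target", {
  img <- matrix(0, 100, 100)
  for (r in seq(10, 90, by = 12)) img <- paint_disk(img, r, 50, 2, 500)
  err <- tryCatch(
    calibrate_threshold(list(img), list(grid_mask(10)),
                        target_rate = 0.01, candidate_grid = c(100, 200)),
    error = identity)
  expect_s3_class(err, "error")
  expect_true(!is.null(err$trace))
  expect_equal(nrow(err$trace), 2)
})

test_that("calibration refuses fewer than 10 cells", {
  expect_error(calibrate_threshold(list(matrix(0, 20, 20)),
                                   list(grid_mask(5))),
               "at least 10 cells")
})

test_that("spots are assigned by centroid containment", {
  mask <- label_mask(paint_disk(matrix(0L, 32, 32), 10, 10, 5, 3))
  spots <- data.frame(channel = "KCC2", row = c(10, 30), col = c(10, 30),
                      area_px = 9L, peak = 500, mean = 400, cell_label = 0L)
  out <- assign_spots_to_cells(spots, mask)
  expect_equal(out$cell_label, c(3L, 0L))
  bad <- spots; bad$row[1] <- 40
  expect_error(assign_spots_to_cells(bad, mask), "outside")
})

test_that("every retained spot is assigned exactly once (conservation)", {
  sp <- small_scene_spec(n_cells = 6L, seed = 19L, rates = c(KCC2 = 8))
  sc <- generate_fish_scene(sp)
  nuc <- segment_nuclei(sc$images$DAPI)
  ex <- expand_cells(nuc, 10)
  spots <- assign_spots_to_cells(detect_spots(sc$images$KCC2, 250), ex)
  counts <- count_spots_per_cell(spots, n_objects(ex))
  expect_equal(sum(counts), nrow(spots) - sum(spots$cell_label == 0))
})

test_that("per-cell tallies equal ground-truth counts on a clean scene", {
  sp <- small_scene_spec(n_cells = 6L, seed = 23L, rates = c(KCC2 = 8))
  sc <- generate_fish_scene(sp)
  nuc <- segment_nuclei(sc$images$DAPI)
  ex <- expand_cells(nuc, 10)
  spots <- assign_spots_to_cells(detect_spots(sc$images$KCC2, 250), ex)
  counts <- count_spots_per_cell(spots, n_objects(ex))
  map <- match_cells_to_truth(ex, sc)
  expect_equal(counts[map], true_spot_counts(sc, "KCC2"))
})
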