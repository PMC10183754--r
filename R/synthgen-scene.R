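#' Declarative description of a synthetic RNAscope scene
#'
#' A `scene_spec` holds everything needed to render a multi-channel
#' fluorescence scene with known ground truth: image geometry, nucleus
#' placement constraints, per-channel Poisson speckle rates (optionally per
#' cell type), point-spread parameters and noise. Identical spec + seed give
#' bit-identical scenes.
#'
#' Cell types carry a `proportion` and a named vector of per-channel Poisson
#' means (`rates`, speckles/cell); the default emulates a mixed field of
#' KCC2-rich neurons and KCC2-negative non-neuronal cells. A negative-control
#' channel (`"negctrl"`) is always rendered: it contains
#' `Poisson(background_spot_rate * n_cells)` false speckles placed uniformly,
#' with peak amplitudes drawn from a bimodal mix (`negctrl_amplitudes`,
#' `negctrl_weights`) emulating dim off-target binding plus occasional bright
#' artifacts.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param pixel_size_um micrometres per pixel (default 0.16, i.e. a 10 px
#'   radial expansion corresponds to 1.6 um).
#' @param n_cells number of nuclei to place.
#' @param nucleus_radius_px nucleus disk radius in pixels.
#' @param min_center_spacing_px minimum Euclidean distance between nucleus
#'   centers; placement fails with an error if this cannot be honoured.
#' @param expansion_radius_px cytoplasmic expansion radius used to bound
#'   speckle placement (speckles are owned unambiguously by their cell).
#' @param channel_rates named vector of Poisson mean speckles/cell; if given,
#'   overrides `cell_types` with a single type `"cell"`.
#' @param cell_types named list; each element is `list(proportion=, rates=)`.
#' @param background_spot_rate expected false speckles per cell on the
#'   negative-control channel.
#' @param negctrl_amplitudes,negctrl_weights bimodal amplitude mix for
#'   negative-control speckles.
#' @param spot_sigma_px isotropic Gaussian PSF sigma for speckles.
#' @param spot_amplitude peak intensity of probe speckles.
#' @param dapi_amplitude nucleus disk intensity on the DAPI channel.
#' @param noise_sd additive Gaussian noise sd (all channels).
#' @param min_spot_spacing_px preferred minimum distance between speckles of
#'   one cell on one channel (best-candidate placement; soft constraint).
#' @param seed integer RNG seed.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_height_px = 1024L, image_width_px = 1024L,
                       pixel_size_um = 0.16, n_cells = 100L,
                       nucleus_radius_px = 15, min_center_spacing_px = 54,
                       expansion_radius_px = 10,
                       channel_rates = NULL,
                       cell_types = list(
                         neuron       = list(proportion = 0.5,
                                             rates = c(KCC2 = 20, NKCC1 = 4)),
                         non_neuronal = list(proportion = 0.5,
                                             rates = c(KCC2 = 0, NKCC1 = 8))),
                       background_spot_rate = 0.3,
                       negctrl_amplitudes = c(400, 900),
                       negctrl_weights = c(0.85, 0.15),
                       spot_sigma_px = 1.5, spot_amplitude = 800,
                       dapi_amplitude = 3000, noise_sd = 40,
                       min_spot_spacing_px = 7, seed = 1L) {
  if (!is.null(channel_rates)) {
    if (is.null(names(channel_rates)) || any(!nzchar(names(channel_rates))))
      stop("channel_rates must be a named vector")
    cell_types <- list(cell = list(proportion = 1, rates = channel_rates))
  }
  spec <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
    nucleus_radius_px = nucleus_radius_px,
    min_center_spacing_px = min_center_spacing_px,
    expansion_radius_px = expansion_radius_px,
    cell_types = cell_types,
    background_spot_rate = background_spot_rate,
    negctrl_amplitudes = negctrl_amplitudes,
    negctrl_weights = negctrl_weights,
    spot_sigma_px = spot_sigma_px, spot_amplitude = spot_amplitude,
    dapi_amplitude = dapi_amplitude, noise_sd = noise_sd,
    min_spot_spacing_px = min_spot_spacing_px, seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(s) {
  stopifnot(s$image_height_px > 0, s$image_width_px > 0, s$pixel_size_um > 0,
            s$n_cells >= 0, s$nucleus_radius_px > 0,
            s$min_center_spacing_px > 0, s$expansion_radius_px >= 0,
            s$background_spot_rate >= 0, s$spot_sigma_px > 0,
            s$noise_sd >= 0)
  props <- vapply(s$cell_types, function(ct) ct$proportion, numeric(1))
  if (any(props < 0) || abs(sum(props) - 1) > 1e-8)
    stop("cell_type proportions must be non-negative and sum to 1")
  for (ct in s$cell_types)
    if (any(ct$rates < 0)) stop("channel rates must be >= 0")
  if (abs(sum(s$negctrl_weights) - 1) > 1e-8)
    stop("negctrl_weights must sum to 1")
  invisible(s)
}

#' Names of probe channels defined by a scene spec
#' @param spec a `scene_spec`.
#' @return character vector of probe channel names (excludes DAPI, negctrl).
#' @export
scene_channels <- function(spec) {
  unique(unlist(lapply(spec$cell_types, function(ct) names(ct$rates))))
}

# Place n points with pairwise distance >= spacing inside the margin box.
# Rejection sampling with a bounded retry budget.
place_centers <- function(n, h, w, margin, spacing, max_attempts = 20000L) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  if (h - 2 * margin <= 0 || w - 2 * margin <= 0)
    stop("image too small for the nucleus margin")
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (att in seq_len(max_attempts)) {
    cand <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
    if (placed == 0L ||
        min(sqrt((pts[seq_len(placed), 1] - cand[1])^2 +
                 (pts[seq_len(placed), 2] - cand[2])^2)) >= spacing) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      if (placed == n) return(pts)
    }
  }
  stop(sprintf(paste0("could not place %d nuclei with min_center_spacing_px",
                      " = %g in a %dx%d image after %d attempts"),
               n, spacing, h, w, max_attempts))
}

# Best-candidate sampling of k points in a disk, preferring pairwise
# distance >= spacing (soft: the best candidate is kept when the budget
# is exhausted, so counts are always realized exactly).
place_spots_in_disk <- function(k, center, rmax, spacing, n_cand = 40L) {
  if (k == 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, k, 2)
  for (i in seq_len(k)) {
    best <- NULL; best_d <- -Inf
    for (j in seq_len(n_cand)) {
      r <- rmax * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
      cand <- center + r * c(cos(th), sin(th))
      d <- if (i == 1) Inf else
        min(sqrt((pts[seq_len(i - 1), 1] - cand[1])^2 +
                 (pts[seq_len(i - 1), 2] - cand[2])^2))
      if (d >= spacing) { best <- cand; break }
      if (d > best_d) { best <- cand; best_d <- d }
    }
    pts[i, ] <- best
  }
  pts
}

# Render isotropic Gaussians (one per row of df: row, col, amplitude) onto a
# fresh h x w canvas. Subassignment on the local matrix stays in place, so
# rendering is linear in total patch area, not in image size per spot.
render_gaussians <- function(h, w, df, sigma) {
  img <- matrix(0, h, w)
  rad <- ceiling(4 * sigma)
  for (i in seq_len(nrow(df))) {
    r <- df$row[i]; c <- df$col[i]; A <- df$amplitude[i]
    r0 <- max(1L, floor(r) - rad); r1 <- min(h, floor(r) + rad + 1L)
    c0 <- max(1L, floor(c) - rad); c1 <- min(w, floor(c) + rad + 1L)
    ri <- r0:r1; ci <- c0:c1
    img[ri, ci] <- img[ri, ci] +
      A * exp(-outer((ri - r)^2, (ci - c)^2, "+") / (2 * sigma^2))
  }
  img
}

render_disks <- function(h, w, centers, radius, A) {
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    r <- centers[i, 1]; c <- centers[i, 2]
    r0 <- max(1L, floor(r - radius)); r1 <- min(h, ceiling(r + radius))
    c0 <- max(1L, floor(c - radius)); c1 <- min(w, ceiling(c + radius))
    ri <- r0:r1; ci <- c0:c1
    d2 <- outer((ri - r)^2, (ci - c)^2, "+")
    img[ri, ci] <- img[ri, ci] + A * (d2 <= radius^2)
  }
  img
}

#' Render a synthetic multi-channel RNAscope scene with exact ground truth
#'
#' Places non-overlapping nuclei, draws per-cell speckle counts from the
#' per-channel Poisson rates of each cell's type, renders speckles as
#' isotropic Gaussians within the nucleus-plus-expansion territory of their
#' owning cell (kept clear of the equidistant boundary to neighbours, so
#' centroid assignment against the expanded mask is unambiguous), renders a
#' uniform negative-control channel at the configured false-speckle rate, and
#' adds Gaussian read-out noise. Every placement is recorded in the returned
#' ground truth.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `fish_scene` with elements `images` (named list of
#'   numeric matrices: `DAPI`, one per probe channel, `negctrl`),
#'   `ground_truth` (list with `cells` and `spots` data frames) and `spec`.
#' @export
generate_fish_scene <- function(spec) {
  validate_scene_spec(spec)
  set.seed(spec$seed)
  h <- spec$image_height_px; w <- spec$image_width_px
  channels <- scene_channels(spec)
  terr <- spec$nucleus_radius_px + spec$expansion_radius_px
  margin <- terr + 3

  centers <- place_centers(spec$n_cells, h, w, margin,
                           spec$min_center_spacing_px)

  # deterministic type assignment: proportions realized as exactly as possible
  types <- character(0)
  if (spec$n_cells > 0) {
    props <- vapply(spec$cell_types, function(ct) ct$proportion, numeric(1))
    n_per <- floor(props * spec$n_cells)
    rem <- spec$n_cells - sum(n_per)
    if (rem > 0) {
      extra <- order(props * spec$n_cells - n_per, decreasing = TRUE)[seq_len(rem)]
      n_per[extra] <- n_per[extra] + 1L
    }
    types <- sample(rep(names(spec$cell_types), times = n_per))
  }

  cells <- data.frame(cell_id = seq_len(spec$n_cells),
                      row = centers[, 1], col = centers[, 2],
                      nucleus_radius_px = rep(spec$nucleus_radius_px,
                                              spec$n_cells),
                      true_class = types,
                      stringsAsFactors = FALSE)

  # speckles: owned placements within the cell territory, clear of the
  # equidistant boundary to any neighbouring cell by >= 2*sigma
  rmax <- max(terr - 3, spec$nucleus_radius_px / 2)
  spot_rows <- list()
  for (i in seq_len(spec$n_cells)) {
    rates <- spec$cell_types[[types[i]]]$rates
    for (ch in channels) {
      lam <- if (ch %in% names(rates)) rates[[ch]] else 0
      k <- rpois(1, lam)
      if (k == 0) next
      pts <- place_spots_in_disk(k, centers[i, ], rmax,
                                 spec$min_spot_spacing_px)
      if (spec$n_cells > 1) {
        d_own <- sqrt(rowSums((pts - matrix(centers[i, ], k, 2,
                                            byrow = TRUE))^2))
        others <- centers[-i, , drop = FALSE]
        for (s in seq_len(k)) {
          d_oth <- min(sqrt((others[, 1] - pts[s, 1])^2 +
                            (others[, 2] - pts[s, 2])^2))
          if (d_oth - d_own[s] < 2 * spec$spot_sigma_px) {
            # pull the spot toward its own center until the margin holds
            v <- pts[s, ] - centers[i, ]
            pts[s, ] <- centers[i, ] + v * 0.5
          }
        }
      }
      spot_rows[[length(spot_rows) + 1L]] <-
        data.frame(cell_id = i, channel = ch, row = pts[, 1], col = pts[, 2],
                   amplitude = spec$spot_amplitude, stringsAsFactors = FALSE)
    }
  }

  # negative control: uniform false speckles, bimodal amplitude mix
  n_bg <- rpois(1, spec$background_spot_rate * spec$n_cells)
  if (n_bg > 0) {
    amps <- sample(spec$negctrl_amplitudes, n_bg, replace = TRUE,
                   prob = spec$negctrl_weights)
    spot_rows[[length(spot_rows) + 1L]] <-
      data.frame(cell_id = 0L, channel = "negctrl",
                 row = runif(n_bg, 1, h), col = runif(n_bg, 1, w),
                 amplitude = amps, stringsAsFactors = FALSE)
  }

  spots <- if (length(spot_rows)) do.call(rbind, spot_rows) else
    data.frame(cell_id = integer(0), channel = character(0),
               row = numeric(0), col = numeric(0), amplitude = numeric(0),
               stringsAsFactors = FALSE)

  imgs <- list(DAPI = render_disks(h, w, centers, spec$nucleus_radius_px,
                                   spec$dapi_amplitude))
  for (ch in c(channels, "negctrl"))
    imgs[[ch]] <- render_gaussians(h, w, spots[spots$channel == ch, ],
                                   spec$spot_sigma_px)

  if (spec$noise_sd > 0)
    imgs <- lapply(imgs, function(im)
      pmax(im + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0))

  structure(list(images = imgs,
                 ground_truth = list(cells = cells, spots = spots),
                 spec = spec),
            class = "fish_scene")
}

#' True per-cell speckle counts of a scene
#'
#' @param scene a `fish_scene`.
#' @param channel probe channel name.
#' @return integer vector of length `n_cells` (cell id order) of true counts.
#' @export
true_spot_counts <- function(scene, channel) {
  gt <- scene$ground_truth
  n <- nrow(gt$cells)
  sp <- gt$spots[gt$spots$channel == channel & gt$spots$cell_id > 0, ]
  counts <- tabulate(sp$cell_id, nbins = n)
  as.integer(counts)
}

#' Match segmented mask labels to ground-truth cells
#'
#' Segmentation labels objects in raster-scan order while ground truth
#' numbers cells in placement order; this maps each true cell to the mask
#' label whose object contains its nucleus center.
#'
#' @param mask a [label_mask()] (nuclei or expanded cells).
#' @param scene the `fish_scene` the mask was computed from.
#' @return integer vector, one mask label per ground-truth cell (0 when the
#'   center falls on background).
#' @export
match_cells_to_truth <- function(mask, scene) {
  cells <- scene$ground_truth$cells
  if (nrow(cells) == 0) return(integer(0))
  as.integer(mask[cbind(round(cells$row), round(cells$col))])
}

#' @export
print.fish_scene <- function(x, ...) {
  cat(sprintf("fish_scene: %dx%d px, %d cells, channels: %s\n",
              x$spec$image_height_px, x$spec$image_width_px,
              nrow(x$ground_truth$cells),
              paste(names(x$images), collapse = ", ")))
  invisible(x)
}

#' Write a scene to disk as 16-bit TIFFs with a JSON sidecar
#'
#' One TIFF per channel plus `channels.json` naming them, and the ground
#' truth as `ground_truth_spots.csv`, `ground_truth_cells.csv` and
#' `ground_truth.json`.
#'
#' @param scene a `fish_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  max_i <- 65535
  files <- list()
  for (ch in names(scene$images)) {
    f <- file.path(dir, paste0(ch, ".tiff"))
    img <- pmin(pmax(scene$images[[ch]], 0), max_i) / max_i
    tiff::writeTIFF(img, f, bits.per.sample = 16L)
    files[[ch]] <- basename(f)
  }
  jsonlite::write_json(files, file.path(dir, "channels.json"),
                       auto_unbox = TRUE)
  gt <- scene$ground_truth
  write.csv(gt$spots, file.path(dir, "ground_truth_spots.csv"),
            row.names = FALSE)
  write.csv(gt$cells, file.path(dir, "ground_truth_cells.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(cells = gt$cells, spots = gt$spots),
                       file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Read a scene's channel images written by [write_scene()]
#'
#' @param dir directory containing `channels.json` and the channel TIFFs.
#' @return named list of numeric matrices on the original intensity scale.
#' @export
read_scene_images <- function(dir) {
  files <- jsonlite::read_json(file.path(dir, "channels.json"),
                               simplifyVector = TRUE)
  lapply(files, function(f) {
    m <- tiff::readTIFF(file.path(dir, f))
    m * 65535
  })
}
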