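# 8-connected components of a logical matrix. bwlabel in EBImage is
# 4-connected; diagonal contact must join speckle components, so the label
# graph is built explicitly over suprathreshold pixels.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) return(lab)
  id <- matrix(0L, h, w)
  id[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  edges <- list()
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- rr + sh[1]; nc <- cc + sh[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    if (!any(ok)) next
    nid <- id[cbind(nr[ok], nc[ok])]
    has <- nid > 0L
    if (any(has))
      edges[[length(edges) + 1L]] <- cbind(id[idx][ok][has], nid[has])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  relabel_raster(lab)
}

#' Detect fluorescent speckles in a probe channel
#'
#' Speckles are 8-connected components of pixels at or above the intensity
#' threshold, optionally after white-top-hat background suppression.
#' With `declump = TRUE` (default) touching speckles are separated by an
#' intensity watershed within the suprathreshold mask, so two nearby mRNA
#' speckles joined by a dim waist still count as two. Components smaller
#' than `min_spot_area_px` (default 8 px) are discarded as detection
#' artifacts. The spot count is non-increasing in the threshold.
#'
#' @param channel numeric intensity matrix.
#' @param intensity_threshold absolute threshold (>= 0); pixels `>=` the
#'   threshold are foreground.
#' @param min_spot_area_px minimum retained component area in pixels.
#' @param method `"threshold"` (plain) or `"tophat"` (white top-hat with a
#'   disk brush of `tophat_size` before thresholding).
#' @param tophat_size brush diameter for the top-hat filter.
#' @param declump split touching speckles by intensity watershed.
#' @param declump_tolerance minimum peak-to-waist depth for a split
#'   (intensity units); defaults to half the threshold, deep enough that
#'   read-out noise inside one speckle never splits it.
#' @param channel_name stored in the `channel` column of the result.
#' @return data frame with one row per speckle: `channel`, `row`, `col`
#'   (intensity-weighted centroid is not used; the centroid is the pixel
#'   mean), `area_px`, `peak`, `mean`, `cell_label` (0 until assigned).
#' @export
detect_spots <- function(channel, intensity_threshold,
                         min_spot_area_px = 8L,
                         method = c("threshold", "tophat"),
                         tophat_size = 7L,
                         declump = TRUE,
                         declump_tolerance = intensity_threshold / 2,
                         channel_name = NA_character_) {
  method <- match.arg(method)
  if (intensity_threshold < 0) stop("intensity_threshold must be >= 0")
  img <- matrix(as.numeric(channel), nrow(channel), ncol(channel))
  if (method == "tophat") {
    brush <- EBImage::makeBrush(tophat_size, shape = "disc")
    img <- as.matrix(EBImage::whiteTopHat(EBImage::Image(img), brush))
  }
  mask <- img >= intensity_threshold
  lab <- if (declump && intensity_threshold > 0 && any(mask)) {
    relabel_raster(as.matrix(EBImage::watershed(
      EBImage::Image(img * mask), tolerance = declump_tolerance, ext = 1)))
  } else {
    label_components8(mask)
  }
  empty <- data.frame(channel = character(0), row = numeric(0),
                      col = numeric(0), area_px = integer(0),
                      peak = numeric(0), mean = numeric(0),
                      cell_label = integer(0), stringsAsFactors = FALSE)
  n <- max(lab)
  if (n == 0L) return(empty)
  px <- which(lab > 0L, arr.ind = TRUE)
  L <- lab[px]
  v <- img[px]
  area <- tabulate(L, nbins = n)
  keep <- which(area >= min_spot_area_px)
  if (length(keep) == 0L) return(empty)
  rowm <- vapply(split(px[, 1], L), mean, numeric(1))
  colm <- vapply(split(px[, 2], L), mean, numeric(1))
  peak <- vapply(split(v, L), max, numeric(1))
  meanv <- vapply(split(v, L), mean, numeric(1))
  out <- data.frame(channel = channel_name,
                    row = rowm[as.character(keep)],
                    col = colm[as.character(keep)],
                    area_px = area[keep],
                    peak = peak[as.character(keep)],
                    mean = meanv[as.character(keep)],
                    cell_label = 0L, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Calibrate the speckle intensity threshold on negative-control images
#'
#' Chooses the smallest candidate threshold whose pooled negative-control
#' speckle rate (total retained speckles across all images divided by total
#' segmented cells) does not exceed `target_rate`. The default target of 0.1
#' speckles/cell is the accepted level of unspecific background staining for
#' RNAscope (one speckle per 10 cells).
#'
#' When no candidate grid is given, candidates are the quantiles (default
#' 200 steps) of the pooled negative-control pixel intensities above a noise
#' floor (their 99.9th percentile), with the floor itself included as the
#' lowest candidate. Restricting to suprathreshold pixels keeps the grid
#' resolved in the speckle intensity range instead of being dominated by
#' background noise; taking the smallest passing candidate preserves
#' sensitivity.
#'
#' @param negctrl_images list of numeric matrices (negative-control channel).
#' @param cell_masks list of [label_mask()]s matching the images (expanded
#'   cell masks; the cell count is the number of objects).
#' @param target_rate maximum acceptable speckles/cell.
#' @param candidate_grid optional strictly increasing numeric vector.
#' @param n_candidates quantile steps for the automatic grid.
#' @param min_spot_area_px passed to [detect_spots()].
#' @return list of class `calibration_result`: `threshold`, `achieved_rate`,
#'   `n_cells`, `target_rate`, and `trace` (data frame of threshold, rate).
#' @export
calibrate_threshold <- function(negctrl_images, cell_masks,
                                target_rate = 0.1, candidate_grid = NULL,
                                n_candidates = 200L, min_spot_area_px = 8L) {
  if (!is.list(negctrl_images)) negctrl_images <- list(negctrl_images)
  if (!is.list(cell_masks)) cell_masks <- list(cell_masks)
  stopifnot(length(negctrl_images) == length(cell_masks))
  n_cells <- sum(vapply(cell_masks, n_objects, integer(1)))
  if (n_cells < 10L)
    stop("calibration requires at least 10 cells across the masks")
  if (is.null(candidate_grid)) {
    pool <- unlist(lapply(negctrl_images, as.numeric))
    floor_t <- quantile(pool, 0.999, names = FALSE)
    fg <- pool[pool >= floor_t]
    candidate_grid <- if (length(fg) == 0) floor_t else
      sort(unique(c(floor_t,
                    quantile(fg, seq(0, 1, length.out = n_candidates),
                             names = FALSE) + 1e-9)))
  }
  if (is.unsorted(candidate_grid, strictly = TRUE))
    stop("candidate_grid must be strictly increasing")
  trace <- data.frame(threshold = candidate_grid,
                      rate = NA_real_)
  chosen <- NA_real_; achieved <- NA_real_
  for (i in seq_along(candidate_grid)) {
    t <- candidate_grid[i]
    total <- sum(vapply(negctrl_images, function(im)
      nrow(detect_spots(im, t, min_spot_area_px)), numeric(1)))
    trace$rate[i] <- total / n_cells
    if (is.na(chosen) && trace$rate[i] <= target_rate) {
      chosen <- t; achieved <- trace$rate[i]
      # later candidates only raise the threshold; fill the trace anyway
    }
  }
  if (is.na(chosen)) {
    cond <- simpleError(sprintf(
      "no candidate threshold achieves a negative-control rate <= %g (best %g)",
      target_rate, min(trace$rate)))
    cond$trace <- trace
    stop(cond)
  }
  structure(list(threshold = chosen, achieved_rate = achieved,
                 n_cells = n_cells, target_rate = target_rate,
                 trace = trace),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration: threshold %.4g, %.3f speckles/cell over %d cells (target %g)\n",
    x$threshold, x$achieved_rate, x$n_cells, x$target_rate))
  invisible(x)
}

#' Assign detected speckles to cells by centroid containment
#'
#' Each speckle receives the label of the expanded-mask pixel under its
#' centroid (rounded to the nearest pixel); 0 means background. This mirrors
#' parent-from-centroid object relating: a speckle straddling two cells is
#' decided by its centroid, never split.
#'
#' @param spots data frame from [detect_spots()].
#' @param cells a [label_mask()] with the same shape as the source image.
#' @return `spots` with `cell_label` filled.
#' @export
assign_spots_to_cells <- function(spots, cells) {
  if (nrow(spots) == 0) return(spots)
  r <- round(spots$row); c <- round(spots$col)
  if (any(r < 1 | r > nrow(cells) | c < 1 | c > ncol(cells)))
    stop("spot centroid outside the image")
  spots$cell_label <- as.integer(cells[cbind(r, c)])
  spots
}

#' Tally assigned speckles per cell
#'
#' @param spots assigned spots data frame.
#' @param n_cells number of cells (labels 1..n_cells).
#' @return integer vector of per-cell speckle counts.
#' @export
count_spots_per_cell <- function(spots, n_cells) {
  s <- spots[spots$cell_label > 0L, ]
  as.integer(tabulate(s$cell_label, nbins = n_cells))
}
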