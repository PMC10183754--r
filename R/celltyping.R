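#' Pipeline configuration
#'
#' Collects the constants of the RNAscope quantification pipeline: the 10 px
#' (1.6 um) cytoplasmic expansion, the 8 px minimum speckle area, the
#' 0.1 speckles/cell negative-control background target, the marker rule
#' (>= 10 KCC2 speckles = neuron, 0 = non-neuronal, 1-9 = unclassified) and
#' the NKCC1 expression bins (0 none, 1-4 low, 5-10 moderate, 11-15 high,
#' >= 16 very high).
#'
#' @param expansion_radius_px cytoplasmic expansion radius.
#' @param min_spot_area_px minimum speckle area.
#' @param target_background_rate negative-control speckles/cell target.
#' @param neuron_min_kcc2 minimum KCC2 speckles to call a neuron.
#' @param nonneuronal_max_kcc2 maximum KCC2 speckles to call non-neuronal.
#' @param smoothing_sigma,min_object_area_px,split_touching nucleus
#'   segmentation parameters (see [segment_nuclei()]).
#' @param neuron_marker_channel,nkcc1_channel,negctrl_channel channel names.
#' @param seed integer seed for any stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expansion_radius_px = 10,
                            min_spot_area_px = 8L,
                            target_background_rate = 0.1,
                            neuron_min_kcc2 = 10L,
                            nonneuronal_max_kcc2 = 0L,
                            smoothing_sigma = 2,
                            min_object_area_px = 50L,
                            split_touching = TRUE,
                            neuron_marker_channel = "KCC2",
                            nkcc1_channel = "NKCC1",
                            negctrl_channel = "negctrl",
                            seed = 1L) {
  stopifnot(expansion_radius_px >= 0, min_spot_area_px >= 0,
            target_background_rate >= 0, neuron_min_kcc2 >= 0,
            nonneuronal_max_kcc2 >= 0,
            nonneuronal_max_kcc2 < neuron_min_kcc2)
  structure(list(expansion_radius_px = expansion_radius_px,
                 min_spot_area_px = as.integer(min_spot_area_px),
                 target_background_rate = target_background_rate,
                 neuron_min_kcc2 = as.integer(neuron_min_kcc2),
                 nonneuronal_max_kcc2 = as.integer(nonneuronal_max_kcc2),
                 smoothing_sigma = smoothing_sigma,
                 min_object_area_px = as.integer(min_object_area_px),
                 split_touching = split_touching,
                 neuron_marker_channel = neuron_marker_channel,
                 nkcc1_channel = nkcc1_channel,
                 negctrl_channel = negctrl_channel,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

expression_bin_levels <- c("none", "low", "moderate", "high", "very_high")
cell_class_levels <- c("neuron", "non_neuronal", "unclassified")

#' Classify cells as neurons or non-neuronal from KCC2 marker counts
#'
#' A cell with `neuron_min_kcc2` (default 10) or more KCC2 speckles is a
#' neuron; a cell with zero KCC2 speckles is non-neuronal; anything between
#' is left unclassified and excluded from neuron/non-neuron denominators.
#'
#' @param records data frame with a `kcc2_count` column of non-negative
#'   integers.
#' @param config a [pipeline_config()].
#' @return `records` with a `cell_class` factor column.
#' @export
classify_cells <- function(records, config = pipeline_config()) {
  k <- records$kcc2_count
  if (any(k < 0)) stop("kcc2_count must be >= 0")
  cls <- ifelse(k >= config$neuron_min_kcc2, "neuron",
         ifelse(k <= config$nonneuronal_max_kcc2, "non_neuronal",
                "unclassified"))
  records$cell_class <- factor(cls, levels = cell_class_levels)
  records
}

#' Bin NKCC1 speckle counts into expression levels
#'
#' 0 speckles = none; 1-4 = low; 5-10 = moderate; 11-15 = high;
#' 16 or more (">15 speckles per cell") = very high.
#'
#' @param records data frame with an `nkcc1_count` column.
#' @param config a [pipeline_config()] (reserved; bins are fixed).
#' @return `records` with an `expression_bin` ordered factor column.
#' @export
bin_expression <- function(records, config = pipeline_config()) {
  n <- records$nkcc1_count
  if (any(n < 0)) stop("nkcc1_count must be >= 0")
  bin <- cut(n, breaks = c(-Inf, 0, 4, 10, 15, Inf),
             labels = expression_bin_levels, right = TRUE)
  records$expression_bin <- factor(as.character(bin),
                                   levels = expression_bin_levels,
                                   ordered = TRUE)
  records
}

#' Summarize per-cell records by group
#'
#' For each group: number of cells, fraction with at least one NKCC1 speckle,
#' fraction in the very-high bin (>15 speckles), the expression-bin
#' histogram, and mean/median NKCC1 counts. Requested groups with no records
#' are omitted with a warning.
#'
#' @param records data frame with `nkcc1_count` and (if grouping on them)
#'   `region` / `cell_class` / `expression_bin` columns; `expression_bin` is
#'   computed on the fly when absent.
#' @param group_by character vector of grouping columns (default
#'   `"cell_class"`; use `c("region", "cell_class")` for region summaries, or
#'   `character(0)` to pool everything).
#' @return data frame, one row per group.
#' @export
summarize_cells <- function(records, group_by = "cell_class") {
  if (nrow(records) == 0)
    stop("summarize_cells needs at least one record")
  if (is.null(records$expression_bin))
    records <- bin_expression(records)
  key <- if (length(group_by) == 0) rep("all", nrow(records)) else
    interaction(records[group_by], drop = FALSE, sep = "/")
  groups <- split(records, key, drop = FALSE)
  present <- vapply(groups, nrow, integer(1)) > 0
  if (any(!present))
    warning("omitting empty groups: ",
            paste(names(groups)[!present], collapse = ", "))
  groups <- groups[present]
  rows <- lapply(names(groups), function(g) {
    r <- groups[[g]]
    hist <- table(factor(r$expression_bin, levels = expression_bin_levels))
    out <- data.frame(group = g, n = nrow(r),
                      frac_nkcc1_pos = mean(r$nkcc1_count >= 1),
                      frac_very_high = mean(r$expression_bin == "very_high"),
                      mean_nkcc1 = mean(r$nkcc1_count),
                      median_nkcc1 = median(r$nkcc1_count),
                      stringsAsFactors = FALSE)
    for (b in expression_bin_levels)
      out[[paste0("bin_", b)]] <- as.integer(hist[[b]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full RNAscope quantification pipeline on one or more scenes
#'
#' Segments nuclei from DAPI, expands them by the configured radius,
#' calibrates the speckle intensity threshold on the negative-control
#' channel(s) so the pooled background rate is at most the target
#' (0.1 speckles/cell), detects and assigns speckles on the marker and NKCC1
#' channels, classifies cells, bins expression and summarizes.
#'
#' @param scenes a `fish_scene`, a named list of channel matrices (must
#'   include `DAPI`), or a list of either.
#' @param config a [pipeline_config()].
#' @param regions optional character vector of region tags, one per scene.
#' @param intensity_threshold optional fixed threshold; skips calibration.
#' @param out_dir optional directory; when given, per-cell records, the
#'   summary and the calibration trace are written there as CSV/JSON.
#' @return list of class `rnascope_result`: `cells` (per-cell records),
#'   `summary`, `calibration`, `masks` (expanded label masks per scene).
#' @export
run_rnascope_pipeline <- function(scenes, config = pipeline_config(),
                                  regions = NULL,
                                  intensity_threshold = NULL,
                                  out_dir = NULL) {
  if (inherits(scenes, "fish_scene") ||
      (is.list(scenes) && !is.null(names(scenes)) && "DAPI" %in% names(scenes)))
    scenes <- list(scenes)
  bundles <- lapply(scenes, function(s)
    if (inherits(s, "fish_scene")) s$images else s)
  for (b in bundles)
    if (!"DAPI" %in% names(b))
      stop("stage segment_nuclei: every bundle needs a DAPI channel")
  if (is.null(regions)) regions <- sprintf("scene_%d", seq_along(bundles))
  set.seed(config$seed)

  masks <- lapply(bundles, function(b) {
    nuc <- segment_nuclei(b$DAPI, smoothing_sigma = config$smoothing_sigma,
                          min_object_area_px = config$min_object_area_px,
                          split_touching = config$split_touching)
    expand_cells(nuc, config$expansion_radius_px)
  })

  calib <- NULL
  if (sum(vapply(masks, n_objects, integer(1))) == 0L) {
    empty <- data.frame(scene = integer(0), region = character(0),
                        cell_id = integer(0), kcc2_count = integer(0),
                        nkcc1_count = integer(0), stringsAsFactors = FALSE)
    return(structure(list(cells = empty, summary = data.frame(),
                          calibration = NULL, masks = masks,
                          threshold = NA_real_),
                     class = "rnascope_result"))
  }
  if (is.null(intensity_threshold)) {
    negs <- lapply(bundles, function(b) b[[config$negctrl_channel]])
    if (any(vapply(negs, is.null, logical(1))))
      stop("stage calibrate_threshold: no '", config$negctrl_channel,
           "' channel and no fixed intensity_threshold given")
    calib <- calibrate_threshold(negs, masks,
                                 target_rate = config$target_background_rate,
                                 min_spot_area_px = config$min_spot_area_px)
    intensity_threshold <- calib$threshold
  }

  recs <- list()
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]; mask <- masks[[i]]
    n <- n_objects(mask)
    if (n == 0) next
    count_channel <- function(ch) {
      if (is.null(b[[ch]])) return(integer(n))
      sp <- detect_spots(b[[ch]], intensity_threshold,
                         config$min_spot_area_px, channel_name = ch)
      sp <- assign_spots_to_cells(sp, mask)
      count_spots_per_cell(sp, n)
    }
    recs[[i]] <- data.frame(
      scene = i, region = regions[i], cell_id = seq_len(n),
      kcc2_count = count_channel(config$neuron_marker_channel),
      nkcc1_count = count_channel(config$nkcc1_channel),
      stringsAsFactors = FALSE)
  }
  cells <- if (length(recs)) do.call(rbind, recs) else
    data.frame(scene = integer(0), region = character(0),
               cell_id = integer(0), kcc2_count = integer(0),
               nkcc1_count = integer(0), stringsAsFactors = FALSE)
  if (nrow(cells)) {
    cells <- classify_cells(cells, config)
    cells <- bin_expression(cells, config)
  }
  summary <- if (nrow(cells)) summarize_cells(cells, "cell_class") else
    data.frame()

  res <- structure(list(cells = cells, summary = summary,
                        calibration = calib, masks = masks,
                        threshold = intensity_threshold),
                   class = "rnascope_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cells, file.path(out_dir, "cell_records.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(calib))
      jsonlite::write_json(calib[c("threshold", "achieved_rate", "n_cells",
                                   "target_rate", "trace")],
                           file.path(out_dir, "calibration.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
  }
  res
}

#' @export
print.rnascope_result <- function(x, ...) {
  cat(sprintf("rnascope_result: %d cells, threshold %.4g\n",
              nrow(x$cells), x$threshold))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}
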