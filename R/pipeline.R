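# End-to-end orchestration: segment -> measure -> calibrate -> classify
# -> stroma -> profile -> sensitivity, with artifact writing and a
# checksummed run manifest.

#' Pipeline configuration
#'
#' Declarative configuration for [runPipeline()]. Defaults follow the
#' package's standard operating point: 5 um cytoplasmic expansion,
#' 5th/99th nuclear-area percentile filter, 10 um distance bins over
#' [-100, 300) um, 500 bootstrap iterations, and a 3 x 3 sensitivity grid
#' around the configured stromal parameters.
#'
#' @param channels Named list mapping roles to channel names; must name
#'   `nuclear`, `matrix`, `marker`, and optionally `cancer`.
#' @param pixel_size_um Micrometres per pixel (used when a stack lacks
#'   its own, and for validation).
#' @param expansion_um Radial nucleus expansion, micrometres (default 5).
#' @param area_percentiles Low/high nuclear-area percentile filter
#'   (default `c(5, 99)`).
#' @param sigma_um Stromal Gaussian smoothing sigma, micrometres
#'   (default 15; a nuclear-foci-type marker typically uses 10).
#' @param stroma_threshold Intensity threshold for the stromal mask
#'   (smoothed grey levels).
#' @param marker_column Cell-table column used for marker classification
#'   (default `"Cell: MARKER max"`, maximum whole-cell intensity).
#' @param cancer_column Column used to gate cancer cells (default
#'   `"Cytoplasm: KER median"`); set `NULL` to skip gating.
#' @param reference_image Id of the reference image for threshold
#'   propagation.
#' @param reference_threshold Expert marker threshold in the reference
#'   image.
#' @param cancer_reference_threshold Expert cancer-marker threshold in
#'   the reference image (`NULL` skips cancer gating).
#' @param bin_width_um Distance bin width (default 10).
#' @param range_um Profile range (default `c(-100, 300)`).
#' @param n_boot Bootstrap iterations (default 500).
#' @param sensitivity_sigmas_um,sensitivity_thresholds Sensitivity grid;
#'   defaults `c(5, 10, 15)` and `stroma_threshold * c(0.8, 1, 1.2)`.
#' @param seed Integer seed for all stochastic steps.
#' @return Validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(channels = list(nuclear = "DAPI", matrix = "FN",
                                           cancer = "KER", marker = "MARKER"),
                           pixel_size_um = 0.3215,
                           expansion_um = 5,
                           area_percentiles = c(5, 99),
                           sigma_um = 15,
                           stroma_threshold,
                           marker_column = NULL,
                           cancer_column = NULL,
                           reference_image,
                           reference_threshold,
                           cancer_reference_threshold = NULL,
                           bin_width_um = 10,
                           range_um = c(-100, 300),
                           n_boot = 500,
                           sensitivity_sigmas_um = c(5, 10, 15),
                           sensitivity_thresholds = NULL,
                           seed = 1) {
  for (role in c("nuclear", "matrix", "marker"))
    if (is.null(channels[[role]]))
      stop("channels must name a '", role, "' channel")
  stopifnot(pixel_size_um > 0, expansion_um >= 0, sigma_um >= 0,
            bin_width_um > 0, n_boot >= 1,
            length(area_percentiles) == 2,
            area_percentiles[1] < area_percentiles[2])
  if (is.null(marker_column))
    marker_column <- paste0("Cell: ", channels$marker, " max")
  if (is.null(cancer_column) && !is.null(channels$cancer))
    cancer_column <- paste0("Cytoplasm: ", channels$cancer, " median")
  if (is.null(sensitivity_thresholds))
    sensitivity_thresholds <- stroma_threshold * c(0.8, 1, 1.2)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 expansion_um = expansion_um,
                 area_percentiles = area_percentiles,
                 sigma_um = sigma_um, stroma_threshold = stroma_threshold,
                 marker_column = marker_column, cancer_column = cancer_column,
                 reference_image = reference_image,
                 reference_threshold = reference_threshold,
                 cancer_reference_threshold = cancer_reference_threshold,
                 bin_width_um = bin_width_um, range_um = range_um,
                 n_boot = n_boot,
                 sensitivity_sigmas_um = sensitivity_sigmas_um,
                 sensitivity_thresholds = sensitivity_thresholds,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipelineConfig()].
#' @return A `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[intersect(names(vals), names(formals(pipelineConfig)))]
  do.call(pipelineConfig, vals)
}

.stageLog <- function(stage, id, ...) {
  message(sprintf("[%s] %s%s", stage, if (is.null(id)) "" else paste0(id, ": "),
                  paste0(...)))
}

#' Run the full spatial analysis pipeline
#'
#' Executes segmentation (external labels where given, otherwise the
#' built-in blob segmenter), 5-um expansion and area filtering, per-cell
#' compartment measurement, percentile-preserving threshold propagation,
#' threshold classification (with optional cancer-cell gating), stromal
#' modeling with signed distances, distance-binned profiling of the
#' marker-positive population, and the parameter sensitivity grid.
#' Re-running with identical inputs and config reproduces identical
#' outputs. Any stage error aborts with the stage name and image id.
#'
#' @param stacks Named list of [ChannelStack-class] objects.
#' @param config A `"PipelineConfig"` from [pipelineConfig()].
#' @param labels Optional named list of externally produced nuclei label
#'   matrices; images without an entry use the built-in segmenter.
#' @param out_dir Optional output directory; when given, cell tables,
#'   the threshold map, masks, profiles, sensitivity results and a
#'   checksummed manifest are written there.
#' @return List with `tables` (per-image cell tables with classes,
#'   distances, bins), `combined` (row-bound table), `threshold_map`,
#'   `cancer_map` (or `NULL`), `stromal_models`, `profile`
#'   ([BinProfile-class] of the marker-positive population),
#'   `sensitivity`, `manifest`.
#' @export
runPipeline <- function(stacks, config, labels = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is(stacks, "ChannelStack")) stacks <- list(image = stacks)
  if (is.null(names(stacks)) || any(!nzchar(names(stacks))))
    stop("stacks must be a named list of ChannelStack objects")
  ch <- config$channels
  for (id in names(stacks)) {
    have <- channelNames(stacks[[id]])
    need <- unlist(ch[c("nuclear", "matrix", "marker")], use.names = FALSE)
    if (!is.null(config$cancer_reference_threshold))
      need <- c(need, ch$cancer)
    missing <- setdiff(need, have)
    if (length(missing))
      stop("validation: image '", id, "' lacks channel(s): ",
           paste(missing, collapse = ", "))
  }
  if (!config$reference_image %in% names(stacks))
    stop("validation: reference image '", config$reference_image,
         "' not among inputs")

  tables <- list(); models <- list()
  for (id in names(stacks)) {
    stack <- stacks[[id]]
    ps <- pixelSize(stack)
    nuc <- if (!is.null(labels[[id]])) {
      .stageLog("segment", id, "using external labels")
      labels[[id]]
    } else {
      .stageLog("segment", id, "built-in blob segmenter")
      segmentNucleiBuiltin(getChannel(stack, ch$nuclear), ps)
    }
    cells <- expandCells(nuc, config$expansion_um, ps)
    geoms <- cellGeometries(nuc, cells, ps)
    if (length(geoms) == 0) stop("segment: image '", id, "' yielded no cells")
    flt <- filterByArea(geoms, config$area_percentiles[1],
                        config$area_percentiles[2])
    .stageLog("segment", id, length(geoms), " cells, ",
              length(flt$kept), " kept after area filter")
    tab <- measureCells(stack, flt$kept, image_id = id)
    .stageLog("measure", id, "measured ", nrow(tab), " cells")
    tables[[id]] <- tab
  }

  .stageLog("calibrate", NULL, "marker column '", config$marker_column, "'")
  map <- propagateThresholds(tables, config$marker_column,
                             config$reference_image,
                             config$reference_threshold)
  cancer_map <- NULL
  if (!is.null(config$cancer_reference_threshold)) {
    cancer_map <- propagateThresholds(tables, config$cancer_column,
                                      config$reference_image,
                                      config$cancer_reference_threshold)
  }

  for (id in names(stacks)) {
    tab <- classifyByThreshold(tables[[id]], map,
                               label_column = "marker_class")
    if (!is.null(cancer_map))
      tab <- classifyByThreshold(tab, cancer_map,
                                 label_column = "cancer_class")
    ps <- pixelSize(stacks[[id]])
    model <- buildStromalModel(getChannel(stacks[[id]], ch$matrix),
                               sigma_um = config$sigma_um,
                               threshold = config$stroma_threshold,
                               pixel_size_um = ps)
    if (nrow(stromalBorder(model)) == 0)
      stop("stroma: image '", id, "' has an empty stromal border")
    d <- signedDistance(model, tab[, c("centroid_x_um", "centroid_y_um")])
    tab$signed_distance_um <- d
    bins <- binCells(d, config$bin_width_um, config$range_um)
    tab$bin_index <- as.integer(bins)
    .stageLog("stroma", id, "stromal fraction ",
              signif(mean(stromalMask(model)), 3))
    tables[[id]] <- tab
    models[[id]] <- model
  }
  combined <- do.call(rbind, c(tables, list(make.row.names = FALSE)))

  pop <- combined$marker_class == "positive"
  pop_label <- "marker-positive"
  if (!is.null(cancer_map)) {
    pop <- pop & combined$cancer_class == "positive"
    pop_label <- "marker-positive cancer"
  }
  .stageLog("profile", NULL, sum(pop), " cells in population '",
            pop_label, "'")
  prof <- distanceProfile(combined, config$marker_column, subset = pop,
                          bin_width_um = config$bin_width_um,
                          range_um = config$range_um,
                          n_boot = config$n_boot, seed = config$seed,
                          population_label = pop_label)

  .stageLog("sensitivity", NULL, length(config$sensitivity_sigmas_um), "x",
            length(config$sensitivity_thresholds), " grid")
  # correlations are computed over all cells on each side of the border
  sens <- suppressWarnings(
    runSensitivityGrid(stacks, tables,
                       sigmas_um = config$sensitivity_sigmas_um,
                       thresholds = config$sensitivity_thresholds,
                       value_column = config$marker_column,
                       fn_channel = ch$matrix,
                       n_boot = config$n_boot, seed = config$seed))

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (id in names(tables))
      files <- c(files, writeCellTable(tables[[id]],
                   file.path(out_dir, paste0("cells_", id, ".csv"))))
    files <- c(files,
               writeThresholdMap(map, file.path(out_dir, "threshold_map.json")))
    for (id in names(models))
      files <- c(files, writeStromalMask(models[[id]],
                   file.path(out_dir, paste0("stroma_mask_", id, ".tif"))))
    files <- c(files, writeProfile(prof, file.path(out_dir, "profile.csv")))
    files <- c(files, writeSensitivityResult(sens,
                 file.path(out_dir, "sensitivity_grid.csv"),
                 file.path(out_dir, "sensitivity_summary.json")))
    manifest <- list(
      package_version = as.character(utils::packageVersion("stromaSpatial")),
      seed = config$seed,
      config = unclass(config),
      complete = TRUE,
      files = lapply(files, function(f)
        list(path = basename(f),
             md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(tables = tables, combined = combined, threshold_map = map,
       cancer_map = cancer_map, stromal_models = models, profile = prof,
       sensitivity = sens, manifest = manifest)
}
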