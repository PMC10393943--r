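#' Pixel clustering run configuration
#'
#' Bundles every parameter of the pixel stage. `dataset` may be a dataset
#' directory (layout of [simulate_dataset] / [load_fov]) or an in-memory
#' list of [multichannel_image]s. A single `seed` drives all stochastic
#' stages through fixed offsets (subsampling: `seed + 1`, SOM:
#' `seed + 2`, consensus: `seed + 3`) unless the stage configs carry
#' explicit seeds.
#'
#' @param dataset dataset directory path or list of [multichannel_image]s.
#' @param markers character vector of clustering markers; defaults to the
#'   dataset manifest's marker list when the dataset is a directory.
#' @param k number of metaclusters.
#' @param sigma Gaussian blur SD in pixels (0 disables smoothing).
#' @param quantile marker-normalization quantile (default 0.999).
#' @param subsample_fraction fraction of pixels used for SOM training.
#' @param pixel_norm,marker_norm flags to disable either normalization
#'   step (ablation support; both on by default).
#' @param som a [som_config]; its seed is overridden by `seed + 2` when
#'   `NULL`-seeded via this constructor's default.
#' @param consensus optional [consensus_config]; built from `k` when NULL.
#' @param remap optional remap CSV path or `remap_table`.
#' @param region_mask_file optional per-FOV region mask filename (binary
#'   TIFF inside each FOV directory); only masked pixels are clustered.
#' @param positivity_filter optional `list(marker =, threshold =)` strict
#'   positivity filter.
#' @param output_dir optional artifact directory; nothing is written when
#'   NULL.
#' @param seed master seed for the run.
#' @return an object of class `pixel_run_config`.
#' @export
pixel_run_config <- function(dataset, markers = NULL, k = 8,
                             sigma = 2, quantile = 0.999,
                             subsample_fraction = 0.1,
                             pixel_norm = TRUE, marker_norm = TRUE,
                             som = NULL, consensus = NULL,
                             remap = NULL, region_mask_file = NULL,
                             positivity_filter = NULL,
                             output_dir = NULL, seed = 1) {
  if (is.character(dataset) && !dir.exists(dataset))
    stopf("dataset directory does not exist: %s", dataset)
  if (is.null(markers) && is.character(dataset)) {
    manifest <- read_dataset_manifest(dataset)
    markers <- manifest$markers
  }
  if (is.null(markers) || !length(markers))
    stopf("clustering marker set must be nonempty")
  seed <- as.integer(seed)
  if (is.null(som)) som <- som_config(seed = seed + 2L)
  if (is.null(consensus)) consensus <- consensus_config(k = k, seed = seed + 3L)
  structure(list(dataset = dataset, markers = markers,
                 sigma = sigma, quantile = quantile,
                 subsample_fraction = subsample_fraction,
                 pixel_norm = pixel_norm, marker_norm = marker_norm,
                 som = som, consensus = consensus, remap = remap,
                 region_mask_file = region_mask_file,
                 positivity_filter = positivity_filter,
                 output_dir = output_dir, seed = seed),
            class = "pixel_run_config")
}

.load_config_images <- function(config) {
  if (is.character(config$dataset)) {
    lapply(list_fovs(config$dataset), load_fov, markers = config$markers)
  } else {
    config$dataset
  }
}

.load_region_masks <- function(config, images) {
  if (is.null(config$region_mask_file)) return(NULL)
  if (!is.character(config$dataset))
    stopf("region mask files require a dataset directory")
  masks <- lapply(list_fovs(config$dataset), function(d) {
    p <- file.path(d, config$region_mask_file)
    if (!file.exists(p)) stopf("region mask missing: %s", p)
    read_tiff(p)
  })
  stats::setNames(masks, vapply(images, function(im) im$fov_id, character(1)))
}

#' Run the full pixel clustering pipeline
#'
#' Executes the cascade on all FOVs pooled: Gaussian smoothing -> pixel
#' extraction (zero/region/positivity exclusion) -> pixel normalization ->
#' 99.9% marker normalization (fit on all retained pixels, before any
#' subsampling) -> subsampled SOM training -> assignment of every retained
#' pixel -> cluster mean profiles -> capped z-scores -> consensus
#' metaclustering -> optional manual remap -> per-FOV pixel phenotype
#' maps. When `config$output_dir` is set, all artifacts plus a manifest of
#' parameters and seeds are written.
#'
#' @param config a [pixel_run_config].
#' @return a list of run artifacts: `table` (fully normalized
#'   [pixel_table]), `norm_params`, `som` ([som_model]), `assignments`
#'   (SOM ids per retained pixel), `profiles`, `capped`, `mapping`
#'   (consensus mapping), `remap` (`remap_table` actually applied),
#'   `metaclusters` (per-pixel metacluster ids), `annotations`, `maps`
#'   (named list of per-FOV [label_map]s), and `config`.
#' @export
run_pixel_clustering <- function(config) {
  t0 <- Sys.time()
  images <- .load_config_images(config)
  if (!length(images)) stopf("dataset contains no FOVs")
  region_masks <- .load_region_masks(config, images)

  smoothed <- lapply(images, function(im) {
    tryCatch(smooth_channels(im, config$sigma),
             error = function(e) stopf("smoothing failed for %s: %s",
                                       im$fov_id, conditionMessage(e)))
  })
  stage <- if (config$sigma > 0) "smoothed" else "raw"
  tables <- lapply(smoothed, function(im) {
    extract_pixels(im,
                   region_mask = if (is.null(region_masks)) NULL else region_masks[[im$fov_id]],
                   positivity_filter = config$positivity_filter,
                   stage = stage)
  })
  table <- bind_pixel_tables(tables)
  if (nrow(table$values) == 0) stopf("no pixels retained after exclusion filters")

  if (config$pixel_norm) {
    table <- normalize_pixels(table)
  } else {
    table$stage <- "pixel_normalized"  # stage bookkeeping for the ablation path
  }
  norm_params <- NULL
  if (config$marker_norm) {
    norm_params <- fit_percentile_norm(table, quantile = config$quantile)
    table <- apply_percentile_norm(table, norm_params)
  } else {
    table$stage <- "fully_normalized"
  }
  # clustering input carries float32 precision (the precision of the raw
  # marker images); this keeps the SOM invariant to global rescaling
  cn <- colnames(table$values)
  table$values <- round_float32_cpp(table$values)
  colnames(table$values) <- cn

  train_table <- subsample_pixels(table, config$subsample_fraction,
                                  seed = config$seed + 1L)
  som <- train_som(train_table$values, config$som)
  assignments <- assign_som(som, table$values)

  profiles <- compute_profiles(table, assignments,
                               n_clusters = config$som$grid_rows * config$som$grid_cols)
  capped <- zscore_cap(profiles)
  mapping <- consensus_metacluster(capped, config$consensus)

  remap <- config$remap
  if (is.null(remap)) {
    remap <- remap_from_mapping(mapping)
  } else if (is.character(remap)) {
    remap <- read_remap(remap)
  }
  remapped <- apply_remap(assignments, remap)

  fov_ids <- vapply(images, function(im) im$fov_id, character(1))
  shapes <- lapply(images, function(im) dim(im$data)[1:2])
  legend <- stats::setNames(remap$annotation[!duplicated(remap$metacluster)],
                            remap$metacluster[!duplicated(remap$metacluster)])
  maps <- stats::setNames(lapply(seq_along(images), function(i) {
    sel <- table$coords$fov == fov_ids[i]
    render_phenotype_map(fov_ids[i], table$coords[sel, , drop = FALSE],
                         remapped$metacluster[sel], shapes[[i]], legend = legend)
  }), fov_ids)

  result <- list(table = table, norm_params = norm_params, som = som,
                 assignments = assignments, profiles = profiles,
                 capped = capped, mapping = mapping, remap = remap,
                 metaclusters = remapped$metacluster,
                 annotations = remapped$annotation,
                 maps = maps, config = config)
  if (!is.null(config$output_dir))
    .write_pixel_artifacts(result, config$output_dir, t0)
  result
}

.write_pixel_artifacts <- function(result, output_dir, t0) {
  for (sub in c("models", "assignments", "profiles", "maps", "logs"))
    dir.create(file.path(output_dir, sub), recursive = TRUE, showWarnings = FALSE)
  config <- result$config

  save_som(result$som, file.path(output_dir, "models", "som.json"))
  if (!is.null(result$norm_params))
    save_norm_params(result$norm_params,
                     file.path(output_dir, "models", "norm_params.json"))

  adf <- cbind(result$table$coords,
               som_cluster = result$assignments,
               metacluster = result$metaclusters,
               annotation = result$annotations)
  utils::write.csv(adf, file.path(output_dir, "assignments", "pixel_assignments.csv"),
                   row.names = FALSE)

  prof <- result$profiles
  pdf <- data.frame(som_cluster = prof$cluster_ids, count = prof$counts,
                    prof$mean_expression, check.names = FALSE)
  utils::write.csv(pdf, file.path(output_dir, "profiles", "cluster_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(som_cluster = rownames(result$capped),
                              result$capped, check.names = FALSE),
                   file.path(output_dir, "profiles", "capped_zscores.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(attr(result$mapping, "consensus")),
                   file.path(output_dir, "profiles", "consensus_matrix.csv"),
                   row.names = FALSE)
  write_remap(result$remap, file.path(output_dir, "profiles", "remap.csv"))

  for (fid in names(result$maps)) {
    save_label_map(result$maps[[fid]],
                   file.path(output_dir, "maps", paste0(fid, "_phenotype.tiff")))
    render_label_png(result$maps[[fid]],
                     file.path(output_dir, "maps", paste0(fid, "_phenotype.png")))
  }

  inputs <- if (is.character(config$dataset)) {
    files <- list.files(config$dataset, recursive = TRUE, full.names = TRUE)
    as.list(tools::md5sum(files))
  } else list()
  manifest <- list(
    tool = sprintf("pixphen %s", as.character(utils::packageVersion("pixphen"))),
    stage = "pixel_clustering",
    seed = config$seed,
    stage_seeds = list(subsample = config$seed + 1L,
                       som = config$som$seed,
                       consensus = config$consensus$seed),
    parameters = list(markers = config$markers, sigma = config$sigma,
                      quantile = config$quantile,
                      subsample_fraction = config$subsample_fraction,
                      pixel_norm = config$pixel_norm,
                      marker_norm = config$marker_norm,
                      som = unclass(config$som),
                      consensus = unclass(config$consensus)),
    input_digests = inputs,
    outputs = list.files(output_dir, recursive = TRUE),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "logs", "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a pixel phenotype map
#'
#' Builds the integer image in which each retained pixel carries its
#' metacluster id and every excluded pixel is 0.
#'
#' @param fov_id FOV identifier.
#' @param coords data frame of 0-based `(row, col)` pixel coordinates.
#' @param ids integer metacluster ids aligned with `coords`.
#' @param shape `c(height, width)` of the FOV.
#' @param legend optional id -> annotation legend.
#' @return a [label_map].
#' @export
render_phenotype_map <- function(fov_id, coords, ids, shape, legend = NULL) {
  if (length(ids) != nrow(coords)) stopf("ids do not align with coords")
  if (nrow(coords) > 0 &&
      (any(coords$row < 0) || any(coords$row >= shape[1]) ||
       any(coords$col < 0) || any(coords$col >= shape[2])))
    stopf("pixel coordinates out of image bounds %d x %d", shape[1], shape[2])
  data <- matrix(0L, shape[1], shape[2])
  if (nrow(coords) > 0)
    data[cbind(coords$row + 1L, coords$col + 1L)] <- as.integer(ids)
  label_map(fov_id, data, legend = legend)
}

#' Cluster composition of a phenotype map
#'
#' The fraction of pixels carrying each (meta)cluster id within an optional
#' region — e.g. percent extracellular-matrix pixels per image, or cluster
#' composition per annotated anatomical region. The denominator is either
#' every pixel in the region (`"all"`, fractions sum to <= 1 because
#' excluded pixels count) or only the assigned ones (`"assigned"`,
#' fractions sum to 1).
#'
#' @param map a [label_map] phenotype map.
#' @param region_mask optional binary matrix of the map's size.
#' @param denominator `"all"` or `"assigned"`.
#' @return named numeric vector of fractions per cluster id.
#' @export
cluster_composition <- function(map, region_mask = NULL,
                                denominator = c("all", "assigned")) {
  denominator <- match.arg(denominator)
  vals <- as.vector(map$data)
  if (!is.null(region_mask)) {
    if (!all(dim(region_mask) == dim(map$data)))
      stopf("region mask dimensions do not match the map")
    vals <- vals[as.vector(region_mask) != 0]
  }
  if (!length(vals)) stopf("region is empty")
  denom <- if (denominator == "all") length(vals) else sum(vals > 0)
  if (denom == 0) stopf("region contains no assigned pixels")
  counts <- table(vals[vals > 0])
  stats::setNames(as.numeric(counts) / denom, names(counts))
}
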