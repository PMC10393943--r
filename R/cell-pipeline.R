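#' Cell feature tables
#'
#' Per-cell feature vectors extracted inside segmentation masks, either
#' `pixel_composition` (fraction of the cell's pixels in each pixel
#' cluster) or `integrated_expression` (marker sums over the cell divided
#' by cell size). Cell size is the total geometric pixel count of the mask
#' region, including pixels that were excluded from pixel clustering.
#'
#' @param cells data frame with columns `fov`, `cell_id`, `cell_size`.
#' @param features numeric matrix, one row per cell, named columns.
#' @param feature_kind `"pixel_composition"` or `"integrated_expression"`.
#' @return an object of class `cell_feature_table`.
#' @export
cell_feature_table <- function(cells, features,
                               feature_kind = c("pixel_composition",
                                                "integrated_expression")) {
  feature_kind <- match.arg(feature_kind)
  if (nrow(cells) != nrow(features)) stopf("cells and features must align")
  if (any(cells$cell_size < 1)) stopf("cell sizes must be >= 1")
  if (anyDuplicated(cells[c("fov", "cell_id")]))
    stopf("cell ids must be unique within each FOV")
  structure(list(cells = cells, features = features,
                 feature_kind = feature_kind,
                 feature_names = colnames(features)),
            class = "cell_feature_table")
}

#' @export
print.cell_feature_table <- function(x, ...) {
  cat(sprintf("<cell_feature_table> %d cells x %d %s features\n",
              nrow(x$cells), ncol(x$features), x$feature_kind))
  invisible(x)
}

.mask_list <- function(masks) {
  if (inherits(masks, "label_map")) {
    stats::setNames(list(masks), masks$fov_id)
  } else {
    stats::setNames(masks, vapply(masks, function(m) m$fov_id, character(1)))
  }
}

#' Pixel-cluster composition features per cell
#'
#' For every cell in the segmentation masks, counts its member pixels per
#' pixel cluster and divides by the total cell size. In-cell pixels that
#' were excluded from pixel clustering contribute to the denominator only,
#' so compositions sum to <= 1 per cell. Misassigned boundary pixels from
#' neighboring cells stay few in number, which is why composition features
#' resist the spillover that corrupts integrated expression.
#'
#' @param coords data frame of 0-based `(fov, row, col)` retained-pixel
#'   coordinates (e.g. `result$table$coords` from
#'   [run_pixel_clustering]).
#' @param ids per-pixel cluster ids aligned with `coords` (SOM clusters or
#'   metaclusters — both levels are supported; pass whichever you want as
#'   features).
#' @param masks a [label_map] segmentation mask or list of them (one per
#'   FOV).
#' @param n_clusters number of feature columns; defaults to `max(ids)`.
#' @return a [cell_feature_table] of kind `pixel_composition`.
#' @export
cell_pixel_composition <- function(coords, ids, masks, n_clusters = max(ids)) {
  if (length(ids) != nrow(coords)) stopf("ids do not align with coords")
  masks <- .mask_list(masks)
  miss <- setdiff(unique(coords$fov), names(masks))
  if (length(miss))
    stopf("no segmentation mask for FOV(s): %s", paste(miss, collapse = ", "))

  rows <- list(); feats <- list()
  for (fid in names(masks)) {
    mask <- masks[[fid]]$data
    sel <- coords$fov == fid
    pix_cell <- integer(0)
    pix_ids <- integer(0)
    if (any(sel)) {
      rc <- cbind(coords$row[sel] + 1L, coords$col[sel] + 1L)
      if (any(rc[, 1] > nrow(mask)) || any(rc[, 2] > ncol(mask)))
        stopf("pixel coordinates exceed mask geometry for FOV %s", fid)
      pix_cell <- mask[rc]
      pix_ids <- ids[sel]
    }
    cell_ids <- sort(setdiff(unique(as.vector(mask)), 0L))
    if (!length(cell_ids)) next
    sizes <- tabulate(mask[mask > 0L], nbins = max(cell_ids))[cell_ids]
    counts <- matrix(0, length(cell_ids), n_clusters,
                     dimnames = list(cell_ids, NULL))
    inside <- pix_cell > 0L
    if (any(inside)) {
      tab <- table(factor(pix_cell[inside], levels = cell_ids),
                   factor(pix_ids[inside], levels = seq_len(n_clusters)))
      counts <- counts + unclass(tab)
    }
    rows[[fid]] <- data.frame(fov = fid, cell_id = cell_ids,
                              cell_size = sizes, stringsAsFactors = FALSE)
    feats[[fid]] <- counts / sizes
  }
  features <- do.call(rbind, feats)
  colnames(features) <- sprintf("cluster_%d", seq_len(n_clusters))
  cell_feature_table(do.call(rbind, rows), features, "pixel_composition")
}

#' 99.9% feature normalization for cell composition features
#'
#' Divides each feature column by its `quantile` (default 0.999) over
#' cells. Columns whose quantile is zero (a pixel cluster absent from all
#' cells) are dropped with a warning naming the cluster.
#'
#' @param table a [cell_feature_table] of kind `pixel_composition`.
#' @param quantile quantile level in (0, 1].
#' @return the normalized [cell_feature_table].
#' @export
normalize_cell_features <- function(table, quantile = 0.999) {
  if (!nrow(table$cells)) stopf("cell feature table is empty")
  if (table$feature_kind != "pixel_composition")
    stopf("feature normalization applies to pixel_composition features")
  q <- apply(table$features, 2, stats::quantile, probs = quantile,
             names = FALSE, type = 7)
  drop <- q <= 0
  if (any(drop))
    warnf("dropping feature column(s) with zero %g-quantile: %s",
          quantile, paste(colnames(table$features)[drop], collapse = ", "))
  features <- sweep(table$features[, !drop, drop = FALSE], 2, q[!drop], "/")
  cell_feature_table(table$cells, features, table$feature_kind)
}

#' Integrated marker expression features per cell (baseline)
#'
#' The classical cytometry-style featurization: per-cell sum of each
#' marker over the mask region, divided by cell size, then 99.9% column
#' normalization. With `preprocess = TRUE`, the smoothing and
#' pixel-normalization cascade is applied to the images before
#' extraction.
#'
#' @param images a [multichannel_image] or list of them.
#' @param masks matching segmentation mask(s).
#' @param preprocess apply Gaussian blur (`sigma`) and pixel normalization
#'   first.
#' @param sigma blur SD when `preprocess = TRUE`.
#' @param quantile column-normalization quantile; `NA` skips it.
#' @return a [cell_feature_table] of kind `integrated_expression`.
#' @export
integrated_expression_features <- function(images, masks, preprocess = FALSE,
                                           sigma = 2, quantile = 0.999) {
  if (inherits(images, "multichannel_image")) images <- list(images)
  masks <- .mask_list(masks)
  rows <- list(); feats <- list()
  for (im in images) {
    mask <- masks[[im$fov_id]]
    if (is.null(mask)) stopf("no segmentation mask for FOV %s", im$fov_id)
    if (!all(dim(mask$data) == dim(im$data)[1:2]))
      stopf("mask geometry does not match image for FOV %s", im$fov_id)
    if (preprocess) {
      im <- smooth_channels(im, sigma)
      flat <- matrix(im$data, ncol = length(im$marker_names))
      sums <- rowSums(flat)
      flat[sums > 0, ] <- flat[sums > 0, , drop = FALSE] / sums[sums > 0]
      im$data <- array(flat, dim = dim(im$data))
    }
    cell_ids <- sort(setdiff(unique(as.vector(mask$data)), 0L))
    if (!length(cell_ids)) next
    sizes <- tabulate(mask$data[mask$data > 0L], nbins = max(cell_ids))[cell_ids]
    flat <- matrix(im$data, ncol = length(im$marker_names))
    cellvec <- as.vector(mask$data)
    inside <- cellvec > 0L
    sums <- rowsum(flat[inside, , drop = FALSE],
                   factor(cellvec[inside], levels = cell_ids))
    feats[[im$fov_id]] <- sums / sizes
    rows[[im$fov_id]] <- data.frame(fov = im$fov_id, cell_id = cell_ids,
                                    cell_size = sizes, stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)
  colnames(features) <- images[[1]]$marker_names
  rownames(features) <- NULL
  if (!is.na(quantile)) {
    q <- apply(features, 2, stats::quantile, probs = quantile,
               names = FALSE, type = 7)
    q[q <= 0] <- 1
    features <- sweep(features, 2, q, "/")
  }
  cell_feature_table(do.call(rbind, rows), features, "integrated_expression")
}

#' Cluster cells from a feature table
#'
#' The cell analogue of the pixel stage: SOM overclustering of the cell
#' feature vectors, cluster mean profiles, capped z-scores, consensus
#' metaclustering and optional manual remap. Cell phenotype maps are
#' rendered by painting each cell's mask region with its metacluster id.
#'
#' @param table a normalized [cell_feature_table].
#' @param som a [som_config]; for small datasets use a smaller grid — an
#'   error (not a silent shrink) is raised when there are fewer cells than
#'   nodes.
#' @param consensus a [consensus_config].
#' @param remap optional remap CSV path or `remap_table`.
#' @param masks optional segmentation masks; when given, per-FOV cell
#'   phenotype maps are rendered.
#' @return list with `labels` (data frame `fov, cell_id, som_cluster,
#'   metacluster, annotation`), `som`, `profiles`, `capped`, `mapping`,
#'   `remap`, and `maps` (NULL without masks).
#' @export
cluster_cells <- function(table, som = som_config(), consensus,
                          remap = NULL, masks = NULL) {
  n_nodes <- som$grid_rows * som$grid_cols
  if (nrow(table$features) < n_nodes)
    stopf("fewer cells (%d) than SOM nodes (%d); use a smaller grid",
          nrow(table$features), n_nodes)
  model <- train_som(table$features, som)
  assignments <- assign_som(model, table$features)
  profiles <- compute_profiles(table$features, assignments, n_clusters = n_nodes)
  nonempty <- sum(profiles$counts > 0)
  if (nonempty < 2) {
    # degenerate input (e.g. constant features): one effective phenotype
    capped <- NULL
    mapping <- stats::setNames(1L, which(profiles$counts > 0))
  } else {
    capped <- zscore_cap(profiles)
    if (consensus$k > nonempty) {
      warnf("k = %d exceeds the %d populated SOM clusters; using k = %d",
            consensus$k, nonempty, nonempty)
      consensus$k <- as.integer(nonempty)
    }
    mapping <- consensus_metacluster(capped, consensus)
  }
  if (is.null(remap)) {
    remap <- remap_from_mapping(mapping)
  } else if (is.character(remap)) {
    remap <- read_remap(remap)
  }
  remapped <- apply_remap(assignments, remap)
  labels <- data.frame(table$cells[c("fov", "cell_id")],
                       som_cluster = assignments,
                       metacluster = remapped$metacluster,
                       annotation = remapped$annotation,
                       stringsAsFactors = FALSE)
  maps <- NULL
  if (!is.null(masks)) {
    masks <- .mask_list(masks)
    maps <- lapply(names(masks), function(fid) {
      paint_cell_map(masks[[fid]], labels[labels$fov == fid, ])
    })
    names(maps) <- names(masks)
  }
  list(labels = labels, som = model, profiles = profiles, capped = capped,
       mapping = mapping, remap = remap, maps = maps)
}

#' Paint a cell phenotype map from a segmentation mask and cell labels
#'
#' @param mask a [label_map] segmentation mask.
#' @param labels data frame with `cell_id` and `metacluster` for this FOV.
#' @return a [label_map] whose pixels carry the cell's metacluster id.
#' @export
paint_cell_map <- function(mask, labels) {
  lut <- integer(max(mask$data, 1L))
  lut[labels$cell_id] <- labels$metacluster
  data <- mask$data
  data[data > 0L] <- lut[data[data > 0L]]
  label_map(mask$fov_id, data)
}
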