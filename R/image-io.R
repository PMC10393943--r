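#' Multi-channel marker image
#'
#' A per-FOV stack of single-marker grayscale channels sharing one geometry.
#' Data are stored as a `height x width x n_markers` array of nonnegative
#' intensities in arbitrary units. The coordinate convention throughout the
#' package is 0-based `(row, col)` with pixel `(0, 0)` at the top-left.
#'
#' @param fov_id field-of-view identifier.
#' @param marker_names unique marker (channel) names, in panel order.
#' @param data numeric array `height x width x n_markers`, values >= 0.
#' @return an object of class `multichannel_image`.
#' @export
multichannel_image <- function(fov_id, marker_names, data) {
  if (length(dim(data)) != 3L)
    stopf("`data` must be a 3-D array (height x width x n_markers)")
  if (dim(data)[3] != length(marker_names))
    stopf("third dimension (%d) must match number of markers (%d)",
          dim(data)[3], length(marker_names))
  if (anyDuplicated(marker_names)) stopf("marker names must be unique")
  if (any(data < 0)) stopf("intensities must be nonnegative")
  dimnames(data) <- list(NULL, NULL, marker_names)
  structure(list(fov_id = as.character(fov_id),
                 marker_names = as.character(marker_names),
                 data = data),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multichannel_image> %s: %d x %d px, %d markers (%s%s)\n",
              x$fov_id, d[1], d[2], d[3],
              paste(utils::head(x$marker_names, 4), collapse = ", "),
              if (d[3] > 4) ", ..." else ""))
  invisible(x)
}

#' Integer label image
#'
#' A 2-D integer image in which 0 marks background / excluded pixels and
#' positive ids mark objects (cells, pixel clusters, phenotypes). An
#' optional legend maps ids to annotations.
#'
#' @param fov_id field-of-view identifier.
#' @param data integer matrix, values >= 0.
#' @param legend optional named character vector, names = ids.
#' @return an object of class `label_map`.
#' @export
label_map <- function(fov_id, data, legend = NULL) {
  if (!is.matrix(data)) stopf("`data` must be a matrix")
  if (any(data < 0)) stopf("label ids must be >= 0")
  if (any(data != floor(data))) stopf("label ids must be integers")
  structure(list(fov_id = as.character(fov_id),
                 data = data,
                 legend = legend),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s: %d x %d px, %d nonzero ids\n",
              x$fov_id, nrow(x$data), ncol(x$data),
              length(setdiff(unique(as.vector(x$data)), 0))))
  invisible(x)
}

.marker_file <- function(dir, marker) {
  for (ext in c(".tiff", ".tif")) {
    p <- file.path(dir, paste0(marker, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Load one FOV's marker channels from a directory of single-channel TIFFs
#'
#' Channels are stacked in the requested `markers` order (never directory
#' listing order). Files are expected at `dir/<marker>.tiff` (or `.tif`).
#'
#' @param dir FOV directory.
#' @param markers character vector of marker names to load.
#' @param fov_id FOV identifier; defaults to the directory basename.
#' @return a [multichannel_image].
#' @export
load_fov <- function(dir, markers, fov_id = basename(dir)) {
  if (!dir.exists(dir)) stopf("FOV directory does not exist: %s", dir)
  channels <- vector("list", length(markers))
  for (i in seq_along(markers)) {
    p <- .marker_file(dir, markers[i])
    if (is.null(p))
      stopf("missing image for marker \"%s\" in %s", markers[i], dir)
    channels[[i]] <- read_tiff(p)
  }
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("channel dimensions differ across markers in %s", dir)
  arr <- array(unlist(channels), dim = c(dims[1, 1], dims[2, 1], length(markers)))
  multichannel_image(fov_id, markers, arr)
}

#' Write one FOV's channels as single-channel float TIFFs
#'
#' @param image a [multichannel_image].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_fov <- function(image, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(image$marker_names)) {
    write_tiff(image$data[, , i],
               file.path(dir, paste0(image$marker_names[i], ".tiff")),
               type = "float32")
  }
  invisible(dir)
}

#' Save / load integer label maps
#'
#' Label maps are written as 32-bit unsigned integer TIFF (lossless round
#' trip, supports > 65k ids). A legend, when present, is written next to the
#' image as `<path>.legend.json`.
#'
#' @param map a [label_map].
#' @param path output TIFF path.
#' @return `path` (`save_label_map`) or a [label_map] (`load_label_map`).
#' @export
save_label_map <- function(map, path) {
  write_tiff(map$data, path, type = "uint32")
  legend_path <- paste0(path, ".legend.json")
  if (!is.null(map$legend)) {
    jsonlite::write_json(as.list(map$legend), legend_path, auto_unbox = TRUE)
  } else if (file.exists(legend_path)) {
    unlink(legend_path)
  }
  invisible(path)
}

#' @param fov_id FOV identifier for the loaded map.
#' @rdname save_label_map
#' @export
load_label_map <- function(path, fov_id = sub("\\.tiff?$", "", basename(path))) {
  data <- read_tiff(path)
  legend_path <- paste0(path, ".legend.json")
  legend <- NULL
  if (file.exists(legend_path)) {
    l <- jsonlite::read_json(legend_path)
    legend <- stats::setNames(unlist(l), names(l))
  }
  label_map(fov_id, data, legend)
}

#' Deterministic id -> color palette for label rendering
#'
#' Golden-angle hue stepping gives well-separated, reproducible colors for
#' any number of ids; id 0 (background) renders black.
#'
#' @param ids positive integer ids.
#' @return named character vector of hex colors.
#' @export
label_palette <- function(ids) {
  ids <- sort(unique(as.integer(ids)))
  ids <- ids[ids > 0]
  hue <- (ids * 0.6180339887498949) %% 1
  val <- 0.75 + 0.25 * ((ids %% 3) / 2)
  stats::setNames(grDevices::hsv(hue, s = 0.85, v = val), ids)
}

#' Render a label map to a color PNG
#'
#' @param map a [label_map].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_label_png <- function(map, path) {
  ids <- map$data
  pal <- label_palette(ids)
  h <- nrow(ids); w <- ncol(ids)
  img <- array(0, dim = c(h, w, 3))
  for (id in as.integer(names(pal))) {
    rgb <- grDevices::col2rgb(pal[[as.character(id)]]) / 255
    sel <- ids == id
    img[, , 1][sel] <- rgb[1]
    img[, , 2][sel] <- rgb[2]
    img[, , 3][sel] <- rgb[3]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read / validate / write a cluster remap table
#'
#' The remap table is the human-in-the-loop artifact: a CSV with header
#' `som_cluster,metacluster,annotation` mapping every SOM cluster to a
#' metacluster id and an annotation string.
#'
#' @param path CSV path.
#' @param n_som if given, require that som clusters `1..n_som` are all
#'   present (errors list the missing ids).
#' @return a validated `remap_table` data frame.
#' @export
read_remap <- function(path, n_som = NULL) {
  if (!file.exists(path)) stopf("remap file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_remap_table(df, n_som = n_som)
}

#' @param df data frame with columns `som_cluster`, `metacluster`,
#'   `annotation`.
#' @rdname read_remap
#' @export
as_remap_table <- function(df, n_som = NULL) {
  required <- c("som_cluster", "metacluster", "annotation")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("remap table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  for (col in c("som_cluster", "metacluster")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)))
      stopf("remap column `%s` must contain integers", col)
  }
  if (any(df$som_cluster < 1) || any(df$metacluster < 1))
    stopf("remap ids must be positive")
  dup <- unique(df$som_cluster[duplicated(df$som_cluster)])
  if (length(dup))
    stopf("duplicate som_cluster id(s) in remap: %s", paste(dup, collapse = ", "))
  if (any(!nzchar(df$annotation)) || any(is.na(df$annotation)))
    stopf("remap annotations must be non-empty")
  if (!is.null(n_som)) {
    missing_ids <- setdiff(seq_len(n_som), df$som_cluster)
    if (length(missing_ids))
      stopf("remap is missing som cluster(s): %s", paste(missing_ids, collapse = ", "))
  }
  df <- df[order(df$som_cluster), required]
  df$som_cluster <- as.integer(df$som_cluster)
  df$metacluster <- as.integer(df$metacluster)
  df$annotation <- as.character(df$annotation)
  rownames(df) <- NULL
  class(df) <- c("remap_table", "data.frame")
  df
}

#' @param table a `remap_table`.
#' @rdname read_remap
#' @export
write_remap <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' List FOV directories of a dataset
#'
#' Dataset layout: `dataset_root/<fov_id>/<marker>.tiff`, with the
#' segmentation mask (if any) at `dataset_root/<fov_id>/segmentation.tiff`.
#'
#' @param dataset_root dataset directory.
#' @return character vector of FOV directory paths, sorted by FOV id.
#' @export
list_fovs <- function(dataset_root) {
  if (!dir.exists(dataset_root)) stopf("dataset directory does not exist: %s", dataset_root)
  dirs <- list.dirs(dataset_root, recursive = FALSE)
  sort(dirs)
}
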