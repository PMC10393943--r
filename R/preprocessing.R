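#' Pixel tables
#'
#' The clustering substrate: a flat table of retained pixels with their
#' `(fov, row, col)` coordinates (0-based, top-left origin) and one column
#' of values per clustering marker. The `stage` field tracks progress
#' through the normalization cascade: `raw` / `smoothed` ->
#' `pixel_normalized` -> `fully_normalized`.
#'
#' @param coords data frame with columns `fov`, `row`, `col`.
#' @param values numeric matrix, one row per pixel, marker columns named.
#' @param stage cascade stage label.
#' @return an object of class `pixel_table`.
#' @export
pixel_table <- function(coords, values,
                        stage = c("raw", "smoothed", "pixel_normalized",
                                  "fully_normalized")) {
  stage <- match.arg(stage)
  if (nrow(coords) != nrow(values))
    stopf("coords (%d rows) and values (%d rows) must align",
          nrow(coords), nrow(values))
  if (is.null(colnames(values))) stopf("`values` must have marker column names")
  structure(list(coords = coords, values = values, stage = stage),
            class = "pixel_table")
}

#' @export
print.pixel_table <- function(x, ...) {
  cat(sprintf("<pixel_table> %d pixels x %d markers, stage = %s, %d FOV(s)\n",
              nrow(x$values), ncol(x$values), x$stage,
              length(unique(x$coords$fov))))
  invisible(x)
}

#' @export
dim.pixel_table <- function(x) dim(x$values)

# reflect-padded index vector for 1-D convolution
.reflect_idx <- function(n, r) {
  if (r == 0) return(seq_len(n))
  left <- pmin(pmax(r:1, 1L), n)
  right <- pmin(pmax(n:(n - r + 1L), 1L), n)
  c(left, seq_len(n), right)
}

# separable Gaussian convolution of a matrix, reflect boundary
.gauss_blur_matrix <- function(mat, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  # along rows (vertical)
  padded <- mat[.reflect_idx(h, r), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(kernel))
    out <- out + kernel[j] * padded[(j - 1L) + seq_len(h), , drop = FALSE]
  # along columns (horizontal)
  padded <- out[, .reflect_idx(w, r), drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(kernel))
    out <- out + kernel[j] * padded[, (j - 1L) + seq_len(w), drop = FALSE]
  out
}

#' Discrete Gaussian kernel (truncated at 4 sigma, normalized)
#'
#' @param sigma standard deviation in pixels.
#' @return numeric vector of kernel weights.
#' @keywords internal
gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian-smooth every channel of a marker image
#'
#' Each channel is independently convolved with a 2-D Gaussian of standard
#' deviation `sigma` (separable kernel truncated at 4 sigma, reflect
#' boundary). Smoothing compensates for capture dropout in the raw counts,
#' analogous to smoothing over transcript dropout in scRNA-seq.
#' `sigma = 0` returns the input unchanged.
#'
#' @param image a [multichannel_image].
#' @param sigma blur standard deviation in pixels (>= 0); 2 is the default
#'   used throughout, with smaller or zero values appropriate for small
#'   histological regions or inherently low-resolution modalities.
#' @return a smoothed [multichannel_image].
#' @export
smooth_channels <- function(image, sigma = 2) {
  if (length(sigma) != 1 || is.na(sigma) || sigma < 0)
    stopf("`sigma` must be a single nonnegative number")
  if (sigma == 0) return(image)
  kernel <- gaussian_kernel(sigma)
  out <- image$data
  for (ch in seq_len(dim(out)[3]))
    out[, , ch] <- .gauss_blur_matrix(image$data[, , ch], kernel)
  out[out < 0] <- 0
  multichannel_image(image$fov_id, image$marker_names, out)
}

#' Extract retained pixels from a marker image into a pixel table
#'
#' Retains pixels that (i) lie inside `region_mask` when one is given,
#' (ii) pass the strict positivity filter when one is given, and (iii) are
#' not zero across all clustering markers. Pixels from several FOVs are
#' pooled downstream with [bind_pixel_tables]: clustering always runs on
#' the aggregate of all FOVs.
#'
#' @param image a [multichannel_image] (typically already smoothed).
#' @param region_mask optional binary/logical matrix of the image size;
#'   only pixels with a nonzero mask value are considered.
#' @param positivity_filter optional `list(marker =, threshold =)`: keep
#'   only pixels with `value > threshold` for that marker (strict).
#' @param stage stage label recorded on the result (`"smoothed"` when the
#'   input has been blurred, `"raw"` otherwise).
#' @return a [pixel_table] with 0-based `(fov, row, col)` coordinates.
#' @export
extract_pixels <- function(image, region_mask = NULL, positivity_filter = NULL,
                           stage = "smoothed") {
  d <- dim(image$data)
  h <- d[1]; w <- d[2]; m <- d[3]
  flat <- matrix(image$data, nrow = h * w, ncol = m)
  colnames(flat) <- image$marker_names

  keep <- rowSums(flat) > 0
  if (!is.null(region_mask)) {
    if (!all(dim(region_mask) == c(h, w)))
      stopf("region mask dimensions (%d x %d) do not match image (%d x %d)",
            nrow(region_mask), ncol(region_mask), h, w)
    keep <- keep & (as.vector(region_mask) != 0)
  }
  if (!is.null(positivity_filter)) {
    marker <- positivity_filter$marker
    if (!marker %in% image$marker_names)
      stopf("positivity filter marker \"%s\" is not in the image", marker)
    keep <- keep & (flat[, marker] > positivity_filter$threshold)
  }

  idx <- which(keep)
  # column-major flattening: linear index -> 0-based (row, col)
  row0 <- (idx - 1L) %% h
  col0 <- (idx - 1L) %/% h
  coords <- data.frame(fov = rep(image$fov_id, length(idx)),
                       row = row0, col = col0,
                       stringsAsFactors = FALSE)
  pixel_table(coords, flat[idx, , drop = FALSE], stage = stage)
}

#' Concatenate pixel tables from several FOVs
#'
#' @param tables list of [pixel_table]s at the same stage with identical
#'   marker columns.
#' @return one pooled [pixel_table].
#' @export
bind_pixel_tables <- function(tables) {
  if (!length(tables)) stopf("no pixel tables to bind")
  stages <- unique(vapply(tables, function(t) t$stage, character(1)))
  if (length(stages) != 1) stopf("pixel tables are at different stages")
  cols <- colnames(tables[[1]]$values)
  for (t in tables)
    if (!identical(colnames(t$values), cols)) stopf("marker columns differ across tables")
  pixel_table(do.call(rbind, lapply(tables, function(t) t$coords)),
              do.call(rbind, lapply(tables, function(t) t$values)),
              stage = stages)
}

#' Pixel normalization: divide each pixel by its total signal
#'
#' After this step every retained pixel's marker values sum to 1, so only
#' the ratio between markers — the phenotyping information — remains.
#' This is the mechanism that makes clustering invariant to per-image
#' intensity scaling (instrument drift, staining variation).
#'
#' @param table a [pixel_table] at stage `raw` or `smoothed` with no
#'   all-zero rows.
#' @return the table at stage `pixel_normalized`; rows sum to 1 within
#'   1e-9.
#' @export
normalize_pixels <- function(table) {
  if (!table$stage %in% c("raw", "smoothed"))
    stopf("pixel normalization expects a raw or smoothed table, got stage %s",
          table$stage)
  sums <- rowSums(table$values)
  if (any(sums == 0))
    stopf("%d all-zero pixel row(s) present; they must be excluded before normalization",
          sum(sums == 0))
  pixel_table(table$coords, table$values / sums, stage = "pixel_normalized")
}

#' Fit the 99.9th-percentile marker normalization
#'
#' Computes, per marker, the `quantile` (default 0.999) of that marker's
#' values over all retained pixels of all FOVs pooled (linear-interpolation
#' quantile). Dividing by these values gives every marker a comparable
#' contribution to the clustering, preventing systematically bright
#' markers from dominating. Percentiles are always fitted on the full
#' retained pixel set, before any subsampling.
#'
#' @param table a [pixel_table] at stage `pixel_normalized`.
#' @param quantile quantile level in (0, 1].
#' @return an object of class `norm_params`: `list(quantile,
#'   per_marker_divisor)`.
#' @export
fit_percentile_norm <- function(table, quantile = 0.999) {
  if (table$stage != "pixel_normalized")
    stopf("percentile normalization is fitted on pixel-normalized values, got stage %s",
          table$stage)
  if (!is_fraction(quantile, 0, 1)) stopf("`quantile` must be in (0, 1]")
  div <- apply(table$values, 2, stats::quantile, probs = quantile,
               names = FALSE, type = 7)
  zero <- colnames(table$values)[div <= 0]
  if (length(zero))
    stopf("marker(s) with zero %g-quantile: %s; exclude them from the clustering panel",
          quantile, paste(zero, collapse = ", "))
  structure(list(quantile = quantile,
                 per_marker_divisor = stats::setNames(div, colnames(table$values))),
            class = "norm_params")
}

#' @param params a `norm_params` object fitted on the same marker set.
#' @rdname fit_percentile_norm
#' @export
apply_percentile_norm <- function(table, params) {
  div <- params$per_marker_divisor
  if (!identical(names(div), colnames(table$values)))
    stopf("normalization parameters were fitted on a different marker set")
  pixel_table(table$coords,
              sweep(table$values, 2, div, "/"),
              stage = "fully_normalized")
}

#' Serialize / load normalization parameters as JSON
#'
#' @param params a `norm_params` object.
#' @param path JSON file path.
#' @return `path` / a `norm_params` object.
#' @export
save_norm_params <- function(params, path) {
  jsonlite::write_json(list(quantile = params$quantile,
                            per_marker_divisor = as.list(params$per_marker_divisor)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_norm_params
#' @export
load_norm_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(quantile = x$quantile,
                 per_marker_divisor = unlist(x$per_marker_divisor)),
            class = "norm_params")
}

#' Uniform pixel subsampling for SOM training
#'
#' Draws `floor(fraction * n)` rows without replacement (deterministic per
#' seed, original row order preserved). Training the SOM on a 10% subsample
#' keeps large datasets tractable; assignment always uses all pixels.
#'
#' @param table a [pixel_table].
#' @param fraction sampling fraction in (0, 1]; 1 returns the table
#'   unchanged.
#' @param seed RNG seed.
#' @return a subsampled [pixel_table].
#' @export
subsample_pixels <- function(table, fraction, seed) {
  if (nrow(table$values) == 0) stopf("cannot subsample an empty pixel table")
  if (!is_fraction(fraction, 0, 1)) stopf("`fraction` must be in (0, 1]")
  if (fraction == 1) return(table)
  n <- nrow(table$values)
  k <- floor(fraction * n)
  idx <- with_seed(seed, sort(sample.int(n, k)))
  pixel_table(table$coords[idx, , drop = FALSE],
              table$values[idx, , drop = FALSE],
              stage = table$stage)
}
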