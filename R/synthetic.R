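#' Synthetic multiplexed-image data with known ground truth
#'
#' The generator emulates the phenomena the pipeline is built to handle:
#' latent pixel phenotypes with characteristic marker signatures, Poisson
#' counting noise, per-pixel signal dropout, per-FOV intensity scaling
#' (instrument-sensitivity batch effects), and boundary spillover between
#' adjacent cells. Every FOV comes with a matched segmentation mask and
#' ground-truth phenotype labels, so recovery can be scored exactly.
#'
#' @name synthetic_data
NULL

#' Generate a phenotype-by-marker signature matrix
#'
#' Each phenotype gets a distinct random subset of `markers_per_phenotype`
#' markers: one dominant marker with high mean intensity and (if the subset
#' has more than one member) secondary markers at lower intensity. Markers
#' outside the subset are exactly zero, so background / all-zero exclusion
#' is exercised downstream.
#'
#' @param n_phenotypes number of latent phenotypes (>= 1).
#' @param n_markers number of markers in the panel.
#' @param markers_per_phenotype subset size per phenotype (1..n_markers).
#' @param seed RNG seed; output is deterministic per seed.
#' @param intensity length-2 numeric: mean intensity ranges are
#'   `[intensity[1]*0.8, intensity[1]*1.2]` for the dominant marker and
#'   `[intensity[2]*0.7, intensity[2]*1.3]` for secondary markers.
#' @return an object of class `signature_matrix` with fields
#'   `phenotype_names`, `marker_names`, `signatures` (matrix, phenotypes x
#'   markers).
#' @export
make_signatures <- function(n_phenotypes, n_markers, markers_per_phenotype,
                            seed, intensity = c(10, 3)) {
  if (!is_count(n_phenotypes)) stopf("`n_phenotypes` must be a positive integer")
  if (!is_count(n_markers)) stopf("`n_markers` must be a positive integer")
  if (!is_count(markers_per_phenotype) || markers_per_phenotype > n_markers)
    stopf("`markers_per_phenotype` must be an integer in [1, n_markers]")
  if (choose(n_markers, markers_per_phenotype) < n_phenotypes)
    stopf("cannot assign %d distinct marker subsets of size %d from %d markers",
          n_phenotypes, markers_per_phenotype, n_markers)

  marker_names <- sprintf("marker_%02d", seq_len(n_markers))
  phenotype_names <- sprintf("pheno_%02d", seq_len(n_phenotypes))
  sig <- matrix(0, n_phenotypes, n_markers,
                dimnames = list(phenotype_names, marker_names))
  with_seed(seed, {
    # Draw subsets from concatenated random permutations of the marker list:
    # whenever n_phenotypes * markers_per_phenotype >= n_markers, every
    # marker is used by at least one phenotype (panels are chosen so every
    # clustering marker is informative). Redraw on within-subset duplicates
    # (possible at permutation boundaries) or repeated subsets.
    slots <- n_phenotypes * markers_per_phenotype
    subsets <- NULL
    for (try in seq_len(10000L)) {
      seq_markers <- integer(0)
      while (length(seq_markers) < slots)
        seq_markers <- c(seq_markers, sample.int(n_markers))
      blocks <- split(seq_markers[seq_len(slots)],
                      rep(seq_len(n_phenotypes), each = markers_per_phenotype))
      keys <- vapply(blocks, function(b) paste(sort(b), collapse = ","), character(1))
      ok <- all(vapply(blocks, function(b) !anyDuplicated(b), logical(1))) &&
        !anyDuplicated(keys)
      if (ok) { subsets <- blocks; break }
    }
    if (is.null(subsets)) stopf("failed to draw distinct marker subsets")
    for (p in seq_len(n_phenotypes)) {
      subset <- subsets[[p]]
      dominant <- subset[1]
      sig[p, dominant] <- stats::runif(1, 0.8 * intensity[1], 1.2 * intensity[1])
      if (markers_per_phenotype > 1) {
        sec <- subset[-1]
        sig[p, sec] <- stats::runif(length(sec), 0.7 * intensity[2], 1.3 * intensity[2])
      }
    }
  })
  structure(list(phenotype_names = phenotype_names,
                 marker_names = marker_names,
                 signatures = sig),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d phenotypes x %d markers\n",
              length(x$phenotype_names), length(x$marker_names)))
  invisible(x)
}

#' Default noise configuration for the simulator
#'
#' `poisson_scale = 1` draws plain Poisson counts around the expected
#' intensity (0 disables noise entirely); `dropout_prob` zeroes each
#' in-cell pixel/marker value independently; `gain` scales all expected
#' intensities (the per-FOV batch-effect dial).
#'
#' @param poisson_scale Poisson scaling factor (0 = noise-free).
#' @param dropout_prob per pixel-marker dropout probability in `[0, 1)`.
#' @param gain multiplicative intensity gain (> 0).
#' @return a list with the three components.
#' @export
noise_config <- function(poisson_scale = 1, dropout_prob = 0.05, gain = 1) {
  if (!is_fraction(dropout_prob, 0, 1, lo_open = FALSE, hi_open = TRUE))
    stopf("`dropout_prob` must be in [0, 1)")
  if (poisson_scale < 0) stopf("`poisson_scale` must be >= 0")
  if (gain <= 0) stopf("`gain` must be > 0")
  list(poisson_scale = poisson_scale, dropout_prob = dropout_prob, gain = gain)
}

# Pixels of an ellipse footprint, 1-based matrix indices.
.ellipse_pixels <- function(h, w, cy, cx, a, b, theta) {
  r <- ceiling(max(a, b))
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  grid <- expand.grid(row = rows, col = cols)
  dy <- grid$row - cy
  dx <- grid$col - cx
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  grid[inside, , drop = FALSE]
}

# Chebyshev dilation of a logical mask by `width` pixels.
.dilate <- function(mask, width) {
  if (width <= 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dr in -width:width) {
    rows_src <- pmin(pmax(seq_len(h) - dr, 1L), h)
    shifted_r <- mask[rows_src, , drop = FALSE]
    for (dc in -width:width) {
      if (dr == 0 && dc == 0) next
      cols_src <- pmin(pmax(seq_len(w) - dc, 1L), w)
      out <- out | shifted_r[, cols_src, drop = FALSE]
    }
  }
  out
}

#' Simulate one field of view
#'
#' Cells are non-overlapping rotated ellipses placed by rejection sampling,
#' each carrying one phenotype. Expected in-cell intensities are `gain *`
#' the phenotype's signature row; with `spillover_width > 0`, pixels of a
#' neighboring cell within `spillover_width` (Chebyshev) of a cell's
#' footprint additionally receive `spillover_frac` of that cell's mean
#' boundary intensity, reproducing the boundary-contamination failure mode
#' of dense tissue. Background pixels are zero.
#'
#' @param signatures a [make_signatures] result.
#' @param height,width image size in pixels.
#' @param n_cells number of cells to place.
#' @param noise a [noise_config] list.
#' @param spillover_width spillover reach in pixels (0 = none).
#' @param spillover_frac fraction of boundary intensity transferred.
#' @param cell_radius length-2 range of ellipse semi-axes, pixels.
#' @param cell_brightness_sd SD (log scale) of a per-cell lognormal
#'   brightness factor emulating biological intensity variation between
#'   cells of the same phenotype (receptor up-/down-regulation); 0
#'   disables it.
#' @param seed RNG seed.
#' @param fov_id FOV identifier.
#' @return list with `image` ([multichannel_image]), `mask` ([label_map]
#'   of cell ids 1..n_cells), and `truth` (list: `pixel_labels` label map of
#'   phenotype indices, `cell_labels` data frame `(fov, cell_id,
#'   phenotype)`, `signatures`).
#' @export
simulate_fov <- function(signatures, height, width, n_cells,
                         noise = noise_config(), spillover_width = 0,
                         spillover_frac = 0.5, cell_radius = c(3.5, 7),
                         cell_brightness_sd = 0, seed = 1, fov_id = "fov01") {
  sig <- signatures$signatures
  n_phen <- nrow(sig)
  n_markers <- ncol(sig)
  if (!is_count(n_cells)) stopf("`n_cells` must be a positive integer")

  with_seed(seed, {
    mask <- matrix(0L, height, width)
    phen_of_cell <- sample(rep_len(seq_len(n_phen), n_cells))
    cell_gain <- if (cell_brightness_sd > 0) {
      stats::rlnorm(n_cells, meanlog = 0, sdlog = cell_brightness_sd)
    } else rep(1, n_cells)
    cell_pixels <- vector("list", n_cells)
    for (cell in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(300L)) {
        a <- stats::runif(1, cell_radius[1], cell_radius[2])
        b <- stats::runif(1, cell_radius[1], cell_radius[2])
        theta <- stats::runif(1, 0, pi)
        r <- max(a, b)
        if (2 * r + 2 >= min(height, width))
          stopf("image too small for cells of radius %.1f", r)
        cy <- stats::runif(1, r + 1, height - r)
        cx <- stats::runif(1, r + 1, width - r)
        px <- .ellipse_pixels(height, width, cy, cx, a, b, theta)
        if (nrow(px) < 3) next
        idx <- cbind(px$row, px$col)
        if (all(mask[idx] == 0L)) {
          mask[idx] <- cell
          cell_pixels[[cell]] <- idx
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("failed to place cell %d of %d after bounded retries; reduce n_cells or cell_radius",
              cell, n_cells)
    }

    # expected intensities
    expected <- array(0, dim = c(height, width, n_markers))
    for (cell in seq_len(n_cells)) {
      idx <- cell_pixels[[cell]]
      row_sig <- cell_gain[cell] * noise$gain * sig[phen_of_cell[cell], ]
      for (j in seq_len(n_markers)) {
        if (row_sig[j] > 0) expected[cbind(idx, j)] <- row_sig[j]
      }
    }

    # additive boundary spillover into adjacent cells
    if (spillover_width > 0) {
      for (cell in seq_len(n_cells)) {
        foot <- matrix(FALSE, height, width)
        foot[cell_pixels[[cell]]] <- TRUE
        halo <- .dilate(foot, as.integer(spillover_width)) & !foot
        recipients <- which(halo & mask > 0L & mask != cell, arr.ind = TRUE)
        if (nrow(recipients) == 0) next
        add <- spillover_frac * cell_gain[cell] * noise$gain * sig[phen_of_cell[cell], ]
        for (j in seq_len(n_markers)) {
          if (add[j] > 0)
            expected[cbind(recipients, j)] <- expected[cbind(recipients, j)] + add[j]
        }
      }
    }

    # Poisson counting noise, then dropout
    data <- expected
    nz <- which(expected > 0)
    if (noise$poisson_scale > 0 && length(nz)) {
      s <- noise$poisson_scale
      data[nz] <- s * stats::rpois(length(nz), expected[nz] / s)
    }
    if (noise$dropout_prob > 0 && length(nz)) {
      drop <- stats::runif(length(nz)) < noise$dropout_prob
      data[nz[drop]] <- 0
    }

    truth_map <- matrix(0L, height, width)
    for (cell in seq_len(n_cells))
      truth_map[cell_pixels[[cell]]] <- phen_of_cell[cell]

    list(
      image = multichannel_image(fov_id, signatures$marker_names, data),
      mask = label_map(fov_id, mask),
      truth = list(
        pixel_labels = label_map(fov_id, truth_map,
                                 legend = stats::setNames(signatures$phenotype_names,
                                                          seq_len(n_phen))),
        cell_labels = data.frame(fov = fov_id,
                                 cell_id = seq_len(n_cells),
                                 phenotype = phen_of_cell,
                                 stringsAsFactors = FALSE),
        signatures = signatures
      )
    )
  })
}

#' Simulate and write a multi-FOV dataset
#'
#' Writes the on-disk layout consumed by [load_fov] and the pipelines:
#' `out_dir/<fov>/<marker>.tiff`, `out_dir/<fov>/segmentation.tiff`,
#' `out_dir/<fov>/ground_truth.tiff`, plus `out_dir/cell_phenotypes.csv`
#' and a `dataset.json` manifest (markers, FOV ids, per-FOV seeds and
#' gains). `per_fov_gain` multiplies all channels of a FOV, emulating
#' drifts in instrument sensitivity between acquisitions.
#'
#' @param signatures a [make_signatures] result.
#' @param n_fovs number of FOVs.
#' @param per_fov_gain numeric vector of length `n_fovs`.
#' @param out_dir output dataset directory.
#' @param seed base RNG seed; FOV `i` uses `seed + 1000 * (i - 1)` unless
#'   `fov_seeds` is given.
#' @param fov_seeds optional explicit per-FOV seeds.
#' @param height,width,n_cells,noise,spillover_width,spillover_frac,cell_radius
#'   forwarded to [simulate_fov].
#' @return invisibly, a list with `dir`, `fov_ids`, `markers`, and the
#'   in-memory per-FOV simulation results (`fovs`).
#' @export
simulate_dataset <- function(signatures, n_fovs, per_fov_gain, out_dir,
                             height = 128, width = 128, n_cells = 40,
                             noise = noise_config(), spillover_width = 0,
                             spillover_frac = 0.5, cell_radius = c(3.5, 7),
                             cell_brightness_sd = 0, seed = 1, fov_seeds = NULL) {
  if (length(per_fov_gain) != n_fovs)
    stopf("`per_fov_gain` must have length n_fovs (%d)", n_fovs)
  if (is.null(fov_seeds)) fov_seeds <- seed + 1000L * (seq_len(n_fovs) - 1L)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create dataset directory: %s", out_dir)

  fov_ids <- sprintf("fov%02d", seq_len(n_fovs))
  fovs <- vector("list", n_fovs)
  cell_rows <- list()
  for (i in seq_len(n_fovs)) {
    fov_noise <- noise
    fov_noise$gain <- noise$gain * per_fov_gain[i]
    sim <- simulate_fov(signatures, height, width, n_cells,
                        noise = fov_noise, spillover_width = spillover_width,
                        spillover_frac = spillover_frac,
                        cell_radius = cell_radius,
                        cell_brightness_sd = cell_brightness_sd,
                        seed = fov_seeds[i], fov_id = fov_ids[i])
    fdir <- file.path(out_dir, fov_ids[i])
    save_fov(sim$image, fdir)
    save_label_map(sim$mask, file.path(fdir, "segmentation.tiff"))
    save_label_map(sim$truth$pixel_labels, file.path(fdir, "ground_truth.tiff"))
    cell_rows[[i]] <- sim$truth$cell_labels
    fovs[[i]] <- sim
  }
  utils::write.csv(do.call(rbind, cell_rows),
                   file.path(out_dir, "cell_phenotypes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(markers = signatures$marker_names,
         phenotypes = signatures$phenotype_names,
         signatures = signatures$signatures,
         fov_ids = fov_ids,
         fov_seeds = fov_seeds,
         per_fov_gain = per_fov_gain,
         noise = noise,
         spillover_width = spillover_width,
         height = height, width = width, n_cells = n_cells,
         seed = seed),
    file.path(out_dir, "dataset.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, fov_ids = fov_ids,
                 markers = signatures$marker_names, fovs = fovs))
}

#' Read the manifest of a simulated dataset
#'
#' @param dataset_root dataset directory containing `dataset.json`.
#' @return the manifest as a list.
#' @export
read_dataset_manifest <- function(dataset_root) {
  p <- file.path(dataset_root, "dataset.json")
  if (!file.exists(p)) stopf("no dataset.json in %s", dataset_root)
  jsonlite::read_json(p, simplifyVector = TRUE)
}
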