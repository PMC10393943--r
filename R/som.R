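#' Self-organizing map configuration
#'
#' Defaults follow the settings used throughout the pipeline: a 10 x 10
#' node grid (100 clusters — deliberate overclustering ahead of
#' metaclustering), start learning rate 0.05 decaying linearly to 0.01,
#' random (data-sampled) initialization, Euclidean distance, and 10 full
#' training passes over the data.
#'
#' @param grid_rows,grid_cols SOM grid dimensions (grid size >= 2 nodes).
#' @param alpha_start,alpha_end learning-rate schedule endpoints,
#'   `0 < alpha_end <= alpha_start < 1`.
#' @param passes full sweeps over the training data (>= 1).
#' @param distance distance function name; only `"euclidean"` is
#'   implemented.
#' @param init node initialization; `"sample"` draws `n_nodes` distinct
#'   training rows.
#' @param radius_start,radius_end neighborhood radius schedule (grid
#'   Chebyshev units); `radius_start = NULL` uses half the grid diagonal.
#' @param seed RNG seed for shuffling and initialization.
#' @return an object of class `som_config`.
#' @export
som_config <- function(grid_rows = 10, grid_cols = 10,
                       alpha_start = 0.05, alpha_end = 0.01,
                       passes = 10, distance = "euclidean",
                       init = "sample", radius_start = NULL,
                       radius_end = 1, seed = 1) {
  if (!is_count(grid_rows) || !is_count(grid_cols) || grid_rows * grid_cols < 2)
    stopf("SOM grid must have at least 2 nodes")
  if (!(alpha_end > 0 && alpha_end <= alpha_start && alpha_start < 1))
    stopf("learning rates must satisfy 0 < alpha_end <= alpha_start < 1")
  if (!is_count(passes)) stopf("`passes` must be a positive integer")
  if (!identical(distance, "euclidean")) stopf("only Euclidean distance is supported")
  if (is.null(radius_start))
    radius_start <- sqrt(grid_rows^2 + grid_cols^2) / 2
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 alpha_start = alpha_start, alpha_end = alpha_end,
                 passes = as.integer(passes),
                 distance = distance, init = init,
                 radius_start = radius_start, radius_end = radius_end,
                 seed = as.integer(seed)),
            class = "som_config")
}

#' Train a self-organizing map
#'
#' Online (stochastic) training: `passes` seeded-shuffled sweeps over the
#' rows of `data`, per-step learning rate decaying linearly from
#' `alpha_start` to `alpha_end` over all steps, best-matching unit by
#' minimal Euclidean distance, and a Gaussian neighborhood over grid
#' Chebyshev distance whose radius decays linearly from half the grid
#' diagonal to 1. Deterministic per seed.
#'
#' @param data numeric matrix (observations x features), finite, with at
#'   least as many rows as SOM nodes.
#' @param config a [som_config].
#' @return an object of class `som_model`: `list(config, weights,
#'   feature_names)` with `weights` a `n_nodes x n_features` matrix.
#' @export
train_som <- function(data, config = som_config()) {
  data <- as.matrix(data)
  n <- nrow(data)
  n_nodes <- config$grid_rows * config$grid_cols
  if (n < n_nodes)
    stopf("need at least %d training rows for a %d x %d grid, got %d",
          n_nodes, config$grid_rows, config$grid_cols, n)
  if (!all(is.finite(data))) stopf("training data must be finite")

  with_seed(config$seed, {
    init_idx <- sample.int(n, n_nodes)
    shuffles <- unlist(lapply(seq_len(config$passes),
                              function(p) sample.int(n)))
  })
  weights <- data[init_idx, , drop = FALSE]
  weights <- som_train_cpp(data, weights, as.integer(shuffles - 1L),
                           config$grid_rows, config$grid_cols,
                           config$alpha_start, config$alpha_end,
                           config$radius_start, config$radius_end)
  rownames(weights) <- NULL
  structure(list(config = config,
                 weights = weights,
                 feature_names = colnames(data)),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d grid, %d features, seed %d\n",
              x$config$grid_rows, x$config$grid_cols,
              ncol(x$weights), x$config$seed))
  invisible(x)
}

#' Assign observations to SOM clusters
#'
#' Each row is mapped to the node with minimal Euclidean distance; ties
#' break to the lowest node id. Assignment is a pure function of the model
#' and the row — it never depends on the other rows.
#'
#' @param model a [som_model].
#' @param data numeric matrix with the model's feature columns.
#' @return integer vector of cluster ids in `1..n_nodes`.
#' @export
assign_som <- function(model, data) {
  data <- as.matrix(data)
  if (ncol(data) != ncol(model$weights))
    stopf("feature count (%d) does not match the model (%d)",
          ncol(data), ncol(model$weights))
  if (!is.null(colnames(data)) && !is.null(model$feature_names) &&
      !identical(colnames(data), model$feature_names))
    stopf("feature names do not match the model")
  som_assign_cpp(data, model$weights)
}

#' Serialize / load a SOM model as JSON
#'
#' @param model a [som_model].
#' @param path JSON file path.
#' @return `path` / a [som_model].
#' @export
save_som <- function(model, path) {
  jsonlite::write_json(
    list(config = unclass(model$config),
         weights = model$weights,
         feature_names = model$feature_names),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_som
#' @export
load_som <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(som_config, x$config[setdiff(names(x$config), character(0))])
  w <- as.matrix(x$weights)
  colnames(w) <- x$feature_names
  structure(list(config = cfg, weights = w, feature_names = x$feature_names),
            class = "som_model")
}
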