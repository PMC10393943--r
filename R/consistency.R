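#' Replicate clustering runs
#'
#' A set of cluster assignment vectors over one shared observation list,
#' produced by re-running the pipeline with different seeds. Exclusion of
#' pixels is deterministic, so the retained-pixel list is identical across
#' replicates and the vectors align element-wise.
#'
#' @param assignments list of integer assignment vectors, equal lengths.
#' @param seeds the seeds that produced them.
#' @param coords optional shared coordinate data frame.
#' @return an object of class `replicate_set`.
#' @export
replicate_set <- function(assignments, seeds = seq_along(assignments),
                          coords = NULL) {
  lens <- vapply(assignments, length, integer(1))
  if (length(unique(lens)) != 1)
    stopf("replicate assignment vectors differ in length")
  structure(list(assignments = assignments, seeds = seeds, coords = coords),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %d replicates x %d observations\n",
              length(x$assignments), length(x$assignments[[1]])))
  invisible(x)
}

#' Run replicate pixel clusterings for consistency scoring
#'
#' Runs the full pixel pipeline `n` times (default 5), identical in every
#' respect except the seed (`base_seed`, `base_seed + 1`, ...).
#'
#' @param config a [pixel_run_config] (its `output_dir` is ignored for the
#'   replicates).
#' @param n number of replicates.
#' @param base_seed seed of the first replicate.
#' @param level `"metacluster"` or `"som"`: which assignment level the
#'   replicate vectors carry.
#' @return a [replicate_set].
#' @export
run_replicates <- function(config, n = 5, base_seed = config$seed,
                           level = c("metacluster", "som")) {
  level <- match.arg(level)
  seeds <- base_seed + seq_len(n) - 1L
  assignments <- vector("list", n)
  coords <- NULL
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    cfg$som$seed <- cfg$seed + 2L
    cfg$consensus$seed <- cfg$seed + 3L
    cfg$output_dir <- NULL
    res <- tryCatch(run_pixel_clustering(cfg),
                    error = function(e) stopf("replicate %d (seed %d) failed: %s",
                                              i, seeds[i], conditionMessage(e)))
    assignments[[i]] <- if (level == "metacluster") res$metaclusters else res$assignments
    if (is.null(coords)) coords <- res$table$coords
  }
  replicate_set(assignments, seeds = seeds, coords = coords)
}

#' Minimum number of clusters needed to cover a fraction of a cluster
#'
#' Given the overlap counts of one reference cluster against every cluster
#' of another replicate, sorts the counts in descending order (ties broken
#' by ascending cluster id) and returns the smallest number of clusters
#' whose cumulative count reaches `coverage * n_pixels`. The coverage
#' target is the exact real-valued product: 95% of a 1,000-pixel cluster
#' is 950 pixels; 95% of 4 pixels (3.8) requires all 4.
#'
#' @param overlap_counts integer vector of per-cluster overlap counts.
#' @param n_pixels reference cluster size; must equal `sum(overlap_counts)`.
#' @param coverage coverage fraction in (0, 1].
#' @return integer: the minimum number of clusters.
#' @export
min_clusters_to_cover <- function(overlap_counts, n_pixels, coverage = 0.95) {
  if (!is_fraction(coverage, 0, 1)) stopf("`coverage` must be in (0, 1]")
  if (n_pixels < 1) stopf("`n_pixels` must be >= 1")
  if (sum(overlap_counts) != n_pixels)
    stopf("overlap counts sum to %d, expected n_pixels = %d",
          sum(overlap_counts), n_pixels)
  ord <- order(-overlap_counts, seq_along(overlap_counts))
  cum <- cumsum(overlap_counts[ord])
  # integer counts vs real threshold: the 1e-9 slack only absorbs binary
  # representation error of coverage * n, never a whole pixel
  target <- coverage * n_pixels - 1e-9
  as.integer(which(cum >= target)[1])
}

# per-cluster pairwise scores for one ordered replicate pair (r vs s):
# named vector over clusters of r
.pairwise_cover <- function(a_r, a_s, coverage) {
  tab <- table(a_r, a_s)
  sizes <- rowSums(tab)
  out <- stats::setNames(numeric(nrow(tab)), rownames(tab))
  for (i in seq_len(nrow(tab))) {
    counts <- as.vector(tab[i, ])
    ord <- order(-counts, seq_along(counts))
    cum <- cumsum(counts[ord])
    out[i] <- which(cum >= coverage * sizes[i] - 1e-9)[1]
  }
  out
}

#' Cluster consistency score
#'
#' The reproducibility statistic for stochastic clustering. For each
#' replicate `r` and each of its clusters `c`, the score is the mean —
#' over the other replicates — of the minimum number of clusters needed to
#' cover `coverage` (default 95%) of `c`'s members. Scores are mapped back
#' to observations: each observation receives the score of its cluster in
#' each replicate, and those values are averaged into one per-observation
#' score. A score of 1 is perfect (the same observations always travel
#' together); larger values mean an observation's cluster is smeared
#' across many clusters in other runs.
#'
#' @param reps a [replicate_set] with >= 2 replicates.
#' @param coverage coverage fraction (default 0.95).
#' @return an object of class `consistency_result`: `per_cluster_scores`
#'   (list, one named vector per replicate), `per_observation_scores`,
#'   `coverage`, and `summary` (mean and SD over observations).
#' @export
cluster_consistency <- function(reps, coverage = 0.95) {
  n_rep <- length(reps$assignments)
  if (n_rep < 2) stopf("consistency requires at least 2 replicates")
  if (!is_fraction(coverage, 0, 1)) stopf("`coverage` must be in (0, 1]")
  n_obs <- length(reps$assignments[[1]])

  per_cluster <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    a_r <- reps$assignments[[r]]
    pair_scores <- NULL
    for (s in setdiff(seq_len(n_rep), r)) {
      ps <- .pairwise_cover(a_r, reps$assignments[[s]], coverage)
      pair_scores <- if (is.null(pair_scores)) ps else pair_scores + ps
    }
    per_cluster[[r]] <- pair_scores / (n_rep - 1)
  }

  obs_scores <- numeric(n_obs)
  for (r in seq_len(n_rep)) {
    sc <- per_cluster[[r]]
    obs_scores <- obs_scores + sc[as.character(reps$assignments[[r]])]
  }
  obs_scores <- unname(obs_scores) / n_rep

  structure(list(per_cluster_scores = per_cluster,
                 per_observation_scores = obs_scores,
                 coverage = coverage,
                 summary = c(mean = mean(obs_scores), sd = stats::sd(obs_scores))),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("<consistency_result> %d observations, coverage %.2f: %.3f +/- %.3f\n",
              length(x$per_observation_scores), x$coverage,
              x$summary["mean"], x$summary["sd"]))
  invisible(x)
}

#' Mean consistency score across coverage thresholds
#'
#' Recomputes the per-observation consistency at each coverage value.
#' Lowering the threshold can only lower scores and raising it can only
#' raise them, so the means are monotone non-decreasing in coverage.
#'
#' @param reps a [replicate_set].
#' @param coverages coverage values in (0, 1].
#' @return data frame with columns `coverage` and `mean_score`.
#' @export
coverage_sweep <- function(reps, coverages) {
  if (!length(coverages) || any(vapply(coverages, function(cv) !is_fraction(cv, 0, 1), logical(1))))
    stopf("coverages must lie in (0, 1]")
  means <- vapply(coverages, function(cv) {
    unname(cluster_consistency(reps, coverage = cv)$summary["mean"])
  }, numeric(1))
  data.frame(coverage = coverages, mean_score = means)
}

#' Per-FOV consistency score maps
#'
#' Renders the per-observation scores back onto image geometry as
#' continuous-valued images (excluded pixels are 0).
#'
#' @param reps a [replicate_set] carrying coordinates.
#' @param result a matching [cluster_consistency] result.
#' @param shapes named list of `c(height, width)` per FOV.
#' @return named list of numeric score matrices.
#' @export
consistency_score_maps <- function(reps, result, shapes) {
  if (is.null(reps$coords)) stopf("replicate set carries no coordinates")
  coords <- reps$coords
  out <- list()
  for (fid in names(shapes)) {
    sel <- coords$fov == fid
    m <- matrix(0, shapes[[fid]][1], shapes[[fid]][2])
    m[cbind(coords$row[sel] + 1L, coords$col[sel] + 1L)] <-
      result$per_observation_scores[sel]
    out[[fid]] <- m
  }
  out
}
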