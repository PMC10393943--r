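#' Per-cluster mean expression profiles
#'
#' The mean fully-normalized expression of every SOM cluster, plus member
#' counts. Empty clusters are kept in the table with count 0 and flagged;
#' they are excluded from z-scoring and metaclustering.
#'
#' @param table a [pixel_table] (or plain numeric matrix) of the values
#'   that were clustered.
#' @param assignments integer cluster ids aligned with the table rows.
#' @param n_clusters total number of clusters (SOM nodes); defaults to
#'   `max(assignments)`.
#' @return an object of class `cluster_profile`: `list(cluster_ids,
#'   mean_expression, counts)`.
#' @export
compute_profiles <- function(table, assignments, n_clusters = max(assignments)) {
  values <- if (inherits(table, "pixel_table")) table$values else as.matrix(table)
  if (length(assignments) != nrow(values))
    stopf("assignments (%d) do not align with table rows (%d)",
          length(assignments), nrow(values))
  counts <- tabulate(assignments, nbins = n_clusters)
  rs <- rowsum(values, assignments)
  sums <- matrix(0, n_clusters, ncol(values))
  sums[as.integer(rownames(rs)), ] <- rs
  means <- sums / ifelse(counts > 0, counts, NA_real_)
  dimnames(means) <- list(seq_len(n_clusters), colnames(values))
  structure(list(cluster_ids = seq_len(n_clusters),
                 mean_expression = means,
                 counts = counts),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> %d clusters (%d nonempty) x %d markers\n",
              length(x$cluster_ids), sum(x$counts > 0), ncol(x$mean_expression)))
  invisible(x)
}

#' Capped z-scores of cluster mean profiles
#'
#' Mean expression is z-scored per marker across the nonempty clusters
#' (sample standard deviation), then capped at `cap` from above — large
#' positive outliers are flattened so they cannot dominate the
#' metaclustering distances, while negative z-scores are left intact
#' (symmetric capping is available but off by default). Zero-variance
#' markers map to z = 0.
#'
#' @param profile a [compute_profiles] result with >= 2 nonempty clusters.
#' @param cap upper cap for z-scores (default 3).
#' @param symmetric also cap from below at `-cap`.
#' @return numeric matrix (nonempty clusters x markers), rownames = SOM
#'   cluster ids.
#' @export
zscore_cap <- function(profile, cap = 3, symmetric = FALSE) {
  keep <- profile$counts > 0
  if (sum(keep) < 2) stopf("z-scoring needs at least 2 nonempty clusters")
  x <- profile$mean_expression[keep, , drop = FALSE]
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  z <- sweep(x, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")
  z[, sdv == 0] <- 0
  z[z > cap] <- cap
  if (symmetric) z[z < -cap] <- -cap
  z
}

#' Consensus hierarchical metaclustering configuration
#'
#' The consensus recipe follows the one standard in cytometry
#' metaclustering: many rounds of item resampling, hierarchical clustering
#' (Euclidean, average linkage) of each subsample cut at `k`, co-assignment
#' tallied into a consensus matrix, and a final average-linkage clustering
#' of `1 - consensus` distances cut at `k`.
#'
#' @param k target number of metaclusters (user-chosen; no automatic
#'   selection).
#' @param iterations resampling rounds (default 100).
#' @param item_subsample fraction of cluster rows drawn per round
#'   (default 0.8; 1 disables resampling).
#' @param linkage hierarchical linkage; only `"average"` is implemented.
#' @param seed RNG seed.
#' @return an object of class `consensus_config`.
#' @export
consensus_config <- function(k, iterations = 100, item_subsample = 0.8,
                             linkage = "average", seed = 1) {
  if (!is_count(k, min = 2)) stopf("`k` must be an integer >= 2")
  if (!is_count(iterations)) stopf("`iterations` must be a positive integer")
  if (!is_fraction(item_subsample, 0, 1)) stopf("`item_subsample` must be in (0, 1]")
  if (!identical(linkage, "average")) stopf("only average linkage is supported")
  structure(list(k = as.integer(k), iterations = as.integer(iterations),
                 item_subsample = item_subsample, linkage = linkage,
                 seed = as.integer(seed)),
            class = "consensus_config")
}

#' Consensus hierarchical metaclustering of SOM cluster profiles
#'
#' @param capped capped z-score matrix from [zscore_cap] (rows = nonempty
#'   SOM clusters, rownames = their ids).
#' @param config a [consensus_config].
#' @return named integer vector: SOM cluster id -> metacluster id in
#'   `1..k`. Also carries the consensus matrix as attribute `"consensus"`.
#' @export
consensus_metacluster <- function(capped, config) {
  n <- nrow(capped)
  k <- config$k
  if (k > n) stopf("k (%d) exceeds the number of nonempty clusters (%d)", k, n)
  ids <- as.integer(rownames(capped))
  if (k == n) {  # every cluster its own metacluster
    out <- stats::setNames(seq_len(n), ids)
    attr(out, "consensus") <- diag(n)
    return(out)
  }
  size <- ceiling(config$item_subsample * n)
  if (size < k)
    stopf("item subsample of %d rows is smaller than k = %d", size, k)

  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  with_seed(config$seed, {
    for (it in seq_len(config$iterations)) {
      idx <- sort(sample.int(n, size))
      hc <- stats::hclust(stats::dist(capped[idx, , drop = FALSE]),
                          method = config$linkage)
      cl <- stats::cutree(hc, k = k)
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
      for (g in unique(cl)) {
        members <- idx[cl == g]
        co_cluster[members, members] <- co_cluster[members, members] + 1
      }
    }
  })
  consensus <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  diag(consensus) <- 1
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = config$linkage)
  mapping <- stats::cutree(hc, k = k)
  out <- stats::setNames(as.integer(mapping), ids)
  attr(out, "consensus") <- consensus
  out
}

#' Apply a cluster remap to an assignment vector
#'
#' Element-wise relabeling of SOM cluster ids into metacluster ids with
#' annotation strings, using a validated [read_remap] table.
#'
#' @param assignments integer SOM cluster ids.
#' @param remap a `remap_table`.
#' @return `list(metacluster = integer vector, annotation = character
#'   vector)`.
#' @export
apply_remap <- function(assignments, remap) {
  pos <- match(assignments, remap$som_cluster)
  if (anyNA(pos)) {
    missing_ids <- sort(unique(assignments[is.na(pos)]))
    stopf("assignment contains som cluster(s) not covered by the remap: %s",
          paste(missing_ids, collapse = ", "))
  }
  list(metacluster = remap$metacluster[pos],
       annotation = remap$annotation[pos])
}

#' Build a remap table from a consensus mapping
#'
#' The output serves as the starting point for manual editing: metacluster
#' ids come from consensus and annotations are placeholders
#' (`"meta_<id>"`).
#'
#' @param mapping named vector from [consensus_metacluster].
#' @return a `remap_table`.
#' @export
remap_from_mapping <- function(mapping) {
  as_remap_table(data.frame(
    som_cluster = as.integer(names(mapping)),
    metacluster = as.integer(mapping),
    annotation = sprintf("meta_%d", as.integer(mapping)),
    stringsAsFactors = FALSE))
}
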