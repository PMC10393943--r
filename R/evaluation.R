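#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same
#' observations, computed from the contingency table. 1 for identical
#' partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  if (!length(a)) stopf("label vectors are empty")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Mean silhouette score
#'
#' Mean silhouette width over a seeded subsample (Euclidean distances):
#' for each observation, `(b - a) / max(a, b)` where `a` is the mean
#' distance to its own cluster and `b` the smallest mean distance to
#' another cluster. Singleton clusters contribute 0.
#'
#' @param features numeric feature matrix.
#' @param labels cluster labels (>= 2 distinct values present).
#' @param subsample number of rows to score (default 1000; `>= n` scores
#'   everything).
#' @param seed RNG seed for the subsample.
#' @return numeric in `[-1, 1]`.
#' @export
silhouette_score <- function(features, labels, subsample = 1000, seed = 1) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) stopf("features and labels must align")
  if (length(unique(labels)) < 2) stopf("silhouette requires at least 2 clusters")
  n <- nrow(features)
  if (subsample < n) {
    idx <- with_seed(seed, sort(sample.int(n, subsample)))
    features <- features[idx, , drop = FALSE]
    labels <- labels[idx]
    if (length(unique(labels)) < 2)
      stopf("subsample collapsed to a single cluster; increase `subsample`")
  }
  d <- as.matrix(stats::dist(features))
  labs <- unique(labels)
  sil <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { sil[i] <- 0; next }
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(labs[labs != labels[i]], function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

#' Per-class and macro F1 against reference labels
#'
#' Computes precision, recall and F1 per reference class plus unweighted
#' macro and support-weighted averages. Predicted phenotypes are first
#' translated to reference classes: either through an explicit `mapping`
#' (injective, must resolve every predicted phenotype used) or, with
#' `mapping = "majority"`, by assigning each predicted phenotype to its
#' majority reference class — the standard way to score an unsupervised
#' clustering against annotations.
#'
#' @param predicted predicted phenotype labels.
#' @param reference reference (e.g. manually annotated) labels.
#' @param mapping named vector (predicted -> reference), or `"majority"`.
#' @return list with `per_class` (data frame: class, precision, recall,
#'   f1, support), `macro_f1`, `weighted_f1`, and the `mapping` used.
#' @export
phenotype_f1 <- function(predicted, reference, mapping = "majority") {
  if (length(predicted) != length(reference)) stopf("label vectors differ in length")
  predicted <- as.character(predicted)
  reference <- as.character(reference)
  if (identical(mapping, "majority")) {
    tab <- table(predicted, reference)
    mapping <- stats::setNames(colnames(tab)[max.col(tab, ties.method = "first")],
                               rownames(tab))
  } else {
    used <- unique(predicted)
    unmapped <- setdiff(used, names(mapping))
    if (length(unmapped))
      stopf("predicted phenotype(s) without a mapping: %s",
            paste(unmapped, collapse = ", "))
    if (anyDuplicated(mapping[names(mapping) %in% used]))
      stopf("phenotype mapping must be injective")
  }
  mapped <- unname(mapping[predicted])

  classes <- sort(unique(reference))
  per_class <- data.frame(class = classes, precision = NA_real_,
                          recall = NA_real_, f1 = 0, support = 0L,
                          stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(mapped == cl & reference == cl)
    fp <- sum(mapped == cl & reference != cl)
    fn <- sum(mapped != cl & reference == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per_class[i, c("precision", "recall", "f1")] <- c(prec, rec, f1)
    per_class$support[i] <- sum(reference == cl)
  }
  list(per_class = per_class,
       macro_f1 = mean(per_class$f1),
       weighted_f1 = sum(per_class$f1 * per_class$support) / sum(per_class$support),
       mapping = mapping)
}

#' Otsu threshold of a numeric vector (256-bin histogram)
#'
#' @param x numeric values with at least 2 distinct values.
#' @param n_bins histogram resolution.
#' @return the threshold maximizing between-class variance.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (rng[1] == rng[2]) stopf("cannot threshold constant values")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_total <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_total * omega - mu)^2 / denom, 0)
  # threshold between the argmax bin and the next: values above are positive
  k <- which.max(sigma_b)
  breaks[k + 1]
}

#' Otsu positivity baseline
#'
#' Classifies each pixel as positive/negative for each marker by an
#' Otsu threshold on a 256-bin histogram of that marker's nonzero values
#' (strictly greater than the threshold is positive). This is the
#' thresholding baseline whose combinatorial explosion of marker-positivity
#' patterns motivates clustering instead: [combo_counts] counts the
#' distinct observed patterns with a given number of positive markers.
#'
#' @param table a [pixel_table] (any stage) or numeric matrix with named
#'   marker columns.
#' @return logical matrix (pixels x markers).
#' @export
otsu_positivity <- function(table) {
  values <- if (inherits(table, "pixel_table")) table$values else as.matrix(table)
  out <- matrix(FALSE, nrow(values), ncol(values),
                dimnames = list(NULL, colnames(values)))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    nz <- v[v > 0]
    if (length(unique(nz)) < 2)
      stopf("marker \"%s\" has fewer than 2 distinct nonzero values",
            colnames(values)[j])
    out[, j] <- v > otsu_threshold(nz)
  }
  out
}

#' @param binary logical positivity matrix from [otsu_positivity].
#' @param n_positive pattern weight: count patterns with exactly this many
#'   positive markers.
#' @rdname otsu_positivity
#' @return `combo_counts`: integer count of distinct observed patterns.
#' @export
combo_counts <- function(binary, n_positive) {
  sel <- rowSums(binary) == n_positive
  if (!any(sel)) return(0L)
  patterns <- apply(binary[sel, , drop = FALSE], 1, paste, collapse = "")
  length(unique(patterns))
}

#' Spearman correlation between replicate composition vectors
#'
#' Quantifies reproducibility across e.g. serial tissue sections: the
#' Spearman rank correlation of cluster-composition vectors for each
#' listed pair, with a mean +/- SD summary (both rho and rho^2 reported).
#'
#' @param compositions list of numeric composition vectors (same length).
#' @param pairing list of length-2 index vectors naming the pairs.
#' @return list with `per_pair` (data frame: i, j, rho, rho_sq) and
#'   `summary` (means and SDs).
#' @export
replicate_correlation <- function(compositions, pairing) {
  rho <- vapply(pairing, function(p) {
    x <- compositions[[p[1]]]; y <- compositions[[p[2]]]
    if (length(x) != length(y)) stopf("paired composition vectors differ in length")
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
  per_pair <- data.frame(i = vapply(pairing, `[`, numeric(1), 1),
                         j = vapply(pairing, `[`, numeric(1), 2),
                         rho = rho, rho_sq = rho^2)
  list(per_pair = per_pair,
       summary = c(mean_rho = mean(rho), sd_rho = stats::sd(rho),
                   mean_rho_sq = mean(rho^2), sd_rho_sq = stats::sd(rho^2)))
}
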