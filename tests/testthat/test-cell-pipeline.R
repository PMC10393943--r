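test_that("cell composition features are exact fractions of cell size", {
  # cell 1: 10 pixels all in cluster 3
  mask <- matrix(0L, 6, 6)
  mask[1:2, 1:5] <- 1L
  coords <- data.frame(fov = "f", row = rep(0:1, 5), col = rep(0:4, each = 2))
  ids <- rep(3L, 10)
  tab <- cell_pixel_composition(coords, ids, label_map("f", mask), n_clusters = 4)
  expect_equal(tab$cells$cell_size, 10)
  expect_equal(unname(tab$features[1, ]), c(0, 0, 1, 0))

  # cell of 8 pixels: 6 assigned to cluster 2, 2 excluded from clustering
  mask2 <- matrix(0L, 4, 4)
  mask2[1:2, 1:4] <- 1L
  coords2 <- data.frame(fov = "f", row = rep(0:1, 3), col = rep(0:2, each = 2))
  tab2 <- cell_pixel_composition(coords2, rep(2L, 6), label_map("f", mask2),
                                 n_clusters = 3)
  expect_equal(tab2$cells$cell_size, 8)
  expect_equal(unname(tab2$features[1, ]), c(0, 0.75, 0))
})

test_that("cell composition equals a per-cell exhaustive tally", {
  set.seed(32)
  mask <- matrix(0L, 20, 20)
  mask[2:6, 2:6] <- 1L; mask[10:15, 3:8] <- 2L; mask[5:9, 12:18] <- 3L
  # random retained pixels across the image
  all_rc <- which(matrix(TRUE, 20, 20), arr.ind = TRUE)
  pick <- sample(nrow(all_rc), 150)
  coords <- data.frame(fov = "f", row = all_rc[pick, 1] - 1L,
                       col = all_rc[pick, 2] - 1L)
  ids <- sample(1:5, 150, replace = TRUE)
  tab <- cell_pixel_composition(coords, ids, label_map("f", mask), n_clusters = 5)
  for (cell in 1:3) {
    size <- sum(mask == cell)
    for (k in 1:5) {
      n <- sum(ids == k & mask[cbind(coords$row + 1, coords$col + 1)] == cell)
      expect_equal(tab$features[tab$cells$cell_id == cell, k], n / size,
                   ignore_attr = TRUE)
    }
  }
})

test_that("cell feature normalization divides by the column quantile", {
  cells <- data.frame(fov = "f", cell_id = 1:20, cell_size = 10)
  feats <- matrix(0.5, 20, 2, dimnames = list(NULL, c("cluster_1", "cluster_2")))
  feats[, 2] <- seq(0.1, 2, length.out = 20)
  tab <- cell_feature_table(cells, feats, "pixel_composition")
  out <- normalize_cell_features(tab)
  expect_true(all(out$features[, 1] == 1))
  expect_lt(abs(quantile(out$features[, 2], 0.999, names = FALSE) - 1), 1e-6)

  feats0 <- cbind(feats, cluster_3 = 0)
  tab0 <- cell_feature_table(cells, feats0, "pixel_composition")
  expect_warning(out0 <- normalize_cell_features(tab0), "cluster_3")
  expect_false("cluster_3" %in% colnames(out0$features))
})

test_that("integrated expression features are per-cell means of marker sums", {
  data <- array(0, dim = c(4, 4, 2))
  mask <- matrix(0L, 4, 4)
  mask[2, 2] <- 1L                 # one-pixel cell
  data[2, 2, ] <- c(2, 4)
  img <- multichannel_image("f", c("a", "b"), data)
  tab <- integrated_expression_features(img, label_map("f", mask), quantile = NA)
  expect_equal(unname(tab$features[1, ]), c(2, 4))

  # doubling intensities doubles raw features but not 99.9%-normalized ones
  img2 <- multichannel_image("f", c("a", "b"), data * 2)
  raw2 <- integrated_expression_features(img2, label_map("f", mask), quantile = NA)
  expect_equal(raw2$features, tab$features * 2)

  set.seed(33)
  big <- array(runif(10 * 10 * 2), dim = c(10, 10, 2))
  bmask <- matrix(0L, 10, 10); bmask[1:4, 1:4] <- 1L; bmask[6:9, 6:9] <- 2L
  bimg <- multichannel_image("f", c("a", "b"), big)
  n1 <- integrated_expression_features(bimg, label_map("f", bmask))
  bimg2 <- multichannel_image("f", c("a", "b"), big * 2)
  n2 <- integrated_expression_features(bimg2, label_map("f", bmask))
  expect_equal(n1$features, n2$features, tolerance = 1e-12)

  # exhaustive summation oracle
  raw <- integrated_expression_features(bimg, label_map("f", bmask), quantile = NA)
  for (cell in 1:2) {
    sel <- bmask == cell
    expect_equal(unname(raw$features[cell, ]),
                 c(sum(big[, , 1][sel]), sum(big[, , 2][sel])) / sum(sel))
  }
})

test_that("cells from disjoint composition archetypes are recovered exactly", {
  set.seed(34)
  n <- 60
  arch <- diag(3)[sample(rep(1:3, 20)), ]   # one-hot compositions
  truth <- max.col(arch)
  feats <- arch + matrix(runif(n * 3, 0, 0.05), n, 3)
  colnames(feats) <- sprintf("cluster_%d", 1:3)
  tab <- cell_feature_table(data.frame(fov = "f", cell_id = 1:n, cell_size = 9),
                            feats, "pixel_composition")
  res <- cluster_cells(tab, som = som_config(3, 3, seed = 4),
                       consensus = consensus_config(k = 3, seed = 5))
  expect_equal(adjusted_rand(res$labels$metacluster, truth), 1)

  res2 <- cluster_cells(tab, som = som_config(3, 3, seed = 4),
                        consensus = consensus_config(k = 3, seed = 5))
  expect_identical(res$labels, res2$labels)
})

test_that("constant features collapse to a single effective phenotype", {
  feats <- matrix(0.5, 40, 3, dimnames = list(NULL, sprintf("cluster_%d", 1:3)))
  tab <- cell_feature_table(data.frame(fov = "f", cell_id = 1:40, cell_size = 4),
                            feats, "pixel_composition")
  res <- cluster_cells(tab, som = som_config(2, 2, seed = 4),
                       consensus = consensus_config(k = 2, seed = 5))
  # all cells identical: at most one populated metacluster can matter;
  # every cell must carry the same label
  expect_equal(length(unique(res$labels$metacluster)), 1)
})

test_that("fewer cells than SOM nodes raises a helpful error", {
  feats <- matrix(runif(10 * 2), 10, 2, dimnames = list(NULL, c("a", "b")))
  tab <- cell_feature_table(data.frame(fov = "f", cell_id = 1:10, cell_size = 4),
                            feats, "pixel_composition")
  expect_error(cluster_cells(tab, som = som_config(10, 10, seed = 1),
                             consensus = consensus_config(k = 2)),
               "smaller grid")
})

test_that("cell phenotype maps paint each cell with its metacluster", {
  mask <- matrix(0L, 6, 6)
  mask[1:2, 1:2] <- 1L; mask[4:5, 4:5] <- 2L
  labels <- data.frame(fov = "f", cell_id = 1:2, metacluster = c(3L, 7L))
  map <- paint_cell_map(label_map("f", mask), labels)
  expect_true(all(map$data[mask == 1] == 3))
  expect_true(all(map$data[mask == 2] == 7))
  expect_true(all(map$data[mask == 0] == 0))
})

test_that("composition features ignore global intensity scaling", {
  fix <- spillover_dataset()
  ds <- fix$ds
  cfg <- pixel_run_config(ds$dir, k = 5, subsample_fraction = 0.5,
                          som = som_config(5, 5, seed = 5), seed = 3)
  res <- run_pixel_clustering(cfg)
  masks <- lapply(ds$fovs, function(f) f$mask)
  comp <- cell_pixel_composition(res$table$coords, res$metaclusters, masks)
  # features are fractions in [0, 1] summing to <= 1
  expect_true(all(comp$features >= 0 & comp$features <= 1))
  expect_true(all(rowSums(comp$features) <= 1 + 1e-9))
})
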