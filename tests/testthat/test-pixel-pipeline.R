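test_that("noise-free synthetic dataset is recovered exactly (ARI = 1)", {
  fix <- tiny_dataset(n_phen = 3,
                      noise = noise_config(poisson_scale = 0, dropout_prob = 0))
  cfg <- pixel_run_config(fix$ds$dir, k = 3, subsample_fraction = 0.5,
                          som = som_config(4, 4, seed = 2), seed = 50)
  res <- run_pixel_clustering(cfg)
  tv <- truth_vector(fix$ds, res$table$coords)
  incell <- tv > 0
  expect_equal(adjusted_rand(res$metaclusters[incell], tv[incell]), 1)
})

test_that("reruns with the identical seed are bit-identical", {
  fix <- tiny_dataset(noise = noise_config())
  cfg <- pixel_run_config(fix$ds$dir, k = 3, subsample_fraction = 0.5,
                          som = som_config(3, 3, seed = 2), seed = 51)
  r1 <- run_pixel_clustering(cfg)
  r2 <- run_pixel_clustering(cfg)
  expect_identical(r1$som$weights, r2$som$weights)
  expect_identical(r1$assignments, r2$assignments)
  expect_identical(r1$mapping, r2$mapping)
  expect_identical(r1$metaclusters, r2$metaclusters)
})

test_that("end-to-end scale invariance: a 10x brighter FOV maps identically", {
  sig <- make_signatures(3, 6, 2, seed = 42)
  sim <- simulate_fov(sig, 64, 64, 12,
                      noise = noise_config(poisson_scale = 0, dropout_prob = 0),
                      seed = 8)
  bright <- sim$image
  bright$data <- bright$data * 10
  cfg1 <- pixel_run_config(list(sim$image), markers = sig$marker_names, k = 3,
                           subsample_fraction = 1,
                           som = som_config(3, 3, seed = 2), seed = 52)
  cfg2 <- pixel_run_config(list(bright), markers = sig$marker_names, k = 3,
                           subsample_fraction = 1,
                           som = som_config(3, 3, seed = 2), seed = 52)
  r1 <- run_pixel_clustering(cfg1)
  r2 <- run_pixel_clustering(cfg2)
  expect_identical(r1$maps[[1]]$data, r2$maps[[1]]$data)
})

test_that("artifacts and manifest are written to the output directory", {
  out <- withr::local_tempdir()
  fix <- tiny_dataset(noise = noise_config())
  cfg <- pixel_run_config(fix$ds$dir, k = 3, subsample_fraction = 0.5,
                          som = som_config(3, 3, seed = 2),
                          output_dir = file.path(out, "run"), seed = 53)
  res <- run_pixel_clustering(cfg)
  expect_true(file.exists(file.path(out, "run", "models", "som.json")))
  expect_true(file.exists(file.path(out, "run", "assignments", "pixel_assignments.csv")))
  expect_true(file.exists(file.path(out, "run", "profiles", "remap.csv")))
  expect_true(file.exists(file.path(out, "run", "maps", "fov01_phenotype.tiff")))
  expect_true(file.exists(file.path(out, "run", "maps", "fov01_phenotype.png")))
  manifest <- jsonlite::read_json(file.path(out, "run", "logs", "manifest.json"))
  expect_equal(manifest$seed, 53)
  expect_true(length(manifest$input_digests) > 0)
  # saved map equals the in-memory map
  back <- load_label_map(file.path(out, "run", "maps", "fov01_phenotype.tiff"))
  expect_equal(back$data, res$maps[["fov01"]]$data * 1.0)
})

test_that("render_phenotype_map paints coordinates and validates bounds", {
  empty <- render_phenotype_map("f", data.frame(row = integer(), col = integer()),
                                integer(), c(8, 8))
  expect_true(all(empty$data == 0))

  one <- render_phenotype_map("f", data.frame(row = 5, col = 5), 4L, c(10, 10))
  expect_equal(one$data[6, 6], 4)
  expect_equal(sum(one$data), 4)

  expect_error(render_phenotype_map("f", data.frame(row = 10, col = 0), 1L,
                                    c(10, 10)), "bounds")

  fix <- tiny_dataset(noise = noise_config())
  cfg <- pixel_run_config(fix$ds$dir, k = 3, subsample_fraction = 0.5,
                          som = som_config(3, 3, seed = 2), seed = 54)
  res <- run_pixel_clustering(cfg)
  n_nonzero <- sum(vapply(res$maps, function(m) sum(m$data > 0), numeric(1)))
  expect_equal(n_nonzero, nrow(res$table$values))
})

test_that("cluster_composition counts fractions per id", {
  data <- matrix(c(rep(1L, 32), rep(2L, 32)), 8, 8)
  map <- label_map("f", data)
  comp <- cluster_composition(map)
  expect_equal(unname(comp), c(0.5, 0.5))

  mask <- data == 1
  comp1 <- cluster_composition(map, region_mask = mask)
  expect_equal(unname(comp1), 1)
  expect_equal(names(comp1), "1")

  set.seed(31)
  rnd <- matrix(sample(0:4, 100, replace = TRUE), 10, 10)
  m <- label_map("f", rnd)
  region <- matrix(sample(c(TRUE, FALSE), 100, TRUE), 10, 10)
  got <- cluster_composition(m, region_mask = region, denominator = "all")
  for (id in names(got))
    expect_equal(unname(got[id]),
                 sum(rnd[region] == as.integer(id)) / sum(region))
  # "assigned" denominator sums to 1; "all" sums to <= 1
  expect_lte(sum(got), 1)
  got2 <- cluster_composition(m, region_mask = region, denominator = "assigned")
  expect_equal(sum(got2), 1)
  expect_error(cluster_composition(m, region_mask = matrix(FALSE, 10, 10)), "empty")
})

test_that("normalization ablation flags change the pipeline result", {
  fix <- tiny_dataset(noise = noise_config(), per_fov_gain = c(1, 5))
  base <- pixel_run_config(fix$ds$dir, k = 3, subsample_fraction = 0.5,
                           som = som_config(3, 3, seed = 2), seed = 55)
  no_pix <- base; no_pix$pixel_norm <- FALSE
  r1 <- run_pixel_clustering(base)
  r2 <- run_pixel_clustering(no_pix)
  # with a 5x gain difference between FOVs, dropping pixel normalization
  # must change assignments
  expect_false(identical(r1$assignments, r2$assignments))
  no_marker <- base; no_marker$marker_norm <- FALSE
  r3 <- run_pixel_clustering(no_marker)
  expect_null(r3$norm_params)
})

test_that("region masks restrict clustering to masked pixels", {
  dir <- withr::local_tempdir()
  fix <- tiny_dataset(dir = file.path(dir, "d"), noise = noise_config())
  # mask out the left half of every FOV
  for (fid in fix$ds$fov_ids) {
    m <- matrix(0L, 64, 64); m[, 33:64] <- 1L
    write_tiff(m, file.path(fix$ds$dir, fid, "region.tiff"), type = "uint8")
  }
  cfg <- pixel_run_config(fix$ds$dir, k = 3, subsample_fraction = 0.5,
                          som = som_config(3, 3, seed = 2),
                          region_mask_file = "region.tiff", seed = 56)
  res <- run_pixel_clustering(cfg)
  expect_true(all(res$table$coords$col >= 32))
})
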