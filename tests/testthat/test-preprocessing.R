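make_image <- function(data, markers = sprintf("m%d", seq_len(dim(data)[3])),
                       fov = "f1") {
  multichannel_image(fov, markers, data)
}

test_that("smoothing leaves constant channels unchanged and sigma = 0 is identity", {
  img <- make_image(array(rep(c(3, 7), each = 100), dim = c(10, 10, 2)))
  sm <- smooth_channels(img, 2)
  expect_equal(sm$data, img$data, tolerance = 1e-12)
  expect_identical(smooth_channels(img, 0), img)
  expect_error(smooth_channels(img, -1), "nonnegative")
})

test_that("unit impulse blur matches the direct truncated-kernel oracle", {
  h <- 41; w <- 41
  data <- array(0, dim = c(h, w, 1))
  data[21, 21, 1] <- 1
  sm <- smooth_channels(make_image(data), 2)
  # oracle: direct evaluation of the normalized separable kernel
  r <- ceiling(4 * 2)
  k <- exp(-((-r):r)^2 / (2 * 2^2)); k <- k / sum(k)
  expected <- outer(k, k)
  got <- sm$data[(21 - r):(21 + r), (21 - r):(21 + r), 1]
  expect_lt(max(abs(got - expected)), 1e-6)
  expect_lt(max(abs(sm$data[, , 1][-((21 - r):(21 + r)), ])), 1e-12)
})

test_that("extract_pixels drops all-zero pixels and respects masks", {
  img0 <- make_image(array(0, dim = c(4, 4, 2)))
  expect_equal(nrow(extract_pixels(img0)$values), 0)

  data <- array(1, dim = c(2, 2, 2))
  data[2, 2, ] <- 0
  tab <- extract_pixels(make_image(data))
  expect_equal(nrow(tab$values), 3)
  # 0-based coordinate convention, top-left origin
  expect_false(any(tab$coords$row == 1 & tab$coords$col == 1))

  set.seed(6)
  data <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  data[data < 0.3] <- 0
  mask <- matrix(0, 8, 8); mask[, 1:4] <- 1
  tab <- extract_pixels(make_image(data), region_mask = mask)
  # exhaustive scan oracle
  n_expected <- 0L
  for (r in 1:8) for (cc in 1:4)
    if (sum(data[r, cc, ]) > 0) n_expected <- n_expected + 1L
  expect_equal(nrow(tab$values), n_expected)
  expect_error(extract_pixels(make_image(data), region_mask = matrix(1, 4, 4)),
               "dimensions")
})

test_that("strict positivity filter subsets pixels", {
  data <- array(0, dim = c(3, 3, 2))
  data[, , 1] <- matrix(c(0, 0.5, 1), 3, 3, byrow = TRUE)
  data[, , 2] <- 1
  tab <- extract_pixels(make_image(data, markers = c("SMA", "CK7")),
                        positivity_filter = list(marker = "SMA", threshold = 0))
  expect_equal(nrow(tab$values), 6)   # strictly > 0 excludes the 0 column
  expect_true(all(tab$values[, "SMA"] > 0))
  expect_error(extract_pixels(make_image(data), positivity_filter =
                                list(marker = "SMA", threshold = 0)), "SMA")
})

test_that("pixel normalization makes rows sum to 1", {
  tab <- pixel_table(data.frame(fov = "f", row = 0:1, col = 0L),
                     matrix(c(2, 2, 1, 0), 2, 2, byrow = TRUE,
                            dimnames = list(NULL, c("a", "b"))),
                     stage = "smoothed")
  out <- normalize_pixels(tab)
  expect_equal(out$values[1, ], c(a = 0.5, b = 0.5))
  expect_equal(out$values[2, ], c(a = 1, b = 0))
  expect_equal(out$stage, "pixel_normalized")

  set.seed(7)
  vals <- matrix(rexp(1000 * 4), 1000, 4,
                 dimnames = list(NULL, letters[1:4]))
  big <- pixel_table(data.frame(fov = "f", row = 0:999, col = 0L), vals, "raw")
  out <- normalize_pixels(big)
  expect_true(all(abs(rowSums(out$values) - 1) < 1e-9))

  zero <- pixel_table(data.frame(fov = "f", row = 0L, col = 0L),
                      matrix(0, 1, 2, dimnames = list(NULL, c("a", "b"))), "raw")
  expect_error(normalize_pixels(zero), "all-zero")
})

test_that("percentile normalization matches the sort-and-interpolate oracle", {
  vals <- matrix(1:1000 / 1000, 1000, 1, dimnames = list(NULL, "a"))
  vals <- cbind(vals, b = 1 - vals[, 1] / 2)
  vals <- vals / rowSums(vals)
  tab <- pixel_table(data.frame(fov = "f", row = 0:999, col = 0L), vals,
                     "pixel_normalized")
  params <- fit_percentile_norm(tab, quantile = 0.999)
  # linear-interpolation quantile oracle (type 7): x_(k) + f * (x_(k+1) - x_(k))
  oracle <- function(x, p) {
    x <- sort(x); hh <- (length(x) - 1) * p + 1
    lo <- floor(hh); x[lo] + (hh - lo) * (x[lo + 1] - x[lo])
  }
  expect_equal(unname(params$per_marker_divisor["a"]), oracle(vals[, "a"], 0.999))
  expect_equal(unname(params$per_marker_divisor["b"]), oracle(vals[, "b"], 0.999))

  out <- apply_percentile_norm(tab, params)
  expect_equal(out$stage, "fully_normalized")
  # post-normalization empirical quantile is 1
  for (m in c("a", "b"))
    expect_lt(abs(quantile(out$values[, m], 0.999, names = FALSE) - 1), 1e-6)
})

test_that("constant marker gives divisor equal to the constant", {
  vals <- matrix(c(0.4, 0.6), 50, 2, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b")))
  tab <- pixel_table(data.frame(fov = "f", row = 0:49, col = 0L), vals,
                     "pixel_normalized")
  params <- fit_percentile_norm(tab)
  expect_equal(unname(params$per_marker_divisor), c(0.4, 0.6))
  out <- apply_percentile_norm(tab, params)
  expect_true(all(out$values == 1))
})

test_that("zero-quantile markers raise an error naming them", {
  vals <- matrix(c(1, 0), 10, 2, byrow = TRUE,
                 dimnames = list(NULL, c("good", "dead")))
  tab <- pixel_table(data.frame(fov = "f", row = 0:9, col = 0L), vals,
                     "pixel_normalized")
  expect_error(fit_percentile_norm(tab), "dead")
})

test_that("apply_percentile_norm validates marker sets and arithmetic", {
  vals <- matrix(c(0.5, 0.5), 5, 2, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b")))
  tab <- pixel_table(data.frame(fov = "f", row = 0:4, col = 0L), vals,
                     "pixel_normalized")
  params <- structure(list(quantile = 0.999,
                           per_marker_divisor = c(a = 0.5, b = 1)),
                      class = "norm_params")
  out <- apply_percentile_norm(tab, params)
  expect_equal(unname(out$values[1, ]), c(1, 0.5))
  bad <- structure(list(quantile = 0.999, per_marker_divisor = c(x = 1, y = 1)),
                   class = "norm_params")
  expect_error(apply_percentile_norm(tab, bad), "marker set")
  identity <- structure(list(quantile = 0.999,
                             per_marker_divisor = c(a = 1, b = 1)),
                        class = "norm_params")
  expect_equal(apply_percentile_norm(tab, identity)$values, tab$values)
})

test_that("norm params survive a JSON round trip", {
  params <- structure(list(quantile = 0.999,
                           per_marker_divisor = c(a = 0.123456789, b = 2)),
                      class = "norm_params")
  p <- withr::local_tempfile(fileext = ".json")
  save_norm_params(params, p)
  back <- load_norm_params(p)
  expect_equal(back$per_marker_divisor, params$per_marker_divisor)
})

test_that("subsampling is exact, distinct and deterministic", {
  set.seed(8)
  vals <- matrix(runif(1000 * 2), 1000, 2, dimnames = list(NULL, c("a", "b")))
  tab <- pixel_table(data.frame(fov = "f", row = 0:999, col = 0L), vals, "raw")
  expect_identical(subsample_pixels(tab, 1, seed = 1), tab)
  s <- subsample_pixels(tab, 0.1, seed = 3)
  expect_equal(nrow(s$values), 100)
  expect_false(anyDuplicated(s$coords[c("row", "col")]) > 0)
  s2 <- subsample_pixels(tab, 0.1, seed = 3)
  expect_identical(s, s2)
  expect_false(identical(s, subsample_pixels(tab, 0.1, seed = 4)))
  empty <- pixel_table(data.frame(fov = character(), row = integer(),
                                  col = integer()),
                       matrix(numeric(), 0, 2,
                              dimnames = list(NULL, c("a", "b"))), "raw")
  expect_error(subsample_pixels(empty, 0.5, seed = 1), "empty")
})

test_that("scale invariance: scaling a FOV leaves pixel-normalized rows unchanged", {
  set.seed(9)
  data <- array(runif(6 * 6 * 3, 0.1, 5), dim = c(6, 6, 3))
  img <- make_image(data)
  img10 <- make_image(data * 10)
  t1 <- normalize_pixels(extract_pixels(smooth_channels(img, 1.5)))
  t2 <- normalize_pixels(extract_pixels(smooth_channels(img10, 1.5)))
  expect_equal(t1$values, t2$values, tolerance = 1e-12)
})
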