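# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# tiny well-separated dataset: k phenotypes, clean enough for exact recovery
tiny_dataset <- function(dir = tempfile("ds"), n_phen = 3, n_markers = 6,
                         n_fovs = 2, height = 64, width = 64, n_cells = 12,
                         noise = noise_config(poisson_scale = 0, dropout_prob = 0),
                         spillover_width = 0, seed = 42, per_fov_gain = rep(1, n_fovs),
                         fov_seeds = NULL, cell_brightness_sd = 0) {
  sig <- make_signatures(n_phen, n_markers, 2, seed = seed)
  list(sig = sig,
       ds = simulate_dataset(sig, n_fovs, per_fov_gain, out_dir = dir,
                             height = height, width = width, n_cells = n_cells,
                             noise = noise, spillover_width = spillover_width,
                             cell_brightness_sd = cell_brightness_sd,
                             seed = seed, fov_seeds = fov_seeds))
}

# ground-truth phenotype for each retained pixel of a run (0 = background)
truth_vector <- function(ds, coords) {
  unlist(lapply(seq_along(ds$fov_ids), function(i) {
    sel <- coords$fov == ds$fov_ids[i]
    ds$fovs[[i]]$truth$pixel_labels$data[cbind(coords$row[sel] + 1L,
                                               coords$col[sel] + 1L)]
  }))
}

# the spillover world used for the cell-phenotyping comparison: densely
# packed small cells, boundary spillover, and per-cell brightness variation
spillover_dataset <- function(dir = tempfile("spill"), seed = 21) {
  sig <- make_signatures(5, 10, 2, seed = 7)
  list(sig = sig,
       ds = simulate_dataset(sig, 2, c(1, 1), out_dir = dir,
                             height = 128, width = 128, n_cells = 150,
                             cell_radius = c(2.5, 4.5), spillover_width = 2,
                             cell_brightness_sd = log(2), seed = seed))
}

expect_same_partition <- function(a, b) {
  expect_equal(adjusted_rand(a, b), 1)
}

# independent nested-loop reference implementation of the consistency score
naive_consistency <- function(assignments, coverage = 0.95) {
  n_rep <- length(assignments)
  n_obs <- length(assignments[[1]])
  score <- matrix(NA_real_, n_rep, max(unlist(assignments)))
  for (r in seq_len(n_rep)) {
    for (cl in unique(assignments[[r]])) {
      members <- which(assignments[[r]] == cl)
      vals <- numeric(0)
      for (s in seq_len(n_rep)) {
        if (s == r) next
        counts <- c()
        for (other in sort(unique(assignments[[s]])))
          counts <- c(counts, sum(assignments[[s]][members] == other))
        counts <- sort(counts, decreasing = TRUE)
        total <- 0; k <- 0
        for (cnt in counts) {
          k <- k + 1; total <- total + cnt
          if (total >= coverage * length(members) - 1e-9) break
        }
        vals <- c(vals, k)
      }
      score[r, cl] <- mean(vals)
    }
  }
  obs <- numeric(n_obs)
  for (i in seq_len(n_obs)) {
    v <- numeric(0)
    for (r in seq_len(n_rep)) v <- c(v, score[r, assignments[[r]][i]])
    obs[i] <- mean(v)
  }
  obs
}
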