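# Small fixtures shared across the suite. Everything is generated in code.

# compact synthetic config: 3 classes, short grid, fast to simulate
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_classes = 3, samples_per_class = 8, n_points = 120,
                   seed = 1)
  do.call(spectra_config, utils::modifyList(defaults, args))
}

# isotropic Gaussian blobs with known assignment
make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[i, ], "+")
  }))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per),
       centers = centers)
}

# accuracy of a hard clustering after optimal cluster-class matching
matched_accuracy <- function(pred, truth) {
  match_clusters(pred, truth, mode = "optimal")$accuracy
}
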