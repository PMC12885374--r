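# Shared fixtures, built in code at test time.

toy_spec <- function(seed = 1L, ...) {
  args <- list(n_per_class = 10L, n_classes = 8L, n_features = 64L,
               n_informative = 5L, n_redundant = 0L, class_separation = 6,
               noise_sd = 1, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

toy_dataset <- function(seed = 1L, ...) generate_features(toy_spec(seed, ...))

# Small well-separated 4-class dataset for classifier/pipeline tests.
easy_dataset <- function(seed = 1L, n_per_class = 12L, n_features = 16L,
                         class_separation = 10, noise_sd = 0.5) {
  generate_features(synthetic_spec(
    n_per_class = n_per_class, n_classes = 4L, n_features = n_features,
    n_informative = 4L, n_redundant = 0L,
    class_separation = class_separation, noise_sd = noise_sd, seed = seed))
}

# Dense grid search over psi in [-lim, lim]^t (t <= 3): the independent
# oracle for the coordinate-descent solver. Vectorized in chunks so the
# 10^-2-step 3-D grid stays tractable.
grid_search_lasso <- function(L, f, alpha, step = 0.01, lim = 2) {
  grid <- seq(-lim, lim, by = step)
  t <- ncol(L)
  n <- nrow(L)
  best <- Inf
  eval_chunk <- function(PSI) { # t x m
    R <- matrix(f, n, ncol(PSI)) - L %*% PSI
    min(colSums(R^2) / (2 * n) + alpha * colSums(abs(PSI)))
  }
  if (t == 1) {
    best <- eval_chunk(matrix(grid, 1))
  } else if (t == 2) {
    for (a in grid)
      best <- min(best, eval_chunk(rbind(a, grid)))
  } else {
    for (a in grid) {
      PSI <- rbind(rep(a, length(grid)^2),
                   rep(grid, each = length(grid)),
                   rep(grid, times = length(grid)))
      best <- min(best, eval_chunk(PSI))
    }
  }
  best
}
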