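test_that("generated shape, labels and determinism contracts", {
  spec <- synthetic_spec(n_per_class = 10L, n_classes = 8L, n_features = 2048L,
                         n_informative = 16L, n_redundant = 8L, seed = 7L)
  ds <- generate_features(spec)
  expect_equal(dim(ds$features), c(80L, 2048L))
  expect_true(all(ds$labels %in% 0:7))
  expect_equal(as.integer(table(ds$labels)), rep(10L, 8))
  ds2 <- generate_features(spec)
  expect_identical(ds$features, ds2$features)
  expect_identical(ds$labels, ds2$labels)
  # sidecar carries ground truth, matrix does not
  expect_equal(ds$info$informative, 1:16)
  expect_equal(ds$info$redundant, 17:24)
})

test_that("invalid specs are rejected as configuration errors", {
  expect_error(synthetic_spec(10, n_features = 8, n_informative = 6,
                              n_redundant = 4), "exceeds")
  expect_error(synthetic_spec(10, redundancy_rho = 1.5), "rho")
  expect_error(synthetic_spec(10, class_separation = -1), "separation")
  expect_error(synthetic_spec(0), "n_per_class")
})

test_that("informative columns carry the planted separation, noise does not", {
  spec <- synthetic_spec(n_per_class = 15L, n_classes = 4L, n_features = 40L,
                         n_informative = 4L, n_redundant = 0L,
                         class_separation = 4, noise_sd = 1, seed = 3L)
  ds <- generate_features(spec)
  centroid_dist <- function(cols) {
    M <- do.call(rbind, lapply(sort(unique(ds$labels)), function(k)
      colMeans(ds$features[ds$labels == k, cols, drop = FALSE])))
    D <- as.matrix(dist(M))
    mean(D[upper.tri(D)])
  }
  d_info <- centroid_dist(ds$info$informative)
  d_noise <- centroid_dist(5:8) # pure-noise block of equal width
  expect_gt(d_info, d_noise)
  expect_gt(d_info, 3) # close to the planted separation 4
})

test_that("redundant columns are correlated with their informative sources", {
  spec <- synthetic_spec(n_per_class = 25L, n_classes = 4L, n_features = 20L,
                         n_informative = 4L, n_redundant = 4L,
                         redundancy_rho = 0.9, seed = 11L)
  ds <- generate_features(spec)
  for (j in seq_len(4)) {
    r <- cor(ds$features[, j], ds$features[, 4 + j])
    expect_gt(r, 0.75)
  }
})

test_that("planted-signal ratio approaches 1 as separation vanishes", {
  ratio_at <- function(sep, seed) {
    spec <- synthetic_spec(n_per_class = 10L, n_classes = 4L, n_features = 16L,
                           n_informative = 4L, n_redundant = 0L,
                           class_separation = sep, noise_sd = 1, seed = seed)
    ds <- generate_features(spec)
    cd <- function(cols) {
      M <- do.call(rbind, lapply(0:3, function(k)
        colMeans(ds$features[ds$labels == k, cols, drop = FALSE])))
      D <- as.matrix(dist(M)); mean(D[upper.tri(D)])
    }
    cd(1:4) / cd(5:8)
  }
  r0 <- mean(vapply(1:20, function(s) ratio_at(0, s), numeric(1)))
  r4 <- mean(vapply(1:20, function(s) ratio_at(4, s), numeric(1)))
  expect_lt(abs(r0 - 1), 0.25)
  expect_gt(r4, 2)
})

test_that("stratified split: counts, conservation, largest-remainder rounding", {
  ds <- toy_dataset(seed = 5L)
  parts <- train_validation_split(ds, 0.7, seed = 5L)
  expect_equal(nrow(parts$train$features), 56L)
  expect_equal(nrow(parts$validation$features), 24L)
  expect_equal(as.integer(table(parts$train$labels)), rep(7L, 8))
  # conservation: every original row appears exactly once across the parts
  all_rows <- rbind(parts$train$features, parts$validation$features)
  expect_equal(dim(all_rows), dim(ds$features))
  key <- function(M) sort(apply(M, 1, function(r) paste(signif(r, 12), collapse = ",")))
  expect_equal(key(all_rows), key(ds$features))

  # class counts {A:7, B:3} at 0.7 -> 5 train A, 2 train B
  X <- matrix(rnorm(20), 10, 2)
  lab <- c(rep(0L, 7), rep(1L, 3))
  dsu <- feature_dataset(X, lab)
  p <- train_validation_split(dsu, 0.7, seed = 1L)
  expect_equal(sum(p$train$labels == 0), 5L)
  expect_equal(sum(p$train$labels == 1), 2L)

  # 2 rows of one class at 0.5 -> 1/1
  ds2 <- feature_dataset(matrix(rnorm(8), 2, 4), c(0L, 0L))
  expect_error(train_validation_split(ds2, 0.5), NA)
  p2 <- train_validation_split(ds2, 0.5, seed = 1)
  expect_equal(nrow(p2$train$features), 1L)

  # singleton class errors, naming the class
  ds1 <- feature_dataset(matrix(rnorm(12), 3, 4), c(0L, 0L, 5L))
  expect_error(train_validation_split(ds1, 0.7), "5")
})

test_that("feature CSV + sidecar round-trip is lossless", {
  ds <- toy_dataset(seed = 9L, n_features = 12L, n_informative = 3L)
  tmp <- tempfile(fileext = ".csv")
  write_feature_csv(ds, tmp)
  back <- read_feature_csv(tmp)
  expect_equal(back$labels, ds$labels)
  expect_equal(unname(back$features), unname(ds$features), tolerance = 1e-12)
  expect_equal(back$info$informative, ds$info$informative)
  expect_equal(back$info$spec$seed, ds$info$spec$seed)
  unlink(c(tmp, sub("csv$", "json", tmp)))
})
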