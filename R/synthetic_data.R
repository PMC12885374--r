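#' Specification of a synthetic deep-feature dataset
#'
#' Describes a seeded synthetic feature matrix emulating deep CNN image
#' descriptors: a planted informative subspace whose class-conditional means
#' sit on a scaled simplex, correlated redundant copies of informative
#' columns, and pure-noise dimensions. The defaults mirror an 8-class,
#' 2048-feature regime.
#'
#' @param n_per_class samples per class.
#' @param n_classes number of classes (default 8).
#' @param n_features total feature count `t` (default 2048).
#' @param n_informative number of informative columns.
#' @param n_redundant number of correlated copies of informative columns.
#' @param class_separation Euclidean distance between class centroids in the
#'   informative subspace (non-negative).
#' @param noise_sd within-class standard deviation (non-negative).
#' @param redundancy_rho correlation between a redundant column and its
#'   informative source, in \[0, 1\].
#' @param seed integer seed; identical specs (including seed) generate
#'   bit-identical datasets.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class, n_classes = 8L, n_features = 2048L,
                           n_informative = 16L, n_redundant = 8L,
                           class_separation = 4, noise_sd = 1,
                           redundancy_rho = 0.9, seed = 1L) {
  if (!is_count(n_per_class, 1L)) stop_config("n_per_class must be a positive integer")
  if (!is_count(n_classes, 2L)) stop_config("n_classes must be an integer >= 2")
  if (!is_count(n_features, 1L)) stop_config("n_features must be a positive integer")
  if (!is_count(n_informative, 1L) || !is_count(n_redundant, 0L))
    stop_config("n_informative/n_redundant must be non-negative integers (n_informative >= 1)")
  if (n_informative + n_redundant > n_features)
    stop_config("n_informative + n_redundant (%d) exceeds n_features (%d)",
                n_informative + n_redundant, n_features)
  if (!is.numeric(class_separation) || class_separation < 0)
    stop_config("class_separation must be a non-negative scalar")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_config("noise_sd must be a non-negative scalar")
  if (!is.numeric(redundancy_rho) || redundancy_rho < 0 || redundancy_rho > 1)
    stop_config("redundancy_rho must lie in [0, 1]")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_classes = as.integer(n_classes),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 class_separation = as.numeric(class_separation),
                 noise_sd = as.numeric(noise_sd),
                 redundancy_rho = as.numeric(redundancy_rho),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Construct a feature dataset
#'
#' Container for an n x t feature matrix with integer class labels in
#' `[0, n_classes)`, the object the selection algorithms operate on.
#'
#' @param features numeric matrix, rows = samples.
#' @param labels integer class labels, `0 .. n_classes - 1`.
#' @param feature_names optional column names (defaults to `f0001`, ...).
#' @param info optional ground-truth sidecar (informative/redundant indices,
#'   generating spec); carried alongside, never inside the matrix.
#' @return An object of class `feature_dataset`.
#' @export
feature_dataset <- function(features, labels, feature_names = NULL, info = NULL) {
  features <- as.matrix(features)
  if (anyNA(features) || any(!is.finite(features)))
    stop_config("feature matrix contains missing or non-finite values")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop_config("labels length (%d) != number of rows (%d)", length(labels), nrow(features))
  if (anyNA(labels) || any(labels < 0))
    stop_config("labels must be non-negative integers")
  if (is.null(feature_names))
    feature_names <- sprintf("f%04d", seq_len(ncol(features)))
  if (length(feature_names) != ncol(features))
    stop_config("feature_names length must equal ncol(features)")
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names, info = info),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.feature_dataset <- function(x) dim(x$features)

# Class centroids on a scaled simplex embedded in the informative subspace:
# class c sits at (sep/sqrt(2)) * e_{c mod d}, giving pairwise centroid
# distance exactly `sep` whenever d >= n_classes.
simplex_centroids <- function(n_classes, n_informative, sep) {
  M <- matrix(0, n_classes, n_informative)
  for (c in seq_len(n_classes)) {
    M[c, ((c - 1L) %% n_informative) + 1L] <- sep / sqrt(2)
  }
  M
}

#' Generate a synthetic deep-feature dataset
#'
#' Draws the informative block as Gaussians around per-class simplex
#' centroids, builds rho-correlated redundant copies of (cyclically chosen)
#' informative columns, fills the remainder with pure noise, and shuffles the
#' row order. Output is a pure function of the spec (including its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return A [feature_dataset()] whose `info` sidecar holds
#'   `informative` and `redundant` column indices and the generating spec.
#' @export
generate_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_per_class * spec$n_classes
  t <- spec$n_features
  ni <- spec$n_informative
  nr <- spec$n_redundant
  with_seed(spec$seed, {
    labels <- rep(seq_len(spec$n_classes) - 1L, each = spec$n_per_class)
    centroids <- simplex_centroids(spec$n_classes, ni, spec$class_separation)
    X <- matrix(rnorm(n * t, sd = spec$noise_sd), n, t)
    X[, seq_len(ni)] <- X[, seq_len(ni)] + centroids[labels + 1L, , drop = FALSE]
    if (nr > 0L) {
      src <- ((seq_len(nr) - 1L) %% ni) + 1L
      rho <- spec$redundancy_rho
      eps <- matrix(rnorm(n * nr, sd = spec$noise_sd), n, nr)
      Z <- X[, src, drop = FALSE]
      mu <- colMeans(Z)
      X[, ni + seq_len(nr)] <- rho * sweep(Z, 2, mu) +
        sqrt(1 - rho^2) * eps + rep(mu, each = n)
    }
    ord <- sample.int(n)
    feature_dataset(X[ord, , drop = FALSE], labels[ord],
                    info = list(informative = seq_len(ni),
                                redundant = if (nr > 0L) ni + seq_len(nr) else integer(0),
                                spec = spec))
  })
}

#' Stratified train/validation split
#'
#' Partitions a dataset by class with per-class train counts given by
#' `train_fraction * class size`, rounded by the largest-remainder rule so
#' that the train total equals `round(train_fraction * n)`.
#'
#' @param ds a [feature_dataset()].
#' @param train_fraction fraction in (0, 1); the 70/30 protocol uses 0.7.
#' @param seed integer seed controlling which rows land in which part.
#' @return A list with elements `train` and `validation`, both
#'   `feature_dataset` objects; together they tile the input exactly.
#' @export
train_validation_split <- function(ds, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(ds, "feature_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must lie strictly between 0 and 1")
  tab <- table(ds$labels)
  if (any(tab < 2L)) {
    bad <- names(tab)[tab < 2L]
    stop_config("class %s has fewer than 2 members; cannot split",
                paste(bad, collapse = ", "))
  }
  classes <- as.integer(names(tab))
  sizes <- as.integer(tab)
  quota <- train_fraction * sizes
  base <- floor(quota)
  target <- round(train_fraction * sum(sizes))
  deficit <- target - sum(base)
  counts <- base
  if (deficit > 0) {
    # largest fractional remainder first; ties broken by ascending class label
    ord <- order(-(quota - base), classes)
    counts[ord[seq_len(deficit)]] <- counts[ord[seq_len(deficit)]] + 1L
  } else if (deficit < 0) {
    ord <- order(quota - base, classes)
    counts[ord[seq_len(-deficit)]] <- counts[ord[seq_len(-deficit)]] - 1L
  }
  with_seed(seed, {
    train_idx <- integer(0)
    for (k in seq_along(classes)) {
      rows <- which(ds$labels == classes[k])
      train_idx <- c(train_idx, sample(rows, counts[k]))
    }
    train_idx <- sort(train_idx)
    val_idx <- setdiff(seq_along(ds$labels), train_idx)
    list(train = feature_dataset(ds$features[train_idx, , drop = FALSE],
                                 ds$labels[train_idx], ds$feature_names, ds$info),
         validation = feature_dataset(ds$features[val_idx, , drop = FALSE],
                                      ds$labels[val_idx], ds$feature_names, ds$info))
  })
}
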