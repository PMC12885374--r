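#' Pairwise Euclidean distance matrix
#'
#' @param X numeric n x t matrix, rows = samples.
#' @return Symmetric n x n matrix with zero diagonal,
#'   `D[a, b] = ||x_a - x_b||_2`.
#' @export
pairwise_distances <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop_config("missing values in feature matrix")
  D <- as.matrix(dist(X, method = "euclidean"))
  dimnames(D) <- NULL
  D
}

#' Intra-class dissimilarity
#'
#' Mean Euclidean distance over unordered pairs of samples of one class,
#' self-pairs excluded. A singleton class has no pairs: the value is
#' undefined (`NA`) with a warning, never 0.
#'
#' @param D distance matrix from [pairwise_distances()].
#' @param labels class label per row of `D`.
#' @param c the class.
#' @return Mean same-class pairwise distance (or `NA` for a singleton).
#' @export
intra_class <- function(D, labels, c) {
  idx <- which(labels == c)
  if (length(idx) == 0L) stop_config("class %s absent from labels", format(c))
  if (length(idx) == 1L) {
    warning(sprintf("class %s has a single member; intra-class dissimilarity undefined", format(c)))
    return(NA_real_)
  }
  sub <- D[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Inter-class dissimilarity
#'
#' Mean Euclidean distance over all pairs (a in class `c`, b outside it).
#'
#' @inheritParams intra_class
#' @return Mean class-to-rest distance.
#' @export
inter_class <- function(D, labels, c) {
  idx <- which(labels == c)
  if (length(idx) == 0L) stop_config("class %s absent from labels", format(c))
  rest <- which(labels != c)
  if (length(rest) == 0L) stop_config("only one class present; inter-class dissimilarity undefined")
  mean(D[idx, rest, drop = FALSE])
}

#' Class compactness/separation report
#'
#' One row per class: intra-class dissimilarity, inter-class dissimilarity,
#' and their difference, the class margin. A large positive margin marks a
#' compact, well-separated class. Optionally joins a per-class accuracy
#' column. When `mask` is given the distances are computed on the selected
#' feature subspace only.
#'
#' @param ds a [feature_dataset()] (or numeric matrix with `labels`).
#' @param labels labels when `ds` is a plain matrix.
#' @param per_class_accuracy optional named (by class) or class-ordered
#'   numeric vector to join as an `accuracy` column.
#' @param mask optional logical feature mask restricting the space.
#' @return data.frame with columns `class`, `intra`, `inter`, `margin`
#'   (and `accuracy` if supplied), ordered by class label; S3 class
#'   `dissimilarity_report`.
#' @export
dissimilarity_report <- function(ds, labels = NULL, per_class_accuracy = NULL,
                                 mask = NULL) {
  if (inherits(ds, "feature_dataset")) {
    X <- ds$features; labels <- ds$labels
  } else X <- as.matrix(ds)
  if (!is.null(mask)) {
    if (length(mask) != ncol(X)) stop_config("mask length != number of features")
    X <- X[, mask, drop = FALSE]
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_config("need at least 2 classes")
  D <- pairwise_distances(X)
  intra <- vapply(classes, function(c) intra_class(D, labels, c), numeric(1))
  inter <- vapply(classes, function(c) inter_class(D, labels, c), numeric(1))
  rep <- data.frame(class = classes, intra = intra, inter = inter,
                    margin = inter - intra)
  if (!is.null(per_class_accuracy)) {
    acc <- per_class_accuracy
    if (!is.null(names(acc))) acc <- acc[as.character(classes)]
    if (length(acc) != length(classes))
      stop_config("per_class_accuracy must have one value per class")
    rep$accuracy <- as.numeric(acc)
  }
  class(rep) <- c("dissimilarity_report", "data.frame")
  rep
}
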