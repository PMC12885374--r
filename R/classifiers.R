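# Compact in-package classifier bank: a CART-style Gini decision tree and
# tanh/softmax multilayer perceptrons trained by full-batch gradient descent
# with momentum. These mirror the reference study's classifier lineup
# (tree + narrow/medium/wide/bi-layer/tri-layer networks) in spirit; no
# external ML package in the runtime environment provides them.

#' The study's classifier bank
#'
#' Six classifiers: a decision tree and five multilayer perceptrons with
#' hidden layouts (10), (20), (50), (10, 10) and (10, 10, 10) neurons.
#'
#' @return Named list of classifier specs (`name`, `type`, `hidden_layout`).
#' @export
classifier_bank <- function() {
  list(
    tree        = list(name = "tree",        type = "tree", hidden_layout = NULL),
    narrow_nn   = list(name = "narrow_nn",   type = "mlp", hidden_layout = c(10L)),
    medium_nn   = list(name = "medium_nn",   type = "mlp", hidden_layout = c(20L)),
    wide_nn     = list(name = "wide_nn",     type = "mlp", hidden_layout = c(50L)),
    bilayer_nn  = list(name = "bilayer_nn",  type = "mlp", hidden_layout = c(10L, 10L)),
    trilayer_nn = list(name = "trilayer_nn", type = "mlp", hidden_layout = c(10L, 10L, 10L))
  )
}

## ---- decision tree (greedy Gini, binary axis-aligned splits) ----

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

best_split <- function(X, y, classes, min_leaf) {
  n <- nrow(X)
  K <- length(classes)
  yi <- match(y, classes)
  parent_counts <- tabulate(yi, K)
  parent_g <- gini_impurity(parent_counts)
  i_seq <- seq_len(n - 1L)
  best <- NULL
  onehot <- matrix(0L, n, K)
  onehot[cbind(seq_len(n), yi)] <- 1L
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    ord <- order(xj)
    xs <- xj[ord]
    # cumulative class counts: row i = left-branch counts after split at i
    CL <- apply(onehot[ord, , drop = FALSE], 2, cumsum)
    CLl <- CL[i_seq, , drop = FALSE]
    CRr <- rep(parent_counts, each = n - 1L) - CLl
    giniL <- 1 - rowSums(CLl^2) / i_seq^2
    giniR <- 1 - rowSums(CRr^2) / (n - i_seq)^2
    score <- (i_seq * giniL + (n - i_seq) * giniR) / n
    valid <- xs[i_seq] != xs[i_seq + 1L] & i_seq >= min_leaf & (n - i_seq) >= min_leaf
    if (!any(valid)) next
    score[!valid] <- Inf
    i <- which.min(score)
    if (is.null(best) || score[i] < best$gini - 1e-12) {
      best <- list(feature = j, threshold = (xs[i] + xs[i + 1L]) / 2,
                   gini = score[i], gain = parent_g - score[i])
    }
  }
  best
}

grow_tree <- function(X, y, classes, depth, max_depth, min_split, min_leaf) {
  counts <- tabulate(match(y, classes), length(classes))
  pred <- classes[which.max(counts)]
  if (depth >= max_depth || nrow(X) < min_split || length(unique(y)) == 1L)
    return(list(leaf = TRUE, prediction = pred))
  sp <- best_split(X, y, classes, min_leaf)
  if (is.null(sp) || sp$gain <= 1e-12)
    return(list(leaf = TRUE, prediction = pred))
  go_left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       prediction = pred,
       left = grow_tree(X[go_left, , drop = FALSE], y[go_left], classes,
                        depth + 1L, max_depth, min_split, min_leaf),
       right = grow_tree(X[!go_left, , drop = FALSE], y[!go_left], classes,
                         depth + 1L, max_depth, min_split, min_leaf))
}

#' Fit a CART-style decision tree
#'
#' Greedy recursive partitioning on Gini impurity with axis-aligned binary
#' splits; deterministic given its inputs.
#'
#' @param X numeric feature matrix.
#' @param y class labels.
#' @param max_depth,min_split,min_leaf growth controls.
#' @return An object of class `cart_tree` with a [predict()] method.
#' @export
fit_tree <- function(X, y, max_depth = 10L, min_split = 4L, min_leaf = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  structure(list(root = grow_tree(X, y, classes, 0L, max_depth, min_split, min_leaf),
                 classes = classes),
            class = "cart_tree")
}

#' @export
predict.cart_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  descend <- function(node, x) {
    while (!node$leaf)
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    node$prediction
  }
  out <- vapply(seq_len(nrow(X)), function(i) descend(object$root, X[i, ]),
                object$classes[1])
  out
}

## ---- multilayer perceptron (tanh hidden, softmax output) ----

#' Fit a multilayer perceptron
#'
#' Tanh hidden layers, softmax output, cross-entropy loss, full-batch
#' gradient descent with momentum; inputs are z-scored internally. A small,
#' deterministic stand-in for the reference study's MATLAB feedforward
#' networks.
#'
#' @param X numeric feature matrix.
#' @param y class labels.
#' @param hidden integer vector of hidden-layer sizes.
#' @param epochs gradient steps (full batch).
#' @param learning_rate,momentum optimizer settings.
#' @param l2 small ridge penalty on weights for stability.
#' @param seed seed for weight initialization.
#' @return An object of class `mlp_net` with a [predict()] method.
#' @export
fit_mlp <- function(X, y, hidden = c(10L), epochs = 200L,
                    learning_rate = 0.05, momentum = 0.9, l2 = 1e-4,
                    seed = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  K <- length(classes)
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), match(y, classes))] <- 1
  sizes <- c(ncol(X), hidden, K)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(1 / sizes[l])),
             sizes[l], sizes[l + 1]))
    B <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    vW <- lapply(W, function(w) w * 0); vB <- lapply(B, function(b) b * 0)
    for (ep in seq_len(epochs)) {
      # forward
      A <- vector("list", L + 1L); A[[1]] <- Xs
      for (l in seq_len(L)) {
        Z <- sweep(A[[l]] %*% W[[l]], 2, B[[l]], "+")
        A[[l + 1]] <- if (l < L) tanh(Z) else {
          E <- exp(Z - apply(Z, 1, max)); E / rowSums(E)
        }
      }
      # backward
      delta <- (A[[L + 1]] - Y) / n
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + l2 * W[[l]]
        gB <- colSums(delta)
        if (l > 1L) delta <- (delta %*% t(W[[l]])) * (1 - A[[l]]^2)
        vW[[l]] <- momentum * vW[[l]] - learning_rate * gW
        vB[[l]] <- momentum * vB[[l]] - learning_rate * gB
        W[[l]] <- W[[l]] + vW[[l]]
        B[[l]] <- B[[l]] + vB[[l]]
      }
    }
    structure(list(W = W, B = B, center = mu, scale = sdv, classes = classes),
              class = "mlp_net")
  })
}

#' @export
predict.mlp_net <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  A <- Xs
  L <- length(object$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% object$W[[l]], 2, object$B[[l]], "+")
    A <- if (l < L) tanh(Z) else Z
  }
  object$classes[max.col(A, ties.method = "first")]
}

fit_classifier <- function(spec, X, y, seed = 1L) {
  if (spec$type == "tree") fit_tree(X, y)
  else fit_mlp(X, y, hidden = spec$hidden_layout, seed = seed)
}
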