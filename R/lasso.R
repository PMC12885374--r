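#' Define an L1-penalized least-squares problem
#'
#' Holds the feature matrix `L`, response `f` and penalty strength `alpha`
#' of the objective
#' \deqn{J(\psi) = \frac{1}{2N}\lVert f - L\psi\rVert_2^2 +
#'   \alpha\lVert\psi\rVert_1,}
#' together with an internally standardized working copy: columns z-scored
#' with the population (1/N) standard deviation and the response centered.
#' Coefficients from [fit_lasso()] live on this standardized scale, which is
#' what makes a single default `alpha` meaningful across datasets.
#' Exact-zero-variance columns are frozen at coefficient 0.
#'
#' @param L numeric feature matrix, rows = samples.
#' @param f numeric response of length `nrow(L)`.
#' @param alpha non-negative penalty strength (field default 0.0030).
#' @return An object of class `lasso_problem`.
#' @export
lasso_problem <- function(L, f, alpha = 0.0030) {
  L <- as.matrix(L)
  f <- as.numeric(f)
  if (length(f) != nrow(L))
    stop_config("response length (%d) != number of rows (%d)", length(f), nrow(L))
  if (anyNA(L) || anyNA(f)) stop_config("missing values in L or f")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop_config("alpha must be a non-negative scalar")
  N <- nrow(L)
  mu <- colMeans(L)
  sdv <- sqrt(colMeans(sweep(L, 2, mu)^2))
  active <- sdv > 0
  sc <- ifelse(active, sdv, 1)
  Ls <- sweep(sweep(L, 2, mu), 2, sc, "/")
  structure(list(L = L, f = f, alpha = alpha, N = N,
                 Ls = Ls, fs = f - mean(f),
                 center = mu, scale = sc, active = active),
            class = "lasso_problem")
}

#' Evaluate the penalized objective
#'
#' Computes `1/(2N) * ||f - L psi||^2 + alpha * ||psi||_1`. By default the
#' raw `L` and `f` stored in the problem are used; `standardized = TRUE`
#' evaluates on the internal standardized copy, the scale on which
#' [fit_lasso()] coefficients and objectives are reported.
#'
#' @param problem a [lasso_problem()].
#' @param psi coefficient vector of length `ncol(L)`.
#' @param standardized evaluate on the standardized working copy?
#' @return Non-negative scalar objective value.
#' @export
lasso_objective <- function(problem, psi, standardized = FALSE) {
  stopifnot(inherits(problem, "lasso_problem"))
  psi <- as.numeric(psi)
  if (length(psi) != ncol(problem$L))
    stop_config("psi length (%d) != number of features (%d)",
                length(psi), ncol(problem$L))
  X <- if (standardized) problem$Ls else problem$L
  y <- if (standardized) problem$fs else problem$f
  r <- y - as.vector(X %*% psi)
  sum(r^2) / (2 * problem$N) + problem$alpha * sum(abs(psi))
}

#' Fit by cyclic coordinate descent with soft-thresholding
#'
#' Minimizes the penalized objective on the standardized problem. Each sweep
#' updates every coordinate by the closed-form soft-threshold rule; the
#' objective is non-increasing across sweeps and iteration stops when the
#' largest coefficient change falls below `tol` or after `max_sweeps`.
#'
#' @param problem a [lasso_problem()].
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_sweeps maximum number of full coordinate sweeps.
#' @return An object of class `lasso_fit` with fields `psi` (standardized
#'   scale), `objective` (equal to
#'   `lasso_objective(problem, psi, standardized = TRUE)`), `n_nonzero`,
#'   `sweeps_used` and `converged`.
#' @export
fit_lasso <- function(problem, tol = 1e-6, max_sweeps = 1000L) {
  stopifnot(inherits(problem, "lasso_problem"))
  if (!is.numeric(tol) || tol <= 0) stop_config("tol must be > 0")
  if (any(!problem$active) && problem$alpha == 0)
    warning("constant column(s) with alpha = 0: coefficient forced to 0 (degenerate variance)")
  res <- .cd_lasso_cpp(problem$Ls, problem$fs, problem$alpha,
                       tol, as.integer(max_sweeps), problem$active,
                       numeric(ncol(problem$Ls)))
  structure(list(psi = as.numeric(res$psi),
                 objective = res$objective,
                 n_nonzero = sum(res$psi != 0),
                 sweeps_used = res$sweeps_used,
                 converged = res$converged,
                 alpha = problem$alpha),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> %d nonzero of %d, objective %.6g, %d sweeps%s\n",
              x$n_nonzero, length(x$psi), x$objective, x$sweeps_used,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Nonzero-coefficient feature mask
#'
#' Features whose coefficient is exactly zero are excluded; the rest are
#' selected for classification.
#'
#' @param fit a `lasso_fit` (or multiclass `lasso_multifit`).
#' @return Logical mask of length `t`; for a multiclass fit, `TRUE` where
#'   the coefficient is nonzero in any per-class fit.
#' @export
select_nonzero <- function(fit) {
  if (inherits(fit, "lasso_multifit")) return(apply(fit$psi != 0, 1, any))
  stopifnot(inherits(fit, "lasso_fit"))
  fit$psi != 0
}

#' Smallest fully-sparsifying penalty
#'
#' For a standardized design and centered response, every `alpha >=
#' max_j |(1/N) L_j' f|` drives all coefficients exactly to zero.
#'
#' @param problem a [lasso_problem()].
#' @return The zero-shrinkage threshold `alpha_max`.
#' @export
lasso_alpha_max <- function(problem) {
  stopifnot(inherits(problem, "lasso_problem"))
  max(abs(crossprod(problem$Ls, problem$fs)) / problem$N)
}

#' Multiclass LASSO by one-hot encoding
#'
#' Fits one penalized regression per class against its one-hot indicator
#' (centered), sharing the standardized design. The aggregate objective is
#' the mean per-class objective and a feature counts as selected when its
#' coefficient is nonzero in any class fit.
#'
#' @param ds a [feature_dataset()] (or a numeric matrix plus `labels`).
#' @param labels integer labels when `ds` is a plain matrix.
#' @param alpha penalty strength.
#' @param tol,max_sweeps convergence controls as in [fit_lasso()].
#' @return An object of class `lasso_multifit`: `psi` (t x K matrix),
#'   `objective` (mean), `per_class_objective`, `n_nonzero` (union count).
#' @export
fit_lasso_multiclass <- function(ds, labels = NULL, alpha = 0.0030,
                                 tol = 1e-6, max_sweeps = 1000L) {
  if (inherits(ds, "feature_dataset")) {
    X <- ds$features; labels <- ds$labels
  } else X <- as.matrix(ds)
  classes <- sort(unique(labels))
  prob <- lasso_problem(X, rep(0, nrow(X)), alpha) # standardization only
  Y <- vapply(classes, function(k) {
    y <- as.numeric(labels == k)
    y - mean(y)
  }, numeric(nrow(X)))
  psi <- matrix(0, ncol(X), length(classes))
  objs <- numeric(length(classes))
  sweeps <- integer(length(classes))
  conv <- logical(length(classes))
  for (k in seq_along(classes)) {
    res <- .cd_lasso_cpp(prob$Ls, Y[, k], alpha, tol, as.integer(max_sweeps),
                         prob$active, numeric(ncol(X)))
    psi[, k] <- res$psi
    objs[k] <- res$objective
    sweeps[k] <- res$sweeps_used
    conv[k] <- res$converged
  }
  structure(list(psi = psi, classes = classes,
                 objective = mean(objs), per_class_objective = objs,
                 n_nonzero = sum(apply(psi != 0, 1, any)),
                 sweeps_used = max(sweeps), converged = all(conv),
                 alpha = alpha),
            class = "lasso_multifit")
}

#' Export coefficients as a data frame
#'
#' @param fit a `lasso_fit`.
#' @param feature_names optional names for the coefficient rows.
#' @return data.frame with columns `feature_name`, `psi`, `selected`.
#' @export
lasso_coef_table <- function(fit, feature_names = NULL) {
  stopifnot(inherits(fit, "lasso_fit"))
  if (is.null(feature_names)) feature_names <- sprintf("f%04d", seq_along(fit$psi))
  data.frame(feature_name = feature_names, psi = fit$psi,
             selected = fit$psi != 0, stringsAsFactors = FALSE)
}
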