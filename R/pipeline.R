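#' Experiment configuration
#'
#' @param n_folds stratified cross-validation folds (default 10).
#' @param train_fraction holdout fraction for split-based stages (default 0.7).
#' @param foa a [foa_config()] for the selection stage.
#' @param classifiers names from [classifier_bank()] to evaluate.
#' @param seed master seed for fold assignment and classifier init.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_folds = 10L, train_fraction = 0.7,
                              foa = foa_config(),
                              classifiers = names(classifier_bank()),
                              seed = 1L) {
  if (!is_count(n_folds, 2L)) stop_config("n_folds must be an integer >= 2")
  bank <- classifier_bank()
  if (!all(classifiers %in% names(bank)))
    stop_config("unknown classifier(s): %s",
                paste(setdiff(classifiers, names(bank)), collapse = ", "))
  structure(list(n_folds = as.integer(n_folds),
                 train_fraction = train_fraction, foa = foa,
                 classifiers = classifiers, seed = as.integer(seed)),
            class = "experiment_config")
}

# Deterministic stratified fold assignment: within each class, shuffled rows
# are dealt round-robin across folds.
stratified_folds <- function(labels, n_folds, seed) {
  tab <- table(labels)
  if (n_folds > min(tab))
    stop_config("n_folds (%d) exceeds the smallest class size (%d)",
                n_folds, min(tab))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (k in as.integer(names(tab))) {
      rows <- sample(which(labels == k))
      fold[rows] <- rep_len(seq_len(n_folds), length(rows))
    }
  })
  fold
}

#' Cross-validated evaluation of the classifier bank
#'
#' Runs stratified k-fold cross-validation on the (optionally masked)
#' feature matrix for every configured classifier, pooling out-of-fold
#' predictions into one macro-averaged metrics report per classifier, plus
#' the wall-clock training time. Fold assignment is a pure function of the
#' config seed.
#'
#' @param ds a [feature_dataset()].
#' @param mask optional logical feature mask (length t).
#' @param cfg an [experiment_config()].
#' @return Named list per classifier: `metrics` (a `metrics_report`),
#'   `time_sec`, `predictions`, `fold`.
#' @export
evaluate_classifiers <- function(ds, mask = NULL, cfg = experiment_config()) {
  stopifnot(inherits(ds, "feature_dataset"))
  X <- ds$features
  if (!is.null(mask)) {
    if (length(mask) != ncol(X)) stop_config("mask length != number of features")
    if (!any(mask)) stop_config("mask selects no features")
    X <- X[, mask, drop = FALSE]
  }
  y <- ds$labels
  fold <- stratified_folds(y, cfg$n_folds, cfg$seed)
  bank <- classifier_bank()[cfg$classifiers]
  out <- list()
  for (nm in names(bank)) {
    pred <- y
    t0 <- proc.time()[["elapsed"]]
    for (f in seq_len(cfg$n_folds)) {
      tr <- fold != f
      model <- fit_classifier(bank[[nm]], X[tr, , drop = FALSE], y[tr],
                              seed = cfg$seed + f)
      pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
    }
    elapsed <- proc.time()[["elapsed"]] - t0
    out[[nm]] <- list(metrics = macro_metrics(y, pred, sort(unique(y))),
                      time_sec = elapsed, predictions = pred, fold = fold)
  }
  out
}

percent_improvement <- function(before, after) {
  flds <- c("accuracy", "error", "recall", "specificity", "precision")
  do.call(rbind, lapply(names(before), function(nm) {
    b <- before[[nm]]$metrics; a <- after[[nm]]$metrics
    vals <- vapply(flds, function(f) {
      if (is.na(b[[f]]) || b[[f]] == 0) NA_real_
      else (a[[f]] - b[[f]]) / b[[f]] * 100
    }, numeric(1))
    cbind(data.frame(Classifier = nm), as.data.frame(as.list(vals)))
  }))
}

pipeline_log <- function(log, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  c(log, line)
}

#' Run the full before/after-selection experiment
#'
#' Evaluates the classifier bank on the full feature space, runs the flea
#' optimization selection, re-evaluates on the selected subspace, and emits
#' the paired metric tables, a percent-improvement table, the selected
#' count, and the class-dissimilarity report on the selected features (with
#' the first classifier's per-class recall joined as accuracy).
#'
#' @param cfg an [experiment_config()].
#' @param data a [feature_dataset()] or a path to a feature CSV.
#' @param out_dir optional directory to write CSV/JSON reports into.
#' @return List of class `pipeline_result` with elements `before`, `after`
#'   (metric tables), `improvement`, `n_selected`, `selection`,
#'   `dissimilarity`, `log`.
#' @export
run_pipeline <- function(cfg, data, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  ds <- if (is.character(data)) read_feature_csv(data) else data
  stopifnot(inherits(ds, "feature_dataset"))
  log <- character(0)
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  log <- pipeline_log(log, "load", sprintf("dataset %d x %d", nrow(ds$features), ncol(ds$features)))

  t1 <- tic()
  before <- evaluate_classifiers(ds, mask = NULL, cfg)
  log <- pipeline_log(log, "evaluate-before",
                      sprintf("in %d x %d -> %d reports, %.2fs",
                              nrow(ds$features), ncol(ds$features),
                              length(before), tic() - t1))

  t1 <- tic()
  sel <- run_foa(ds, cfg$foa)
  log <- pipeline_log(log, "select",
                      sprintf("in %d features -> out %d selected, %.2fs",
                              ncol(ds$features), sel$n_selected, tic() - t1))

  t1 <- tic()
  after <- evaluate_classifiers(ds, mask = sel$mask, cfg)
  log <- pipeline_log(log, "evaluate-after",
                      sprintf("in %d x %d -> %d reports, %.2fs",
                              nrow(ds$features), sel$n_selected,
                              length(after), tic() - t1))

  first <- after[[1]]$metrics$per_class
  acc <- setNames(first$recall, first$class)
  dis <- dissimilarity_report(ds, per_class_accuracy = acc, mask = sel$mask)
  log <- pipeline_log(log, "dissimilarity",
                      sprintf("%d classes on %d selected features, total %.2fs",
                              nrow(dis), sel$n_selected, tic() - t0))

  res <- structure(list(
    before = metrics_table(lapply(before, `[[`, "metrics"),
                           vapply(before, `[[`, numeric(1), "time_sec")),
    after = metrics_table(lapply(after, `[[`, "metrics"),
                          vapply(after, `[[`, numeric(1), "time_sec")),
    improvement = percent_improvement(before, after),
    n_selected = sel$n_selected, selection = sel,
    dissimilarity = dis, log = log), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res$before, file.path(out_dir, "metrics_before.csv"), row.names = FALSE)
    write.csv(res$after, file.path(out_dir, "metrics_after.csv"), row.names = FALSE)
    write.csv(res$improvement, file.path(out_dir, "improvement.csv"), row.names = FALSE)
    write.csv(as.data.frame(res$dissimilarity), file.path(out_dir, "dissimilarity.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(n_selected = sel$n_selected,
                              mask = sel$mask, ranking = sel$ranking,
                              importance = sel$importance,
                              fitness_trace = sel$fitness_trace),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(res$log, file.path(out_dir, "pipeline.log"))
  }
  res
}

# Mean squared error of a least-squares one-hot regressor on a held-out
# split: the small fixed downstream model the ablation arms share.
downstream_mse <- function(ds, mask, train_fraction, seed) {
  if (!any(mask)) return(NA_real_)
  parts <- train_validation_split(ds, train_fraction, seed)
  Xtr <- cbind(1, parts$train$features[, mask, drop = FALSE])
  Xva <- cbind(1, parts$validation$features[, mask, drop = FALSE])
  classes <- sort(unique(ds$labels))
  Ytr <- outer(parts$train$labels, classes, "==") * 1
  Yva <- outer(parts$validation$labels, classes, "==") * 1
  # ridge-stabilized normal equations
  A <- crossprod(Xtr) + diag(1e-6, ncol(Xtr))
  W <- solve(A, crossprod(Xtr, Ytr))
  mean((Yva - Xva %*% W)^2)
}

#' Three-arm ablation: penalized shrinkage vs flea search vs hybrid
#'
#' Arm 1 selects by the penalized fit alone (nonzero-coefficient union);
#' arm 2 thresholds the flea-search importance without the final shrinkage
#' step; arm 3 is the full hybrid. Every arm reports its selected count,
#' the held-out mean squared error of a shared least-squares one-hot
#' regressor, a convergence-iteration count and a final-gradient analogue,
#' on the same seed.
#'
#' @param ds a [feature_dataset()].
#' @param cfg an [experiment_config()].
#' @return data.frame of class `ablation_report` with columns `Model`,
#'   `Epochs`, `Time`, `MSE`, `Gradient`, `Selected`.
#' @export
run_ablation <- function(ds, cfg = experiment_config()) {
  stopifnot(inherits(ds, "feature_dataset"))
  tic <- function() proc.time()[["elapsed"]]
  alpha <- cfg$foa$alpha

  t0 <- tic()
  lfit <- fit_lasso_multiclass(ds, alpha = alpha)
  mask1 <- select_nonzero(lfit)
  t_lasso <- tic() - t0

  t0 <- tic()
  sel <- run_foa(ds, cfg$foa)
  mask2 <- sel$importance >= cfg$foa$binarize_threshold
  mask3 <- sel$mask
  t_foa <- tic() - t0

  trace <- sel$fitness_trace
  conv_iter <- if (length(trace)) which(trace >= max(trace) - 1e-12)[1] else NA_integer_
  grad_foa <- if (length(trace) >= 2) abs(diff(utils::tail(trace, 2))) else NA_real_

  rows <- data.frame(
    Model = c("lasso_only", "foa_only", "foa_lasso"),
    Epochs = c(lfit$sweeps_used, conv_iter, conv_iter),
    Time = c(t_lasso, t_foa, t_foa),
    MSE = c(downstream_mse(ds, mask1, cfg$train_fraction, cfg$seed),
            downstream_mse(ds, mask2, cfg$train_fraction, cfg$seed),
            downstream_mse(ds, mask3, cfg$train_fraction, cfg$seed)),
    Gradient = c(NA_real_, grad_foa, grad_foa),
    Selected = c(sum(mask1), sum(mask2), sum(mask3)))
  class(rows) <- c("ablation_report", "data.frame")
  rows
}
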