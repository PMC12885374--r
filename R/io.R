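#' Write / read a feature dataset as CSV with a JSON sidecar
#'
#' The CSV holds one row per sample with a header of feature names and a
#' final `label` column. The sidecar (same path with extension `.json`)
#' carries the generating spec, seed and ground-truth informative/redundant
#' indices when present, keeping ground truth out of the feature matrix.
#'
#' @param ds a [feature_dataset()].
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
write_feature_csv <- function(ds, path) {
  stopifnot(inherits(ds, "feature_dataset"))
  df <- as.data.frame(ds$features)
  names(df) <- ds$feature_names
  df$label <- ds$labels
  write.csv(df, path, row.names = FALSE)
  if (!is.null(ds$info)) {
    side <- ds$info
    if (!is.null(side$spec)) side$spec <- unclass(side$spec)
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop_config("no 'label' column in %s", path)
  labels <- as.integer(df$label)
  X <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  info <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    info <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(info$spec)) info$spec <- do.call(synthetic_spec, info$spec)
  }
  feature_dataset(X, labels, colnames(X), info = info)
}

#' Write a metrics table in the standard column order
#'
#' Rows are classifiers; columns follow the reporting order Accuracy, Error,
#' Recall, Specificity, Precision, False Positive Rate, F1_Score, MCC,
#' Kappa, Training Time(Sec).
#'
#' @param reports named list of `metrics_report` objects.
#' @param times named numeric vector of training times in seconds (optional).
#' @param path optional CSV output path.
#' @return The table as a data.frame (invisibly written to `path` if given).
#' @export
metrics_table <- function(reports, times = NULL, path = NULL) {
  rows <- lapply(names(reports), function(nm) {
    m <- reports[[nm]]
    data.frame(Classifier = nm, Accuracy = m$accuracy, Error = m$error,
               Recall = m$recall, Specificity = m$specificity,
               Precision = m$precision, `False Positive Rate` = m$fpr,
               F1_Score = m$f1, MCC = m$mcc, Kappa = m$kappa,
               `Training Time(Sec)` = if (is.null(times)) NA_real_ else times[[nm]],
               check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  tab
}
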