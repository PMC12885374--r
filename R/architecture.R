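#' @title Layer-graph models of standard and slimmed ResNet-50
#' @description Constructive, framework-agnostic inventories of the two
#'   50-layer residual networks compared in this package: typed nodes
#'   (input, conv, batchnorm, relu, maxpool, avgpool, addition,
#'   fullyconnected, softmax, classification_output) wired into a DAG, with
#'   shape metadata sufficient to count learnable parameters exactly.
#' @name layer_graph
NULL

LAYER_KINDS <- c("input", "conv", "batchnorm", "relu", "maxpool", "avgpool",
                 "addition", "fullyconnected", "softmax",
                 "classification_output")

# Mutable builder: nodes as a growing list, edges as (from, to) index pairs.
new_graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$edges <- list()
  env$add <- function(kind, from = NULL, ...) {
    stopifnot(kind %in% LAYER_KINDS)
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- c(list(id = id, kind = kind), list(...))
    for (f in from) env$edges[[length(env$edges) + 1L]] <- c(f, id)
    id
  }
  env
}

finalize_graph <- function(b, stage_config, width_multiplier, n_output_classes,
                           variant) {
  edges <- if (length(b$edges)) do.call(rbind, b$edges) else matrix(integer(0), 0, 2)
  g <- structure(list(nodes = b$nodes, edges = edges,
                      stage_config = stage_config,
                      width_multiplier = width_multiplier,
                      n_output_classes = n_output_classes,
                      variant = variant),
                 class = "layer_graph")
  validate_layer_graph(g)
  g
}

# Kahn topological check: every built graph must be acyclic, with one
# source (input) and one sink; addition nodes must have exactly 2 inbound.
validate_layer_graph <- function(g) {
  n <- length(g$nodes)
  indeg <- tabulate(g$edges[, 2], n)
  outdeg <- tabulate(g$edges[, 1], n)
  kinds <- vapply(g$nodes, `[[`, character(1), "kind")
  if (sum(indeg == 0) != 1L || kinds[indeg == 0] != "input")
    stop_config("graph must have exactly one input source")
  if (sum(outdeg == 0) != 1L)
    stop_config("graph must have exactly one terminal node")
  if (any(indeg[kinds == "addition"] != 2L))
    stop_config("every addition node needs exactly 2 inbound branches")
  # Kahn's algorithm
  adj <- split(g$edges[, 2], factor(g$edges[, 1], levels = seq_len(n)))
  deg <- indeg
  queue <- which(deg == 0)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (w in adj[[v]]) {
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen != n) stop_config("layer graph contains a cycle")
  invisible(g)
}

scale_width <- function(w, m) max(1L, as.integer(round(w * m)))

# Shared bottleneck-stage grammar. Each block: three conv+bn pairs
# (1x1 -> 3x3 -> 1x1), relu after the first two and after the addition;
# the first block of each stage carries a 1x1 projection conv+bn on the
# shortcut branch.
build_resnet_graph <- function(stage_config, width_multiplier,
                               n_output_classes, classification_node,
                               variant) {
  b <- new_graph_builder()
  wm <- width_multiplier
  inp <- b$add("input", shape = c(224L, 224L, 3L))
  c1 <- scale_width(64L, wm)
  v <- b$add("conv", from = inp, in_channels = 3L, out_channels = c1,
             kernel = 7L, stride = 2L)
  v <- b$add("batchnorm", from = v, channels = c1)
  v <- b$add("relu", from = v)
  v <- b$add("maxpool", from = v, kernel = 3L, stride = 2L)
  in_ch <- c1
  base_widths <- c(64L, 128L, 256L, 512L)
  for (s in seq_along(stage_config)) {
    w <- scale_width(base_widths[((s - 1L) %% 4L) + 1L], wm)
    out_ch <- 4L * w
    for (blk in seq_len(stage_config[s])) {
      entry <- v
      u <- b$add("conv", from = entry, in_channels = in_ch, out_channels = w,
                 kernel = 1L, stride = 1L)
      u <- b$add("batchnorm", from = u, channels = w)
      u <- b$add("relu", from = u)
      u <- b$add("conv", from = u, in_channels = w, out_channels = w,
                 kernel = 3L, stride = 1L)
      u <- b$add("batchnorm", from = u, channels = w)
      u <- b$add("relu", from = u)
      u <- b$add("conv", from = u, in_channels = w, out_channels = out_ch,
                 kernel = 1L, stride = 1L)
      u <- b$add("batchnorm", from = u, channels = out_ch)
      if (blk == 1L) {
        sc <- b$add("conv", from = entry, in_channels = in_ch,
                    out_channels = out_ch, kernel = 1L, stride = 1L)
        sc <- b$add("batchnorm", from = sc, channels = out_ch)
        shortcut <- sc
      } else shortcut <- entry
      u <- b$add("addition", from = c(u, shortcut))
      v <- b$add("relu", from = u)
      in_ch <- out_ch
    }
  }
  v <- b$add("avgpool", from = v)
  v <- b$add("fullyconnected", from = v, in_features = in_ch,
             out_features = n_output_classes)
  v <- b$add("softmax", from = v)
  if (classification_node) v <- b$add("classification_output", from = v)
  finalize_graph(b, stage_config, width_multiplier, n_output_classes, variant)
}

#' Build the standard ResNet-50 layer graph
#'
#' Stem (7x7/64 conv, batchnorm, relu, maxpool), four bottleneck stages with
#' (3, 4, 6, 3) blocks, a projection conv+bn on each stage's first shortcut,
#' global average pool, 1000-way fully-connected head, softmax, and a
#' classification-output node: 177 nodes in total.
#'
#' @return A `layer_graph`.
#' @export
build_standard_resnet50 <- function() {
  build_resnet_graph(c(3L, 4L, 6L, 3L), 1, 1000L,
                     classification_node = TRUE, variant = "standard")
}

#' Build the slimmed (modified) ResNet-50 layer graph
#'
#' Same block grammar as the standard network but with a reduced stage
#' configuration (default (3, 4, 3, 3), i.e. 13 bottleneck blocks), an
#' 8-way fully-connected head, and no separate classification-output node:
#' 146 nodes at the defaults.
#'
#' @param stage_config residual-block counts per stage; totals other than 13
#'   are allowed but flagged with a warning as departing from the reference
#'   inventory.
#' @param width_multiplier channel-width scale in (0, 1\]; widths are
#'   rounded, minimum 1.
#' @param n_output_classes size of the fully-connected head (default 8).
#' @return A `layer_graph`.
#' @export
build_modified_resnet50 <- function(stage_config = c(3L, 4L, 3L, 3L),
                                    width_multiplier = 1,
                                    n_output_classes = 8L) {
  stage_config <- as.integer(stage_config)
  if (any(stage_config < 1L)) stop_config("stage_config entries must be >= 1")
  if (!is.numeric(width_multiplier) || width_multiplier <= 0 || width_multiplier > 1)
    stop_config("width_multiplier must lie in (0, 1]")
  if (sum(stage_config) != 13L)
    warning(sprintf("stage_config sums to %d, not 13: not the reference inventory",
                    sum(stage_config)))
  build_resnet_graph(stage_config, width_multiplier, as.integer(n_output_classes),
                     classification_node = FALSE, variant = "modified")
}

#' Census of layer kinds
#'
#' @param graph a `layer_graph`.
#' @return Named integer vector of node counts per kind (zero-count kinds
#'   included) with a `"total"` entry.
#' @export
count_layers <- function(graph) {
  stopifnot(inherits(graph, "layer_graph"))
  kinds <- vapply(graph$nodes, `[[`, character(1), "kind")
  counts <- vapply(LAYER_KINDS, function(k) sum(kinds == k), integer(1))
  c(counts, total = length(kinds))
}

#' Count learnable parameters
#'
#' Convolutions are bias-free (`k^2 * in * out`; batch normalization follows
#' every convolution and absorbs the bias), batchnorm contributes scale and
#' offset (`2 * channels`), the fully-connected head has weights and bias
#' (`in * out + out`); all other kinds have none.
#'
#' @param graph a `layer_graph`.
#' @return Exact integer parameter count.
#' @export
count_parameters <- function(graph) {
  stopifnot(inherits(graph, "layer_graph"))
  total <- 0
  for (nd in graph$nodes) {
    total <- total + switch(nd$kind,
      conv = {
        if (is.null(nd$kernel) || is.null(nd$in_channels) || is.null(nd$out_channels))
          stop_config("conv node %d lacks shape metadata", nd$id)
        as.numeric(nd$kernel)^2 * nd$in_channels * nd$out_channels
      },
      batchnorm = {
        if (is.null(nd$channels)) stop_config("batchnorm node %d lacks shape metadata", nd$id)
        2 * nd$channels
      },
      fullyconnected = {
        if (is.null(nd$in_features) || is.null(nd$out_features))
          stop_config("fullyconnected node %d lacks shape metadata", nd$id)
        as.numeric(nd$in_features) * nd$out_features + nd$out_features
      },
      0)
  }
  total
}

#' @export
print.layer_graph <- function(x, ...) {
  cts <- count_layers(x)
  cat(sprintf("<layer_graph> %s ResNet-50 variant: %d nodes, %.1fM parameters\n",
              x$variant, cts[["total"]], count_parameters(x) / 1e6))
  print(cts[cts > 0])
  invisible(x)
}

#' Export a layer graph as JSON
#'
#' @param graph a `layer_graph`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_layer_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "layer_graph"))
  jsonlite::write_json(list(variant = graph$variant,
                            stage_config = graph$stage_config,
                            width_multiplier = graph$width_multiplier,
                            n_output_classes = graph$n_output_classes,
                            nodes = graph$nodes,
                            edges = apply(graph$edges, 1, identity, simplify = FALSE)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
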