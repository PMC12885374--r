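#' Flea Optimization Algorithm configuration
#'
#' Controls the population-based search over feature-selection vectors.
#' Fleas are rows of an s x t position matrix in \[0, 1\]; a position is
#' binarized at `binarize_threshold` into a candidate feature mask whose
#' fitness is the negated converged penalized least-squares objective on the
#' masked columns. Defaults follow the reference hyperparameter table:
#' population 20, penalty `alpha = 0.0030`, optimization learning rate
#' 0.0001, resilin (jump-elasticity) drawn uniformly on (0, 1).
#'
#' @param population_size number of fleas `s` (>= 2).
#' @param max_iterations search budget; the four magnification regimes use
#'   690 (40x), 720 (100x), 700 (200x) and 630 (400x), see
#'   [foa_iterations()]. Default 690.
#' @param optimization_learning_rate scale of the Gaussian drift term in the
#'   exploitation move (eta).
#' @param resilin_range interval the per-move jump elasticity is drawn from.
#' @param alpha penalty strength of the fitness objective.
#' @param explore_probability per-coordinate probability of an exploration
#'   jump instead of an exploitation move.
#' @param binarize_threshold cut in (0, 1) turning positions into masks.
#' @param fitness_max_sweeps coordinate-descent sweep cap used inside the
#'   loop (the final mask uses a full-tolerance fit).
#' @param fitness_tol in-loop coordinate-descent tolerance; looser than the
#'   final fit's because fitness only needs the objective to rank masks.
#' @param seed integer seed; a run is a pure function of config + data.
#' @return An object of class `foa_config`.
#' @export
foa_config <- function(population_size = 20L, max_iterations = 690L,
                       optimization_learning_rate = 1e-4,
                       resilin_range = c(0, 1), alpha = 0.0030,
                       explore_probability = 0.02,
                       binarize_threshold = 0.5,
                       fitness_max_sweeps = 100L, fitness_tol = 1e-4,
                       seed = 1L) {
  if (!is_count(population_size, 2L)) stop_config("population_size must be an integer >= 2")
  if (!is_count(max_iterations, 1L)) stop_config("max_iterations must be >= 1")
  if (!is.numeric(resilin_range) || length(resilin_range) != 2L ||
      any(resilin_range < 0) || any(resilin_range > 1) ||
      resilin_range[1] > resilin_range[2])
    stop_config("resilin_range must be an interval inside [0, 1]")
  if (!is.numeric(explore_probability) || explore_probability < 0 || explore_probability > 1)
    stop_config("explore_probability must lie in [0, 1]")
  if (!is.numeric(binarize_threshold) || binarize_threshold <= 0 || binarize_threshold >= 1)
    stop_config("binarize_threshold must lie strictly inside (0, 1)")
  if (!is.numeric(alpha) || alpha < 0) stop_config("alpha must be non-negative")
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 optimization_learning_rate = optimization_learning_rate,
                 resilin_range = as.numeric(resilin_range),
                 alpha = alpha,
                 explore_probability = explore_probability,
                 binarize_threshold = binarize_threshold,
                 fitness_max_sweeps = as.integer(fitness_max_sweeps),
                 fitness_tol = fitness_tol,
                 seed = as.integer(seed)),
            class = "foa_config")
}

#' Iteration budget per magnification regime
#'
#' @param magnification one of `"40x"`, `"100x"`, `"200x"`, `"400x"`.
#' @return The iteration budget: 690, 720, 700 or 630.
#' @export
foa_iterations <- function(magnification = c("40x", "100x", "200x", "400x")) {
  magnification <- match.arg(magnification)
  c("40x" = 690L, "100x" = 720L, "200x" = 700L, "400x" = 630L)[[magnification]]
}

# Precompute the standardized design and centered one-hot responses once per
# dataset; every fitness call reuses them. Fitness values are memoized by
# candidate mask (fleas converge onto few distinct masks late in a run).
foa_fitness_context <- function(ds) {
  prob <- lasso_problem(ds$features, rep(0, nrow(ds$features)))
  classes <- sort(unique(ds$labels))
  n <- nrow(ds$features)
  Y <- vapply(classes, function(k) {
    y <- as.numeric(ds$labels == k); y - mean(y)
  }, numeric(n))
  list(Gfull = crossprod(prob$Ls) / n, B = crossprod(prob$Ls, Y) / n,
       yty = colSums(Y^2) / n, active = prob$active, t = ncol(ds$features),
       cache = new.env(parent = emptyenv()))
}

fitness_from_context <- function(position, ctx, config) {
  mask <- position >= config$binarize_threshold & ctx$active
  if (!any(mask)) return(-Inf)
  cols <- which(mask)
  key <- paste(cols, collapse = " ")
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  fit_tol <- if (is.null(config$fitness_tol)) 1e-4 else config$fitness_tol
  val <- -.cd_fitness_cpp(ctx$Gfull, ctx$B, ctx$yty, cols - 1L, config$alpha,
                          fit_tol, config$fitness_max_sweeps)
  ctx$cache[[key]] <- val
  val
}

#' Fitness of a single flea position
#'
#' Binarizes the position at the configured threshold; an empty mask scores
#' `-Inf` (it can never become the incumbent best), otherwise the fitness is
#' the negated mean converged penalized objective fitted on the masked
#' columns only, so higher fitness means lower penalized loss.
#'
#' @param position numeric vector in \[0, 1\]^t.
#' @param ds a [feature_dataset()].
#' @param alpha penalty strength.
#' @param binarize_threshold mask cut, default 0.5.
#' @param max_sweeps coordinate-descent sweep cap.
#' @return Scalar fitness.
#' @export
flea_fitness <- function(position, ds, alpha = 0.0030,
                         binarize_threshold = 0.5, max_sweeps = 100L) {
  cfg <- list(alpha = alpha, binarize_threshold = binarize_threshold,
              fitness_max_sweeps = as.integer(max_sweeps),
              fitness_tol = 1e-6)
  fitness_from_context(position, foa_fitness_context(ds), cfg)
}

#' Initialize a flea population
#'
#' Positions are i.i.d. U(0, 1); fitness is evaluated once and the incumbent
#' best recorded. Uses the current RNG stream ([run_foa()] seeds it).
#'
#' @param config a [foa_config()].
#' @param ds a [feature_dataset()] defining `t` and the fitness landscape.
#' @return An object of class `flea_population` with fields `positions`
#'   (s x t), `fitness`, `best_position`, `best_fitness`.
#' @export
initialize_population <- function(config, ds) {
  stopifnot(inherits(config, "foa_config"), inherits(ds, "feature_dataset"))
  ctx <- foa_fitness_context(ds)
  t <- ctx$t
  if (t < 1L) stop_config("dataset has no features")
  s <- config$population_size
  positions <- matrix(runif(s * t), s, t)
  fitness <- vapply(seq_len(s), function(i)
    fitness_from_context(positions[i, ], ctx, config), numeric(1))
  b <- which.max(fitness)
  structure(list(positions = positions, fitness = fitness,
                 best_position = positions[b, ], best_fitness = fitness[b],
                 context = ctx),
            class = "flea_population")
}

#' One FOA generation
#'
#' For every flea except the incumbent best (elitism) and every coordinate:
#' with probability `explore_probability` take an exploration jump
#' `f <- r*u + (1 - r)*f` with `u ~ U(0,1)` and a fresh resilin draw
#' `r ~ U(resilin_range)`; otherwise exploit,
#' `f <- f + r*(best - f) + eta*zeta` with `zeta ~ N(0,1)`. Positions are
#' clipped to \[0, 1\], fitness re-evaluated, and the incumbent best updated
#' only if beaten, so the best fitness never decreases.
#'
#' @param pop a `flea_population`.
#' @param config a [foa_config()].
#' @return The updated `flea_population`.
#' @export
update_positions <- function(pop, config) {
  stopifnot(inherits(pop, "flea_population"), inherits(config, "foa_config"))
  ctx <- pop$context
  s <- nrow(pop$positions); t <- ncol(pop$positions)
  eta <- config$optimization_learning_rate
  best_i <- which.max(pop$fitness)
  for (i in seq_len(s)) {
    if (i == best_i) next
    f <- pop$positions[i, ]
    r <- runif(t, config$resilin_range[1], config$resilin_range[2])
    explore <- runif(t) < config$explore_probability
    if (any(explore)) {
      u <- runif(sum(explore))
      f[explore] <- r[explore] * u + (1 - r[explore]) * f[explore]
    }
    if (any(!explore)) {
      zeta <- rnorm(sum(!explore))
      f[!explore] <- f[!explore] +
        r[!explore] * (pop$best_position[!explore] - f[!explore]) + eta * zeta
    }
    f <- pmin(pmax(f, 0), 1)
    pop$positions[i, ] <- f
    pop$fitness[i] <- fitness_from_context(f, ctx, config)
  }
  b <- which.max(pop$fitness)
  if (pop$fitness[b] > pop$best_fitness) {
    pop$best_fitness <- pop$fitness[b]
    pop$best_position <- pop$positions[b, ]
  }
  pop
}

#' Run the Flea Optimization Algorithm
#'
#' Initializes a population and iterates [update_positions()] for
#' `max_iterations` generations. Per-feature importance is the mean position
#' value over the elite (top-fitness) half of the final population; the
#' ranking sorts importance descending with ties broken by ascending index.
#' Features whose importance reaches `binarize_threshold` form the candidate
#' set, on which a full-tolerance multiclass penalized fit is run; its
#' nonzero union is the final mask. If the candidate set is empty the
#' top-`ceil(t/10)` ranked features are used instead, with a warning.
#'
#' @param ds a [feature_dataset()].
#' @param config a [foa_config()].
#' @return An object of class `selection_result`: `mask` (length-t logical),
#'   `ranking`, `importance`, `fitness_trace` (non-decreasing),
#'   `n_selected`, plus the final `best_fitness`.
#' @export
run_foa <- function(ds, config = foa_config()) {
  stopifnot(inherits(ds, "feature_dataset"), inherits(config, "foa_config"))
  with_seed(config$seed, {
    pop <- initialize_population(config, ds)
    trace <- numeric(config$max_iterations)
    for (it in seq_len(config$max_iterations)) {
      pop <- update_positions(pop, config)
      trace[it] <- pop$best_fitness
    }
    t <- ncol(pop$positions)
    elite_n <- ceiling(config$population_size / 2)
    elite <- order(-pop$fitness)[seq_len(elite_n)]
    importance <- colMeans(pop$positions[elite, , drop = FALSE])
    ranking <- order(-importance, seq_len(t))
    candidates <- which(importance >= config$binarize_threshold)
    if (length(candidates) == 0L) {
      warning("empty candidate set after thresholding; falling back to top-ranked features")
      candidates <- ranking[seq_len(ceiling(t / 10))]
    }
    final_fit <- fit_lasso_multiclass(ds$features[, candidates, drop = FALSE],
                                      ds$labels, alpha = config$alpha)
    mask <- logical(t)
    mask[candidates] <- select_nonzero(final_fit)
    structure(list(mask = mask,
                   ranking = ranking,
                   importance = importance,
                   fitness_trace = trace,
                   n_selected = sum(mask),
                   best_fitness = pop$best_fitness,
                   candidates = candidates,
                   config = config),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d features selected; best fitness %.6g after %d iterations\n",
              x$n_selected, length(x$mask), x$best_fitness,
              length(x$fitness_trace)))
  invisible(x)
}
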