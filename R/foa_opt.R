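#' Fruit-fly optimizer configuration
#'
#' The optimizer searches the two DPC decision variables directly: the
#' swarm anchor `(X_axis, Y_axis)` holds the current `(d_c, k)` location,
#' each fly proposes `anchor + U(step_low, step_high)` per coordinate
#' (random step instead of a fixed step, which helps escape local optima),
#' proposals are clamped into the parameter box and scored by the fitness
#' ("smell concentration"), and the anchor relocates to the best proposal
#' whenever it improves the best smell found so far (elitism).
#'
#' @param sizepop number of flies per generation (default 10).
#' @param maxgen number of generations (default 10).
#' @param step_low,step_high bounds of the uniform random step (default
#'   -5, 5, gray-level / cluster-count units).
#' @param seed RNG seed; every random draw of the optimizer derives from it.
#' @param bounds list of per-variable `(low, high)` ranges; defaults to
#'   `d_c` in `[1, 10]` and `k` in `[2, 40]`.
#' @return a `foa_config` list.
#' @export
foa_config <- function(sizepop = 10L, maxgen = 10L,
                       step_low = -5, step_high = 5, seed = NULL,
                       bounds = list(d_c = c(1, 10), k = c(2, 40))) {
  if (sizepop < 1L || maxgen < 1L) stop("sizepop and maxgen must be >= 1")
  if (!(step_low < step_high)) stop("step_low must be < step_high")
  for (b in bounds) if (!(b[1] < b[2])) stop("bound low must be < high")
  structure(list(sizepop = as.integer(sizepop), maxgen = as.integer(maxgen),
                 step_low = step_low, step_high = step_high, seed = seed,
                 bounds = bounds),
            class = "foa_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Decode a fly position into DPC parameters
#'
#' Coordinates map one-to-one onto the decision variables: the first onto
#' `d_c`, clamped into its range; the second onto `k`, clamped and rounded
#' half-up to an integer.
#'
#' @param position numeric vector `(x_dc, x_k)`.
#' @param bounds per-variable ranges (see [foa_config()]).
#' @return a [dpc_params()] list.
#' @export
foa_decode <- function(position, bounds = list(d_c = c(1, 10), k = c(2, 40))) {
  if (any(!is.finite(position))) stop("position must be finite")
  d_c <- clamp(position[1], bounds$d_c[1], bounds$d_c[2])
  k <- round_half_up(clamp(position[2], bounds$k[1], bounds$k[2]))
  dpc_params(d_c, k)
}

#' Initialize the fly swarm
#'
#' The anchor is drawn uniformly inside the parameter box; the swarm starts
#' with no evaluated proposals and an empty trace.
#'
#' @param config a [foa_config()]. Uses the current RNG stream (seed it
#'   first, or call via [foa_optimize()] which seeds it).
#' @return a `fly_swarm` list.
#' @export
foa_init_swarm <- function(config) {
  axis <- vapply(config$bounds, function(b) runif(1, b[1], b[2]), numeric(1))
  structure(list(axis = axis, positions = NULL, smell = NULL,
                 best_smell = -Inf, best_params = NULL, best_position = NULL,
                 trace = numeric(0)),
            class = "fly_swarm")
}

#' Smell phase: random-step proposals around the anchor
#'
#' @param swarm a `fly_swarm`.
#' @param config a [foa_config()].
#' @return matrix (sizepop x 2) of candidate positions.
#' @export
foa_smell_step <- function(swarm, config) {
  nvar <- length(swarm$axis)
  steps <- matrix(runif(config$sizepop * nvar, config$step_low,
                        config$step_high),
                  nrow = config$sizepop)
  sweep(steps, 2, swarm$axis, "+")
}

#' Best smell of a generation
#'
#' @param smells numeric vector of fitness values, all finite.
#' @return list `(best_smell, best_index)`; ties go to the lowest index.
#' @export
foa_select_best <- function(smells) {
  if (length(smells) == 0L) stop("no smells to select from")
  if (any(!is.finite(smells))) stop("fitness returned a non-finite value")
  i <- which.max(smells)
  list(best_smell = smells[i], best_index = i)
}

#' Vision phase: elitist anchor relocation
#'
#' The anchor flies to the best proposal only when it improves on the best
#' smell seen so far, so the best-so-far trace never decreases.
#'
#' @param swarm a `fly_swarm` with evaluated `positions` and `smell`.
#' @param best output of [foa_select_best()].
#' @param params_of list of decoded [dpc_params()] per fly.
#' @return the updated swarm (trace extended by one generation).
#' @export
foa_visual_step <- function(swarm, best, params_of) {
  if (best$best_smell > swarm$best_smell) {
    swarm$best_smell <- best$best_smell
    swarm$best_position <- swarm$positions[best$best_index, ]
    swarm$best_params <- params_of[[best$best_index]]
    swarm$axis <- swarm$best_position
  }
  swarm$trace <- c(swarm$trace, swarm$best_smell)
  swarm
}

#' Run the fruit-fly optimizer
#'
#' Alternates the smell phase (random-step proposals, decoded and scored)
#' and the vision phase (elitist relocation) for `maxgen` generations,
#' evaluating `sizepop * maxgen` candidates in total.
#'
#' @param fitness function taking a [dpc_params()] list and returning a
#'   finite scalar to maximize.
#' @param config a [foa_config()].
#' @return list: `best_params`, `best_smell`, `trace` (best smell per
#'   generation, non-decreasing), `evaluations`.
#' @export
foa_optimize <- function(fitness, config = foa_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  swarm <- foa_init_swarm(config)
  for (gen in seq_len(config$maxgen)) {
    swarm$positions <- foa_smell_step(swarm, config)
    params <- apply(swarm$positions, 1, foa_decode, bounds = config$bounds,
                    simplify = FALSE)
    swarm$smell <- vapply(params, function(p) as.numeric(fitness(p)),
                          numeric(1))
    best <- foa_select_best(swarm$smell)
    swarm <- foa_visual_step(swarm, best, params)
  }
  list(best_params = swarm$best_params, best_smell = swarm$best_smell,
       trace = swarm$trace, evaluations = config$sizepop * config$maxgen)
}
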