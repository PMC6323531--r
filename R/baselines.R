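#' Exhaustive grid search over the DPC parameter lattice
#'
#' Evaluates the fitness at every cell of the effective integer lattice
#' `d_c in 1..10, k in 2..40` (390 cells). Because gray distances are
#' integers, every real `d_c` behaves like `ceiling(d_c)`, so this lattice
#' is exhaustive: the grid optimum is a true upper bound for any optimizer
#' on the same objective.
#'
#' @param fitness function of a [dpc_params()] list returning a scalar, or
#'   `NULL` to use segmentation entropy of `hist`.
#' @param hist a [gray_histogram()] (required when `fitness` is `NULL`).
#' @param d_c_values,k_values lattice axes.
#' @return a `grid_result`: `table` (data.frame `d_c`, `k`, `fitness`),
#'   `best_params`, `best_fitness`, `evaluations`.
#' @export
grid_search <- function(fitness = NULL, hist = NULL,
                        d_c_values = 1:10, k_values = 2:40) {
  if (is.null(fitness)) {
    if (is.null(hist)) stop("supply a fitness function or a histogram")
    fitness <- entropy_fitness(hist)
  }
  cells <- expand.grid(d_c = d_c_values, k = k_values)
  vals <- mapply(function(d_c, k) fitness(dpc_params(d_c, k)),
                 cells$d_c, cells$k)
  i <- which.max(vals)
  structure(list(table = cbind(cells, fitness = vals),
                 best_params = dpc_params(cells$d_c[i], cells$k[i]),
                 best_fitness = vals[i], evaluations = nrow(cells)),
            class = "grid_result")
}

#' Entropy fitness closure for a histogram
#'
#' Returns the smell-concentration function used throughout: for given
#' `(d_c, k)` it fits the DPC model on `hist` and returns the Shannon
#' entropy (bits) of the resulting cluster-size distribution. Evaluations
#' are memoized on the effective lattice cell `(ceiling(d_c), k)` since
#' only that cell determines the clustering.
#'
#' @param hist a [gray_histogram()].
#' @return function `params -> entropy bits`.
#' @export
entropy_fitness <- function(hist) {
  cache <- new.env(parent = emptyenv())
  function(params) {
    key <- paste(ceiling(params$d_c), params$k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    model <- dpc_fit(hist, params$d_c, params$k)
    val <- segmentation_entropy(hist, model)
    cache[[key]] <- val
    val
  }
}

#' Weighted one-dimensional k-means on the gray histogram
#'
#' Lloyd's algorithm over the present gray levels, each weighted by its
#' pixel count, with k-means++-style seeded initialization; iterates until
#' assignments are stable. `nstart` independent starts are run and the one
#' with the smallest weighted within-cluster sum of squares kept (a single
#' start can converge to a poor local optimum). Cluster ids are 0-based and
#' ordered by ascending cluster mean.
#'
#' @param hist a [gray_histogram()].
#' @param k number of clusters, `2 <= k <=` number of present levels.
#' @param seed RNG seed for the k-means++ initializations.
#' @param nstart number of random restarts (default 10).
#' @param max_iter safety cap on Lloyd iterations.
#' @return list: `level_label` (length-256, gray+1 indexed, NA at absent
#'   levels), `centers` (cluster means), `effective_k`, `withinss`.
#' @export
kmeans_gray <- function(hist, k, seed = NULL, nstart = 10L,
                        max_iter = 100L) {
  levels <- which(hist$counts > 0L) - 1L
  counts <- as.numeric(hist$counts[levels + 1L])
  if (k < 2 || k > length(levels))
    stop("k must be in [2, number of present levels]")
  if (!is.null(seed)) set.seed(seed)
  assign_lab <- function(ctr) {
    apply(abs(outer(levels, ctr, "-")), 1, which.min)
  }
  one_start <- function() {
    # k-means++ seeding on the weighted points
    centers <- numeric(k)
    centers[1] <- levels[sample.int(length(levels), 1, prob = counts)]
    for (j in seq_len(k)[-1]) {
      d2 <- vapply(levels, function(g) min((g - centers[seq_len(j - 1)])^2),
                   numeric(1))
      w <- counts * d2
      centers[j] <- if (sum(w) == 0) levels[which.max(d2)] else
        levels[sample.int(length(levels), 1, prob = w)]
    }
    lab <- assign_lab(centers)
    for (it in seq_len(max_iter)) {
      for (j in seq_len(k)) {
        m <- lab == j
        if (any(m)) centers[j] <- sum(levels[m] * counts[m]) / sum(counts[m])
      }
      new_lab <- assign_lab(centers)
      if (all(new_lab == lab)) break
      lab <- new_lab
    }
    wss <- sum(counts * (levels - centers[lab])^2)
    list(lab = lab, centers = centers, wss = wss)
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    cand <- one_start()
    if (is.null(best) || cand$wss < best$wss) best <- cand
  }
  lab <- best$lab
  ord <- order(vapply(seq_len(k), function(j)
    if (any(lab == j)) sum(levels[lab == j] * counts[lab == j]) /
      sum(counts[lab == j]) else Inf, numeric(1)))
  relabel <- match(seq_len(k), ord) - 1L
  level_label <- rep(NA_integer_, 256L)
  level_label[levels + 1L] <- relabel[lab]
  list(level_label = level_label, centers = sort(best$centers),
       effective_k = length(unique(lab)), withinss = best$wss)
}

#' Real-coded genetic algorithm over the DPC parameter box
#'
#' Baseline optimizer: tournament selection (size 2), extended arithmetic
#' crossover (rate 0.9; one blend coefficient per gene drawn from
#' `U(-1, 2)`, so children may extrapolate past their parents, repaired by
#' clamping onto the box -- plain interior averaging cannot reach optima on
#' the box boundary, where the entropy objective typically peaks),
#' uniform-reset mutation (rate 0.15 per gene, the main source of fresh
#' diversity once the blend contracts the population), elitism of one.
#' Genomes are real `(d_c, k)` points in the same box as the fruit-fly
#' optimizer and are decoded with the same clamp/round rule, so the two
#' methods optimize the identical objective and differ only in their search
#' dynamics. At the default population 10 and 20 generations it spends
#' 200 fitness evaluations, twice the fruit-fly budget.
#'
#' @param fitness function of a [dpc_params()] list, to maximize.
#' @param pop population size (default 10).
#' @param gens generations (default 20).
#' @param seed RNG seed.
#' @param p_cross,p_mut crossover and per-gene mutation rates.
#' @param bounds per-variable ranges.
#' @return list: `best_params`, `best_fitness`, `trace` (non-decreasing),
#'   `evaluations`.
#' @export
ga_optimize <- function(fitness, pop = 10L, gens = 20L, seed = NULL,
                        p_cross = 0.9, p_mut = 0.15,
                        bounds = list(d_c = c(1, 10), k = c(2, 40))) {
  if (pop < 2L || gens < 1L) stop("pop must be >= 2, gens >= 1")
  if (!is.null(seed)) set.seed(seed)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  nvar <- length(bounds)
  genomes <- matrix(runif(pop * nvar, rep(lo, each = pop),
                          rep(hi, each = pop)), nrow = pop)
  score <- function(g) {
    p <- foa_decode(g, bounds)
    val <- as.numeric(fitness(p))
    if (!is.finite(val)) stop("fitness returned a non-finite value")
    val
  }
  best_fit <- -Inf; best_genome <- NULL; trace <- numeric(0)
  evals <- 0L
  for (gen in seq_len(gens)) {
    fit <- apply(genomes, 1, score)
    evals <- evals + pop
    i <- which.max(fit)
    if (fit[i] > best_fit) { best_fit <- fit[i]; best_genome <- genomes[i, ] }
    trace <- c(trace, best_fit)
    if (gen == gens) break
    tournament <- function() {
      a <- sample.int(pop, 2)
      genomes[a[which.max(fit[a])], ]
    }
    offspring <- matrix(0, nrow = pop, ncol = nvar)
    offspring[1, ] <- best_genome                      # elitism of one
    for (r in 2:pop) {
      p1 <- tournament(); p2 <- tournament()
      child <- if (runif(1) < p_cross) {
        a <- runif(nvar, -1, 2); a * p1 + (1 - a) * p2
      } else p1
      mut <- runif(nvar) < p_mut
      child[mut] <- runif(sum(mut), lo[mut], hi[mut])
      offspring[r, ] <- clamp(child, lo, hi)
    }
    genomes <- offspring
  }
  list(best_params = foa_decode(best_genome, bounds), best_fitness = best_fit,
       trace = trace, evaluations = evals)
}
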