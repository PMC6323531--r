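#' Segment a grayscale image end to end
#'
#' Orchestrates the full method: build the gray-level histogram, let the
#' chosen optimizer propose `(d_c, k)`, fit the density-peaks clustering,
#' score candidates by segmentation entropy, and return the elitist best
#' segmentation together with its quality metrics (entropy in bits, SEC)
#' and the per-generation convergence trace.
#'
#' Methods:
#' * `"foa"` -- random-step fruit-fly optimizer (default population 10,
#'   10 generations, 100 fitness evaluations);
#' * `"ga"`  -- real-coded genetic algorithm (population 10, 20
#'   generations, 200 evaluations);
#' * `"grid"` -- exhaustive search of the 390-cell `(d_c, k)` lattice, the
#'   deterministic upper bound for the stochastic methods;
#' * `"kmeans"` -- weighted 1-D k-means on the histogram at fixed `k`
#'   (default 7), bypassing DPC.
#'
#' @param img a [gray_image()] (or integer matrix).
#' @param method one of `"foa"`, `"ga"`, `"grid"`, `"kmeans"`.
#' @param pop,gens population size and generations for the stochastic
#'   methods; `NULL` picks the method default (10/10 for foa, 10/20 for
#'   ga).
#' @param seed seed driving every random draw of the run.
#' @param kmeans_k cluster count for `method = "kmeans"`.
#' @param step_range length-2 numeric, the fruit-fly random-step bounds.
#' @return a `segmentation_result`: `method`, `params` (`d_c`, `k`),
#'   `effective_k`, `entropy_bits`, `sec`, `labels` (matrix),
#'   `cluster_mean_gray`, `centers` (DPC center gray levels, NULL for
#'   kmeans), `trace`, `evaluations`, `seed`, `model`.
#' @export
segment_image <- function(img, method = c("foa", "ga", "grid", "kmeans"),
                          pop = NULL, gens = NULL, seed = NULL,
                          kmeans_k = 7L, step_range = c(-5, 5)) {
  method <- match.arg(method)
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  hist <- gray_histogram(img)
  fitness <- entropy_fitness(hist)

  if (method == "kmeans") {
    n_levels <- sum(hist$counts > 0L)
    km <- kmeans_gray(hist, k = min(kmeans_k, n_levels), seed = seed)
    model <- list(level_label = km$level_label)
    seg <- relabel_pixels(img, model)
    return(new_segmentation_result(
      method = method, d_c = NA_real_, k = as.integer(kmeans_k),
      seg = seg, centers = NULL, trace = numeric(0),
      evaluations = 0L, seed = seed))
  }

  opt <- switch(method,
    foa = foa_optimize(fitness, foa_config(
      sizepop = if (is.null(pop)) 10L else pop,
      maxgen = if (is.null(gens)) 10L else gens,
      step_low = step_range[1], step_high = step_range[2], seed = seed)),
    ga = {
      r <- ga_optimize(fitness, pop = if (is.null(pop)) 10L else pop,
                       gens = if (is.null(gens)) 20L else gens, seed = seed)
      list(best_params = r$best_params, best_smell = r$best_fitness,
           trace = r$trace, evaluations = r$evaluations)
    },
    grid = {
      r <- grid_search(fitness)
      list(best_params = r$best_params, best_smell = r$best_fitness,
           trace = r$best_fitness, evaluations = r$evaluations)
    })

  model <- dpc_fit(hist, opt$best_params$d_c, opt$best_params$k)
  seg <- relabel_pixels(img, model)
  res <- new_segmentation_result(
    method = method, d_c = opt$best_params$d_c, k = opt$best_params$k,
    seg = seg, centers = model$centers, trace = opt$trace,
    evaluations = opt$evaluations, seed = seed)
  res$model <- model
  # the fitness the optimizer reported must be the entropy of the final
  # segmentation it chose
  stopifnot(isTRUE(all.equal(res$entropy_bits, opt$best_smell)))
  res
}

new_segmentation_result <- function(method, d_c, k, seg, centers, trace,
                                    evaluations, seed) {
  structure(list(
    method = method,
    params = list(d_c = d_c, k = as.integer(k)),
    effective_k = seg$effective_k,
    entropy_bits = image_entropy(seg),
    sec = sec(seg),
    labels = seg$labels,
    cluster_mean_gray = seg$cluster_mean_gray,
    centers = centers,
    trace = trace,
    evaluations = evaluations,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result: method=%s d_c=%s k=%d effective_k=%d>\n",
    x$method, format(x$params$d_c), x$params$k, x$effective_k))
  cat(sprintf("  entropy = %.4f bits, SEC = %.2f, evaluations = %d\n",
              x$entropy_bits, x$sec, x$evaluations))
  invisible(x)
}

#' Default palette: each cluster rendered at its mean source gray
#'
#' @param result a `segmentation_result`.
#' @return named integer vector usable with [write_label_image()].
#' @export
mean_gray_palette <- function(result) {
  p <- round_half_up(result$cluster_mean_gray)
  storage.mode(p) <- "integer"
  p
}

#' Write a machine-readable segmentation report
#'
#' JSON report with the chosen parameters, quality metrics and convergence
#' trace; the schema ships at
#' `system.file("schema", "segmentation-report.schema.json",
#' package = "foadpc")`. The report contains no timestamps, so identical
#' seeds yield byte-identical files.
#'
#' @param result a `segmentation_result`.
#' @param path output path.
#' @export
write_report <- function(result, path) {
  report <- list(
    schema = "foadpc-segmentation-report-v1",
    method = result$method,
    seed = if (is.na(result$seed)) NULL else result$seed,
    d_c = if (is.na(result$params$d_c)) NULL else result$params$d_c,
    k = result$params$k,
    effective_k = result$effective_k,
    entropy_bits = result$entropy_bits,
    sec = result$sec,
    evaluations = result$evaluations,
    centers = as.integer(result$centers),
    cluster_mean_gray = unname(result$cluster_mean_gray),
    trace = result$trace)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export the convergence trace as CSV
#'
#' @param result a `segmentation_result` from a stochastic method.
#' @param path output CSV path (header `generation,best_smell`).
#' @export
write_trace <- function(result, path) {
  df <- data.frame(generation = seq_along(result$trace),
                   best_smell = result$trace)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
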