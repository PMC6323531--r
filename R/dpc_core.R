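#' Neighborhood indicator of density-peaks clustering
#'
#' `chi(x)` is 1 for `x < 0` and 0 otherwise. The local density of a point
#' is the number of points whose distance falls strictly below the cut-off,
#' i.e. `sum(chi(d_ij - d_c))`.
#'
#' @param x finite numeric vector.
#' @return 0/1 vector of the same length.
#' @export
chi <- function(x) {
  if (any(!is.finite(x))) stop("chi() requires finite input")
  as.integer(x < 0)
}

#' Validate DPC parameters
#'
#' The cut-off distance `d_c` is a real in `[1, 10]` (gray-level units) and
#' the requested cluster count `k` an integer in `[2, 40]`; these ranges
#' bound the optimizer's search box. Because gray distances are integers,
#' only `ceiling(d_c)` affects the clustering, so the 390-cell integer
#' lattice `d_c in 1..10, k in 2..40` covers every distinct behavior.
#'
#' @param d_c cut-off distance.
#' @param k cluster count.
#' @return a `dpc_params` list.
#' @export
dpc_params <- function(d_c, k) {
  if (!is.finite(d_c) || d_c < 1 || d_c > 10)
    stop("d_c must lie in [1, 10]")
  if (!is.finite(k) || k != round(k) || k < 2 || k > 40)
    stop("k must be an integer in [2, 40]")
  structure(list(d_c = as.numeric(d_c), k = as.integer(k)),
            class = "dpc_params")
}

#' Frequency-weighted local density per gray level
#'
#' For every present gray level `g`, the density is the number of pixels at
#' levels `g'` with `|g - g'| < d_c` (strict, per [chi()]; the level's own
#' pixels are included). Pixels are the clustered points and the gray-level
#' difference is the distance, so the histogram ordinate weights the density.
#'
#' @param hist a [gray_histogram()].
#' @param d_c cut-off distance in `[1, 10]`.
#' @return list with `levels` (ascending present gray levels) and `rho`
#'   (density per level).
#' @export
dpc_density <- function(hist, d_c) {
  if (!is.finite(d_c) || d_c < 1 || d_c > 10)
    stop("d_c must lie in [1, 10]")
  levels <- which(hist$counts > 0L) - 1L
  counts <- hist$counts[levels + 1L]
  d <- abs(outer(levels, levels, "-"))
  rho <- as.vector((d < d_c) %*% counts)
  list(levels = levels, rho = rho)
}

# Total rank order of present levels: density descending, then pixel count
# descending, then gray ascending. The strict-density partial order of the
# delta definition is extended to this total order so results are
# deterministic under density ties.
dpc_rank_order <- function(rho, counts, levels) {
  order(-rho, -counts, levels)
}

#' Separation distance delta and nearest denser neighbor
#'
#' Levels are ranked by (density desc, count desc, gray asc). For every
#' level except the top-ranked one, `delta` is the minimal gray distance to
#' a strictly higher-ranked level and `nn_higher` that neighbor (distance
#' ties resolved to the lower gray). The top-ranked level takes the maximum
#' distance to any other level, so the global density peak always carries
#' the largest `gamma = rho * delta` and can be selected as a center. A
#' single-level histogram gets `delta = 1` by convention so `gamma` stays
#' defined.
#'
#' @param levels ascending present gray levels.
#' @param rho densities per level (from [dpc_density()]).
#' @param counts pixel counts per level.
#' @return list with `delta`, `nn_higher` (NA for the top-ranked level) and
#'   `rank_order` (indices into `levels`, highest rank first).
#' @export
dpc_delta <- function(levels, rho, counts) {
  n <- length(levels)
  stopifnot(length(rho) == n, length(counts) == n, n >= 1L)
  ord <- dpc_rank_order(rho, counts, levels)
  delta <- numeric(n)
  nn <- rep(NA_integer_, n)
  if (n == 1L) {
    delta[1] <- 1
    return(list(delta = delta, nn_higher = nn, rank_order = ord))
  }
  top <- ord[1]
  delta[top] <- max(abs(levels - levels[top]))
  for (r in 2:n) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1L)]
    d <- abs(levels[higher] - levels[i])
    best <- min(d)
    cand <- higher[d == best]
    nn[i] <- cand[which.min(levels[cand])]
    delta[i] <- best
  }
  list(delta = delta, nn_higher = nn, rank_order = ord)
}

#' Center score gamma = rho * delta
#'
#' @param rho,delta aligned numeric vectors.
#' @return elementwise product.
#' @export
dpc_gamma <- function(rho, delta) {
  if (length(rho) != length(delta)) stop("rho and delta lengths differ")
  rho * delta
}

# Order of center candidacy: gamma desc, rho desc, gray asc.
dpc_center_order <- function(gamma, rho, levels) {
  order(-gamma, -rho, levels)
}

#' Select cluster centers by gamma ranking
#'
#' The `min(k, number of levels)` levels with the largest `gamma` become
#' centers; ties broken by larger density, then lower gray. This replaces
#' the manual pick from the rho-delta decision graph.
#'
#' @param profile density profile as returned by [dpc_profile()].
#' @param k requested cluster count (>= 2; silently clamped to the number of
#'   present levels).
#' @return integer vector of center gray levels, in descending-gamma order.
#' @export
dpc_select_centers <- function(profile, k) {
  if (k < 2) stop("k must be >= 2")
  n <- length(profile$levels)
  k_eff <- min(as.integer(k), n)
  ord <- dpc_center_order(profile$gamma, profile$rho, profile$levels)
  profile$levels[ord[seq_len(k_eff)]]
}

#' Propagate cluster labels down the density ranking
#'
#' Centers receive labels `0..k_eff-1` in their gamma order; the remaining
#' levels are visited in decreasing density rank and each inherits the label
#' of its nearest denser neighbor, which is already labeled by construction.
#'
#' @param profile density profile from [dpc_profile()].
#' @param centers center gray levels from [dpc_select_centers()].
#' @return integer vector of cluster ids aligned with `profile$levels`.
#' @export
dpc_assign_labels <- function(profile, centers) {
  levels <- profile$levels
  n <- length(levels)
  if (!all(centers %in% levels)) stop("centers must be present levels")
  label <- rep(NA_integer_, n)
  label[match(centers, levels)] <- seq_along(centers) - 1L
  for (i in profile$rank_order) {
    if (!is.na(label[i])) next
    nn <- profile$nn_higher[i]
    # the nearest denser neighbor outranks i, so it is labeled already
    stopifnot(!is.na(nn), !is.na(label[nn]))
    label[i] <- label[nn]
  }
  label
}

#' Full density profile of a histogram
#'
#' Computes rho, delta, nn_higher and gamma for every present gray level.
#'
#' @param hist a [gray_histogram()].
#' @param d_c cut-off distance in `[1, 10]`.
#' @return a `dpc_profile` list: `levels`, `counts`, `rho`, `delta`,
#'   `nn_higher`, `gamma`, `rank_order`.
#' @export
dpc_profile <- function(hist, d_c) {
  den <- dpc_density(hist, d_c)
  counts <- hist$counts[den$levels + 1L]
  del <- dpc_delta(den$levels, den$rho, counts)
  structure(
    list(levels = den$levels, counts = counts, rho = den$rho,
         delta = del$delta, nn_higher = del$nn_higher,
         gamma = dpc_gamma(den$rho, del$delta),
         rank_order = del$rank_order),
    class = "dpc_profile")
}

#' Fit a density-peaks clustering of a gray-level histogram
#'
#' @param hist a [gray_histogram()].
#' @param d_c cut-off distance in `[1, 10]`.
#' @param k requested cluster count (clamped to the number of present
#'   levels; the optimizer searches `k` in `[2, 40]` but larger values are
#'   accepted here, e.g. for identity clusterings).
#' @return a `dpc_model`: `params`, `profile`, `centers`, `effective_k`,
#'   `level_label` (length-256 integer vector indexed by gray+1, NA at
#'   absent levels).
#' @export
dpc_fit <- function(hist, d_c, k) {
  profile <- dpc_profile(hist, d_c)
  centers <- dpc_select_centers(profile, k)
  label <- dpc_assign_labels(profile, centers)
  level_label <- rep(NA_integer_, 256L)
  level_label[profile$levels + 1L] <- label
  structure(
    list(params = list(d_c = as.numeric(d_c), k = as.integer(k)),
         profile = profile, centers = centers,
         effective_k = length(centers), level_label = level_label),
    class = "dpc_model")
}

#' @export
print.dpc_model <- function(x, ...) {
  cat(sprintf("<dpc_model: d_c = %g, k = %d (effective %d), %d levels>\n",
              x$params$d_c, x$params$k, x$effective_k,
              length(x$profile$levels)))
  invisible(x)
}

#' Decision-graph table
#'
#' One row per present gray level with its rho, delta and gamma, sorted by
#' gray -- the data behind the classic rho-delta scatter used to pick
#' centers by eye.
#'
#' @param profile a [dpc_profile()].
#' @param path optional CSV output path (header `gray,rho,delta,gamma`).
#' @return data.frame with columns `gray`, `rho`, `delta`, `gamma`.
#' @export
decision_graph <- function(profile, path = NULL) {
  df <- data.frame(gray = profile$levels, rho = profile$rho,
                   delta = profile$delta, gamma = profile$gamma)
  df <- df[order(df$gray), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
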