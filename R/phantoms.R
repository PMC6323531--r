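#' Specify a synthetic grayscale phantom
#'
#' Phantoms emulate the piecewise-constant structure of brain CT/MRI slices
#' (a dark background with brighter lesion/edema-like regions) without any
#' external image data: a background gray, a list of constant-gray regions
#' (ellipses or axis-aligned rectangles, later regions painted over earlier
#' ones), and additive Gaussian pixel noise.
#'
#' @param size `c(height, width)` in pixels.
#' @param background background gray in `[0, 255]`.
#' @param regions list of regions; each is a list with `shape` ("ellipse"
#'   or "rectangle"), `gray` (base gray, distinct across regions and from
#'   the background), and geometry: ellipse `center = c(row, col)`,
#'   `radii = c(r_row, r_col)`; rectangle `corner = c(row, col)` (top-left,
#'   1-based) and `extent = c(h, w)`. The default is a two-region
#'   lesion-plus-edema-like layout (an ellipse at gray 120 and a rectangle
#'   at gray 200 on a gray-40 background) scaled to `size`.
#' @param noise_sigma standard deviation of the additive Gaussian noise in
#'   gray-level units (default 5, a moderate scanner-noise level for 8-bit
#'   data).
#' @param seed RNG seed for the noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(128L, 128L), background = 40L,
                         regions = NULL,
                         noise_sigma = 5, seed = NULL) {
  if (is.null(regions)) {
    h <- size[1]; w <- size[2]
    regions <- list(
      list(shape = "ellipse", gray = 120L,
           center = round(c(0.352 * h, 0.391 * w)),
           radii = round(c(0.203 * h, 0.234 * w))),
      list(shape = "rectangle", gray = 200L,
           corner = round(c(0.625 * h, 0.547 * w)),
           extent = round(c(0.266 * h, 0.313 * w))))
  }
  grays <- c(background, vapply(regions, function(r) as.numeric(r$gray),
                                numeric(1)))
  if (anyDuplicated(grays)) stop("region base grays must be distinct")
  if (any(grays < 0 | grays > 255)) stop("base grays must lie in [0, 255]")
  for (r in regions) {
    if (!r$shape %in% c("ellipse", "rectangle"))
      stop("unknown shape: ", r$shape)
    ok <- if (r$shape == "ellipse") {
      all(r$center - r$radii >= 1) && r$center[1] + r$radii[1] <= size[1] &&
        r$center[2] + r$radii[2] <= size[2]
    } else {
      all(r$corner >= 1) && r$corner[1] + r$extent[1] - 1 <= size[1] &&
        r$corner[2] + r$extent[2] - 1 <= size[2]
    }
    if (!ok) stop("region geometry out of image bounds")
  }
  structure(list(size = as.integer(size), background = as.integer(background),
                 regions = regions, noise_sigma = noise_sigma, seed = seed),
            class = "phantom_spec")
}

#' Generate a phantom image with ground-truth labels
#'
#' Paints the background and each region in order (later regions overwrite
#' earlier ones), then adds seeded Gaussian noise, rounds half-up and clips
#' to `[0, 255]`. Truth label 0 is the background; region `i` gets label
#' `i`.
#'
#' @param spec a [phantom_spec()].
#' @return list: `image` (a [gray_image()]), `truth` (integer matrix of
#'   region labels), `base_grays` (gray per truth label, background first).
#' @export
phantom_generate <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  base <- matrix(as.numeric(spec$background), h, w)
  truth <- matrix(0L, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    inside <- if (r$shape == "ellipse") {
      ((rows - r$center[1]) / r$radii[1])^2 +
        ((cols - r$center[2]) / r$radii[2])^2 <= 1
    } else {
      rows >= r$corner[1] & rows < r$corner[1] + r$extent[1] &
        cols >= r$corner[2] & cols < r$corner[2] + r$extent[2]
    }
    base[inside] <- r$gray
    truth[inside] <- i
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$noise_sigma > 0)
    base <- base + rnorm(length(base), sd = spec$noise_sigma)
  pix <- pmin(pmax(round_half_up(base), 0), 255)
  list(image = gray_image(matrix(as.integer(pix), h, w)), truth = truth,
       base_grays = c(spec$background,
                      vapply(spec$regions, function(r) as.integer(r$gray),
                             integer(1))))
}

# Hungarian algorithm (shortest augmenting path, O(n^3)) for a square cost
# matrix; returns, for each column, the assigned row. Sizes here are tiny
# (<= number of clusters, 40), so a compact R implementation suffices.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)   # index 1 = virtual column 0
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1]  # row assigned to each column
}

#' Pixel accuracy after optimal cluster-to-truth matching
#'
#' Builds the confusion matrix between predicted cluster ids and truth
#' labels and scores the agreement. With `one_to_one = TRUE` (the default)
#' clusters and truth classes are matched one-to-one by the Hungarian
#' algorithm, maximizing the matched pixel count; with
#' `one_to_one = FALSE` every predicted cluster is merged into the truth
#' class it overlaps most (many-to-one), which is the natural score when an
#' over-segmented result (many gray clusters) is compared against a few
#' anatomical truth regions.
#'
#' @param pred integer matrix of predicted cluster ids.
#' @param truth integer matrix of truth labels, same shape.
#' @param one_to_one require a one-to-one cluster/truth matching.
#' @return accuracy in `[0, 1]`.
#' @export
match_and_score <- function(pred, truth, one_to_one = TRUE) {
  if (!all(dim(pred) == dim(truth))) stop("pred and truth shapes differ")
  conf <- table(factor(as.integer(pred)), factor(as.integer(truth)))
  conf <- matrix(as.numeric(conf), nrow = nrow(conf))
  if (!one_to_one) return(sum(apply(conf, 1, max)) / sum(conf))
  n <- max(dim(conf))
  padded <- matrix(0, n, n)
  padded[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  assignment <- solve_assignment(max(padded) - padded)  # maximize overlap
  matched <- sum(padded[cbind(assignment, seq_len(n))])
  matched / sum(conf)
}
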