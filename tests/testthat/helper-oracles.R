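# Independent reference implementations used as oracles. These deliberately
# use naive per-pixel / per-pair loops rather than the package's vectorized
# histogram-level code paths.

# Brute-force DPC on the expanded pixel multiset. Returns per-level rho,
# delta and labels, following the documented tie-break rules:
# rank order (rho desc, counts desc, gray asc), nn ties -> lower gray,
# center order (gamma desc, rho desc, gray asc).
oracle_dpc <- function(counts, d_c, k) {
  pixels <- rep(0:255, counts)              # one entry per pixel
  levels <- sort(unique(pixels))
  n <- length(levels)
  lev_counts <- vapply(levels, function(g) sum(pixels == g), integer(1))
  rho <- numeric(n)
  for (i in seq_len(n))
    rho[i] <- sum(abs(levels[i] - pixels) < d_c)   # enumerate every pixel
  ord <- order(-rho, -lev_counts, levels)
  delta <- numeric(n)
  nn <- rep(NA_integer_, n)
  if (n == 1L) {
    delta[1] <- 1
  } else {
    top <- ord[1]
    delta[top] <- max(abs(levels - levels[top]))
    for (r in 2:n) {
      i <- ord[r]
      best <- Inf; bi <- NA_integer_
      for (s in seq_len(r - 1L)) {
        j <- ord[s]
        d <- abs(levels[i] - levels[j])
        if (d < best || (d == best && levels[j] < levels[bi])) {
          best <- d; bi <- j
        }
      }
      delta[i] <- best; nn[i] <- bi
    }
  }
  gamma <- rho * delta
  cord <- order(-gamma, -rho, levels)
  k_eff <- min(k, n)
  centers <- levels[cord[seq_len(k_eff)]]
  label <- rep(NA_integer_, n)
  for (c in seq_len(k_eff)) label[cord[c]] <- c - 1L
  for (r in seq_len(n)) {
    i <- ord[r]
    if (is.na(label[i])) label[i] <- label[nn[i]]
  }
  list(levels = levels, rho = rho, delta = delta, gamma = gamma,
       centers = centers, label = label)
}

# Random sparse histogram: at most max_levels present levels, at most
# max_pixels pixels in total.
random_hist_counts <- function(max_levels = 20L, max_pixels = 10000L) {
  n_lev <- sample.int(max_levels, 1)
  levels <- sort(sample(0:255, n_lev))
  counts <- rep(0L, 256)
  budget <- sample.int(max_pixels - n_lev + 1L, 1) + n_lev - 1L
  alloc <- as.integer(rmultinom(1, budget - n_lev, rep(1, n_lev))) + 1L
  counts[levels + 1L] <- alloc
  counts
}

hist_from_counts <- function(counts) {
  structure(list(counts = as.integer(counts), total = sum(counts)),
            class = "gray_histogram")
}

# An image whose histogram equals `counts` exactly (single-row raster).
image_from_counts <- function(counts) {
  pixels <- rep(0:255, counts)
  gray_image(matrix(pixels, nrow = 1))
}

# Exhaustive maximum-overlap one-to-one matching by permutation enumeration
# (square matrices up to ~7x7).
oracle_best_matching <- function(conf) {
  n <- max(dim(conf))
  padded <- matrix(0, n, n)
  padded[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(n)))
    best <- max(best, sum(padded[cbind(p, seq_len(n))]))
  best
}

# The 5 standard test phantoms: 128x128, 8-bit, 2-4 piecewise-constant
# regions with base grays >= 60 apart, Gaussian noise sigma 5 (one at 8).
standard_phantom_specs <- function() {
  list(
    phantom_spec(seed = 101),
    phantom_spec(background = 30, regions = list(
      list(shape = "ellipse", gray = 110, center = c(60, 64),
           radii = c(40, 50)),
      list(shape = "ellipse", gray = 190, center = c(60, 64),
           radii = c(18, 22))), seed = 102),
    phantom_spec(background = 60, regions = list(
      list(shape = "rectangle", gray = 140, corner = c(20, 20),
           extent = c(50, 90)),
      list(shape = "ellipse", gray = 220, center = c(95, 64),
           radii = c(20, 40))), seed = 103),
    phantom_spec(background = 20, regions = list(
      list(shape = "ellipse", gray = 90, center = c(40, 40),
           radii = c(25, 25)),
      list(shape = "ellipse", gray = 160, center = c(85, 85),
           radii = c(25, 25)),
      list(shape = "rectangle", gray = 230, corner = c(10, 90),
           extent = c(25, 25))), seed = 104),
    phantom_spec(noise_sigma = 8, seed = 105))
}
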