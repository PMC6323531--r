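#' Relabel pixels by their gray level's cluster
#'
#' Every pixel inherits the cluster of its gray level under a fitted DPC
#' model; cluster mean grays are pixel-count weighted means of the source
#' image.
#'
#' @param img a [gray_image()].
#' @param model a [dpc_fit()] model covering every gray value in `img`.
#' @return a `segmented_image`: `labels` (integer matrix of 0-based cluster
#'   ids), `cluster_mean_gray` (named numeric vector), `cluster_size`
#'   (named integer vector, pixels per cluster), `effective_k`.
#' @export
relabel_pixels <- function(img, model) {
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  lab <- model$level_label[as.integer(img) + 1L]
  if (anyNA(lab)) {
    bad <- sort(unique(as.integer(img)[is.na(lab)]))
    stop("gray value(s) not covered by the model: ",
         paste(bad, collapse = ", "))
  }
  labels <- matrix(lab, nrow = nrow(img))
  segmented_image(labels, as.integer(img))
}

#' Construct a segmented image from labels and source grays
#'
#' @param labels integer matrix of 0-based cluster ids.
#' @param source_gray integer vector or matrix of the source gray values,
#'   same length as `labels`.
#' @return a `segmented_image` (see [relabel_pixels()]).
#' @export
segmented_image <- function(labels, source_gray) {
  if (length(labels) != length(source_gray))
    stop("labels and source_gray sizes differ")
  lab <- as.integer(labels)
  ids <- sort(unique(lab))
  if (min(ids) < 0L) stop("cluster ids must be >= 0")
  size <- vapply(ids, function(i) sum(lab == i), integer(1))
  means <- vapply(ids, function(i) mean(as.numeric(source_gray)[lab == i]),
                  numeric(1))
  names(size) <- names(means) <- as.character(ids)
  structure(list(labels = labels, cluster_mean_gray = means,
                 cluster_size = size, effective_k = length(ids)),
            class = "segmented_image")
}

# Shannon entropy (bits) of a vector of non-negative weights.
entropy_bits <- function(w) {
  w <- w[w > 0]
  p <- w / sum(w)
  -sum(p * log2(p))
}

#' Entropy of a segmented image
#'
#' Shannon entropy `H = -sum q_c log2 q_c` (bits) of the cluster-frequency
#' distribution of the segmentation; `0 * log 0` is 0. This is the smell
#' concentration (fitness) maximized by the optimizers: higher entropy
#' means the segmentation spreads pixels over more, better-balanced
#' regions. `H <= log2(effective_k)`, with equality iff clusters are
#' equally populated.
#'
#' @param seg a [segmented_image()].
#' @return entropy in bits.
#' @export
image_entropy <- function(seg) {
  entropy_bits(seg$cluster_size)
}

# Fast fitness path used by the optimizers: entropy of the segmentation of
# `hist` under a DPC model, computed from the histogram alone (the label of
# each pixel depends only on its gray level, so cluster sizes are sums of
# level counts).
segmentation_entropy <- function(hist, model) {
  lab <- model$level_label[model$profile$levels + 1L]
  sizes <- rowsum(as.numeric(model$profile$counts), lab)
  entropy_bits(as.vector(sizes))
}

#' Between-class variance of a segmentation (SEC)
#'
#' Clusters are ordered by ascending mean gray; for each adjacent pair with
#' sizes `N`, `M` and mean grays `U1`, `U2`, the two-class between-class
#' variance `N/(N+M) (U1-U)^2 + M/(N+M) (U2-U)^2` (with pooled mean
#' `U = (N U1 + M U2)/(N+M)`) is accumulated. Each term equals the classic
#' two-class Otsu variance `N M / (N+M)^2 (U1-U2)^2`. Larger SEC means
#' stronger contrast between neighboring regions. A single-cluster
#' segmentation has SEC 0 by convention.
#'
#' @param seg a [segmented_image()].
#' @return SEC value (squared gray-level units).
#' @export
sec <- function(seg) {
  if (seg$effective_k < 2L) return(0)
  ord <- order(seg$cluster_mean_gray)
  u <- unname(seg$cluster_mean_gray[ord])
  n <- unname(as.numeric(seg$cluster_size[ord]))
  total <- 0
  for (i in seq_len(length(u) - 1L)) {
    N <- n[i]; M <- n[i + 1L]
    U1 <- u[i]; U2 <- u[i + 1L]
    U <- (N * U1 + M * U2) / (N + M)
    total <- total + N / (N + M) * (U1 - U)^2 + M / (N + M) * (U2 - U)^2
  }
  total
}
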