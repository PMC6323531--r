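#' Construct an 8-bit grayscale image
#'
#' A `gray_image` is an integer matrix of gray values in `[0, 255]` with at
#' least one pixel. All clustering in this package operates on the 256-level
#' gray domain, so higher bit depths must be rescaled explicitly at read time
#' (see [load_gray_image()]).
#'
#' @param pixels integer (or whole-number numeric) matrix of gray values.
#' @return a `gray_image` object (integer matrix with class attribute).
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || length(pixels) < 1L)
    stop("pixels must be a non-empty matrix")
  if (anyNA(pixels)) stop("pixels must not contain NA")
  if (is.double(pixels)) {
    if (max(abs(pixels - round(pixels))) > 1e-9)
      stop("pixels must be whole numbers")
    storage.mode(pixels) <- "integer"
  }
  if (min(pixels) < 0L || max(pixels) > 255L)
    stop("gray values must lie in [0, 255]")
  structure(pixels, class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# round() in R rounds half to even; image quantization here uses the
# conventional round-half-up so results are reproducible across platforms.
round_half_up <- function(x) floor(x + 0.5)

#' Read a grayscale image from PNG, PGM or TIFF
#'
#' Reads an image file and returns an 8-bit [gray_image()]. Multi-channel
#' images are converted by the ITU-R BT.601 luma `0.299 R + 0.587 G +
#' 0.114 B`, rounded half-up; an alpha channel, if any, is ignored. Inputs
#' with more than 8 bits per sample are rejected unless `rescale = TRUE`, in
#' which case they are min-max rescaled onto `[0, 255]` (a constant image
#' maps to 0).
#'
#' @param path file path; format inferred from the extension
#'   (`.png`, `.pgm`, `.tif`/`.tiff`).
#' @param rescale rescale >8-bit input to the 0..255 domain instead of
#'   raising an error.
#' @return a [gray_image()].
#' @export
load_gray_image <- function(path, rescale = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    img_from_unit_array(arr, rescale, path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE)
    img_from_integer_array(arr, rescale, path)
  } else if (ext == "pgm") {
    read_pgm(path, rescale)
  } else {
    stop("unsupported image format: .", ext)
  }
}

# arr: numeric array in [0,1] as returned by png::readPNG.
# 8-bit samples are exact multiples of 1/255; detect deeper inputs by
# checking that v*255 is integral.
img_from_unit_array <- function(arr, rescale, path) {
  gray <- collapse_luma(arr * 255)
  if (max(abs(gray - round(gray))) > 1e-6) {
    if (!rescale)
      stop("more than 8 bits per sample in ", path,
           "; pass rescale = TRUE to min-max rescale")
    gray <- minmax_rescale(gray)
  }
  gray_image(round_half_up(gray))
}

# arr: integer-valued array as returned by tiff::readTIFF(as.is = TRUE).
img_from_integer_array <- function(arr, rescale, path) {
  gray <- collapse_luma(arr)
  if (max(gray) > 255) {
    if (!rescale)
      stop("more than 8 bits per sample in ", path,
           "; pass rescale = TRUE to min-max rescale")
    gray <- minmax_rescale(gray)
  }
  gray_image(round_half_up(gray))
}

collapse_luma <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) {
    g <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    return(matrix(g, nrow = dim(arr)[1]))
  }
  if (length(dim(arr)) == 3L && dim(arr)[3] %in% c(1L, 2L))
    return(matrix(arr[, , 1], nrow = dim(arr)[1]))  # gray or gray+alpha
  stop("unsupported channel layout")
}

minmax_rescale <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1]) * 255
}

# Minimal PGM reader: plain (P2) and raw (P5), maxval <= 65535.
read_pgm <- function(path, rescale = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens: magic, width, height, maxval; '#' starts a comment
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  n <- w * h
  if (magic == "P5") {
    bytes <- if (maxval > 255L) 2L else 1L
    raw <- readBin(con, "integer", n = n, size = bytes,
                   signed = FALSE, endian = "big")
    vals <- raw
  } else {
    rest <- readChar(con, 1e8, useBytes = TRUE)
    rest <- gsub("#[^\n]*", " ", rest)
    vals <- as.integer(strsplit(trimws(rest), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  if (anyNA(vals) || length(vals) < n) stop("truncated PGM data")
  if (maxval > 255L) {
    if (!rescale)
      stop("more than 8 bits per sample in ", path,
           "; pass rescale = TRUE to min-max rescale")
    vals <- round_half_up(minmax_rescale(vals))
  }
  gray_image(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
}

#' Gray-level histogram of an image
#'
#' Counts pixels per gray level 0..255. The histogram is the point set that
#' density-peaks clustering operates on: gray levels are the points, pixel
#' frequencies their weights, and the absolute gray difference the distance.
#'
#' @param img a [gray_image()] or integer matrix of values in `[0,255]`.
#' @return a `gray_histogram`: list with `counts` (length-256 integer vector,
#'   `counts[g+1]` = number of pixels of gray `g`) and `total` (pixel count).
#' @export
gray_histogram <- function(img) {
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  structure(list(counts = counts, total = length(img)),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram: %d pixels, %d present levels>\n",
              x$total, sum(x$counts > 0L)))
  invisible(x)
}

#' Write a label image as an 8-bit grayscale PNG
#'
#' Renders a cluster-label matrix to PNG using a palette that maps every
#' cluster id to an output gray. Reading the file back yields exactly
#' `palette[labels]`.
#'
#' @param labels integer matrix of cluster ids (0-based).
#' @param palette named integer vector, names are cluster ids as characters,
#'   values output grays in `[0,255]`. The default palette used by
#'   [segment_image()] maps each cluster to its mean source gray rounded
#'   half-up.
#' @param path output PNG path.
#' @export
write_label_image <- function(labels, palette, path) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  ids <- sort(unique(as.integer(labels)))
  missing <- setdiff(as.character(ids), names(palette))
  if (length(missing) > 0L)
    stop("palette missing cluster id(s): ", paste(missing, collapse = ", "))
  if (min(palette) < 0 || max(palette) > 255)
    stop("palette grays must lie in [0, 255]")
  gray <- matrix(palette[as.character(labels)], nrow = nrow(labels))
  png::writePNG(gray / 255, target = path)
  invisible(path)
}
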