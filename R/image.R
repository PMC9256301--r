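#' Grayscale image container
#'
#' A `gray_image` is a plain numeric matrix with values in `[0, 1]`,
#' carrying the class attribute `"gray_image"`. Rows are `y` (0-based row
#' index), columns are `x` (0-based column index). At least 3 rows and 3
#' columns are required so finite differences have interior pixels.
#'
#' @param values Numeric matrix with all values finite and in `[0, 1]`.
#' @return A `gray_image` (numeric matrix).
#' @export
gray_image <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "snakeseg_input_error")
  }
  if (nrow(values) < 3L || ncol(values) < 3L) {
    abort("image must be at least 3 x 3 pixels.", class = "snakeseg_input_error")
  }
  if (any(!is.finite(values))) {
    abort("image contains non-finite values.", class = "snakeseg_input_error")
  }
  if (min(values) < 0 || max(values) > 1) {
    abort("image values must lie in [0, 1]; use normalize_image() first.",
          class = "snakeseg_input_error")
  }
  structure(values, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d pixels, range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

as_plain_matrix <- function(m) {
  attr(m, "kind") <- NULL
  class(m) <- c("matrix", "array")
  m
}

#' Min-max normalize a raw intensity grid to [0, 1]
#'
#' Linearly rescales so the minimum maps to 0 and the maximum to 1. A
#' constant grid maps to all zeros (the degenerate-range convention).
#'
#' @param raw Numeric matrix of raw intensities (any finite range).
#' @return A [gray_image()].
#' @export
#' @examples
#' normalize_image(matrix(c(0, 127.5, 255), 3, 3, byrow = TRUE))
normalize_image <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw) || length(raw) == 0L) {
    abort("`raw` must be a non-empty numeric matrix.",
          class = "snakeseg_input_error")
  }
  if (any(!is.finite(raw))) {
    abort("`raw` contains non-finite values.", class = "snakeseg_input_error")
  }
  rng <- range(raw)
  out <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else
    matrix(0, nrow(raw), ncol(raw))
  gray_image(out)
}

# Reflective (half-sample symmetric) padding by r pixels on all sides.
# Indices reflect with period 2n, so r may exceed the image size.
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

pad_reflect <- function(m, r) {
  if (r == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- reflect_index(seq.int(1L - r, h + r), h)
  ci <- reflect_index(seq.int(1L - r, w + r), w)
  m[ri, ci, drop = FALSE]
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Gaussian smoothing with reflective borders
#'
#' Separable convolution with a sampled, unit-mass Gaussian kernel of
#' standard deviation `sigma` (truncated at 4 sigma). `sigma = 0` returns the
#' input unchanged. Reflective border handling avoids spurious image-edge
#' gradients that would otherwise attract a snake to the frame.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param sigma Kernel standard deviation in pixels, `>= 0`.
#' @param clip Clip the result back to `[0, 1]` (guards rounding spill).
#' @return A matrix of the same shape (a `gray_image` when `clip = TRUE`).
#' @export
gaussian_smooth <- function(img, sigma, clip = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    abort("`sigma` must be a single finite value >= 0.",
          class = "snakeseg_param_error")
  }
  m <- as_plain_matrix(img)
  if (sigma == 0) return(if (clip) gray_image(m) else m)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  p <- pad_reflect(m, r)
  h <- nrow(m); w <- ncol(m)
  # convolve along x (columns)
  acc <- matrix(0, h + 2L * r, w)
  for (j in seq_along(k)) {
    acc <- acc + k[j] * p[, (j - 1L) + seq_len(w), drop = FALSE]
  }
  # convolve along y (rows)
  out <- matrix(0, h, w)
  for (j in seq_along(k)) {
    out <- out + k[j] * acc[(j - 1L) + seq_len(h), , drop = FALSE]
  }
  if (clip) gray_image(pmin(pmax(out, 0), 1)) else out
}

#' Image gradient by finite differences
#'
#' Central differences on interior pixels and one-sided differences at the
#' borders. `u` holds the x-derivative (along columns), `v` the y-derivative
#' (along rows).
#'
#' @param img A [gray_image()] or numeric matrix.
#' @return A [vector_field()] with components `u` and `v`.
#' @export
image_gradient <- function(img) {
  m <- as_plain_matrix(img)
  h <- nrow(m); w <- ncol(m)
  if (h < 2L || w < 2L) abort("image too small for gradients.",
                              class = "snakeseg_input_error")
  u <- matrix(0, h, w)
  u[, 2:(w - 1L)] <- (m[, 3:w, drop = FALSE] - m[, 1:(w - 2L), drop = FALSE]) / 2
  u[, 1L] <- m[, 2L] - m[, 1L]
  u[, w] <- m[, w] - m[, w - 1L]
  v <- matrix(0, h, w)
  v[2:(h - 1L), ] <- (m[3:h, , drop = FALSE] - m[1:(h - 2L), , drop = FALSE]) / 2
  v[1L, ] <- m[2L, ] - m[1L, ]
  v[h, ] <- m[h, ] - m[h - 1L, ]
  vector_field(u, v)
}

#' Per-pixel 2-D vector field
#'
#' Holds the x-components `u` and y-components `v` of a vector field over the
#' pixel grid (image gradients, GVF fields).
#'
#' @param u,v Numeric matrices of one common shape, all values finite.
#' @return A `vector_field` (list with elements `u`, `v`).
#' @export
vector_field <- function(u, v) {
  if (!is.matrix(u) || !is.matrix(v) || !all(dim(u) == dim(v))) {
    abort("`u` and `v` must be matrices of one shape.",
          class = "snakeseg_input_error")
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    abort("vector field contains non-finite components.",
          class = "snakeseg_input_error")
  }
  structure(list(u = as_plain_matrix(u), v = as_plain_matrix(v)),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %d x %d, max |F| = %.4g\n",
              nrow(x$u), ncol(x$u), sqrt(max(x$u^2 + x$v^2))))
  invisible(x)
}

#' Read a single-channel grayscale image (PNG or TIFF)
#'
#' 8- and 16-bit single-channel files are accepted; values arrive scaled to
#' `[0, 1]`. Multi-channel (RGB/RGBA) inputs are rejected.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("image file not found: %s", path),
          class = "snakeseg_input_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format: .%s (use PNG or TIFF)", ext),
          class = "snakeseg_input_error")
  )
  if (length(dim(arr)) == 3L) {
    abort(sprintf("expected a single-channel image, got %d channels.",
                  dim(arr)[3]), class = "snakeseg_input_error")
  }
  gray_image(pmin(pmax(arr, 0), 1))
}

#' Write a matrix as PNG (8-bit) or 32-bit float TIFF
#'
#' PNG output clips to `[0, 1]`. TIFF storage is limited to `[0, 1]`
#' samples, so signed data (energy maps, force-field components) are
#' written min-max rescaled with the original range recorded in a
#' `<path>.range` sidecar; [read_scalar_tiff()] undoes the rescaling.
#'
#' @param m Numeric matrix.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(m, path) {
  m <- as_plain_matrix(m)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(m, 0), 1), path)
  } else if (ext %in% c("tif", "tiff")) {
    lo <- min(m); hi <- max(m)
    scaled <- if (hi > lo) (m - lo) / (hi - lo) else matrix(0, nrow(m),
                                                           ncol(m))
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
    writeLines(format(c(lo, hi), digits = 17), paste0(path, ".range"))
  } else {
    abort(sprintf("unsupported output format: .%s", ext),
          class = "snakeseg_input_error")
  }
  invisible(path)
}

#' Read back a float TIFF written by [write_image()]
#'
#' Restores the original value range from the `<path>.range` sidecar; a
#' bare TIFF without a sidecar is returned as stored.
#'
#' @param path TIFF path.
#' @return A numeric matrix.
#' @export
read_scalar_tiff <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("TIFF not found: %s", path),
          class = "snakeseg_input_error")
  }
  m <- tiff::readTIFF(path)
  side <- paste0(path, ".range")
  if (file.exists(side)) {
    rng <- as.numeric(readLines(side))
    m <- rng[1] + m * (rng[2] - rng[1])
  }
  m
}
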