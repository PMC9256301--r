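# Image-derived energy maps for the snake's external energy.
#
# Each map is a numeric matrix of the image's shape with an attribute
# `kind` in {"line", "edge", "termination", "combined"}.

new_energy_map <- function(values, kind) {
  if (any(!is.finite(values))) {
    abort("energy map contains non-finite values.",
          class = "snakeseg_numeric_error")
  }
  structure(as_plain_matrix(values), kind = kind,
            class = c("energy_map", "matrix", "array"))
}

#' @export
print.energy_map <- function(x, ...) {
  cat(sprintf("<energy_map:%s> %d x %d, range [%.4g, %.4g]\n",
              attr(x, "kind"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Line energy: the image intensity itself
#'
#' `E_line(x, y) = A(x, y)`. A snake weighting this term positively is
#' attracted to dark structures (low intensity minimizes the energy);
#' a negative weight attracts to bright structures.
#'
#' @param img A [gray_image()].
#' @return An energy map of the image's shape.
#' @export
line_energy <- function(img) {
  new_energy_map(as_plain_matrix(gray_image(as_plain_matrix(img))), "line")
}

#' Edge energy from the smoothed intensity gradient
#'
#' The attractive convention `E_edge = -|grad(G_sigma * A)|^2`: strong edges
#' are deep minima, so gradient descent on the energy pulls the contour onto
#' boundaries. All values are `<= 0`. `form = "reciprocal"` instead returns
#' `1 / max(|grad A|^2, eps)` — an alternative published form that repels the
#' contour from edges; it is provided for completeness and is not used by any
#' default pipeline.
#'
#' @param img A [gray_image()].
#' @param sigma Gaussian pre-smoothing in pixels (`>= 0`).
#' @param form `"attractive"` (default) or `"reciprocal"`.
#' @param eps Clamp for the reciprocal form's denominator.
#' @return An energy map of the image's shape.
#' @export
edge_energy <- function(img, sigma = 1, form = c("attractive", "reciprocal"),
                        eps = 1e-8) {
  form <- match.arg(form)
  sm <- gaussian_smooth(img, sigma, clip = FALSE)
  g <- image_gradient(sm)
  sq <- g$u^2 + g$v^2
  vals <- if (form == "attractive") -sq else 1 / pmax(sq, eps)
  new_energy_map(vals, "edge")
}

#' Termination energy: level-line curvature of the smoothed image
#'
#' For the smoothed image `C = G_sigma * A`, computes the curvature of the
#' iso-intensity lines,
#' `(C_yy C_x^2 - 2 C_xy C_x C_y + C_xx C_y^2) / (C_x^2 + C_y^2)^(3/2)`,
#' which peaks at line terminations and corners. Where the gradient magnitude
#' squared falls below `eps_grad` the curvature is defined as 0 (flat
#' regions have no level-line direction).
#'
#' @param img A [gray_image()].
#' @param sigma Gaussian smoothing in pixels; must be `> 0` for stable
#'   second derivatives.
#' @param eps_grad Gradient-squared threshold below which the value is 0.
#' @return An energy map of the image's shape.
#' @export
termination_energy <- function(img, sigma = 1, eps_grad = 1e-8) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    abort("`sigma` must be > 0 for termination energy.",
          class = "snakeseg_param_error")
  }
  cs <- gaussian_smooth(img, sigma, clip = FALSE)
  g1 <- image_gradient(cs)
  gx <- image_gradient(g1$u)   # u: C_xx, v: C_xy
  gy <- image_gradient(g1$v)   # u: C_yx, v: C_yy
  cx <- g1$u; cy <- g1$v
  num <- gy$v * cx^2 - 2 * gx$v * cx * cy + gx$u * cy^2
  den2 <- cx^2 + cy^2
  vals <- matrix(0, nrow(den2), ncol(den2))
  ok <- den2 >= eps_grad
  vals[ok] <- num[ok] / den2[ok]^1.5
  new_energy_map(vals, "termination")
}

#' Weighted combination of external energy maps
#'
#' `w_line * E_line + w_edge * E_edge + w_term * E_term`, the external energy
#' the classic snake descends.
#'
#' @param line,edge,term Energy maps of one common shape (any may be a plain
#'   matrix).
#' @param w_line,w_edge,w_term Scalar weights.
#' @return An energy map of kind `"combined"`.
#' @export
combine_external_energy <- function(line, edge, term,
                                    w_line = 0, w_edge = 1, w_term = 0) {
  dims <- list(dim(line), dim(edge), dim(term))
  if (!all(vapply(dims, function(d) all(d == dims[[1]]), logical(1)))) {
    abort("energy maps must share one shape.", class = "snakeseg_input_error")
  }
  vals <- w_line * as_plain_matrix(line) + w_edge * as_plain_matrix(edge) +
    w_term * as_plain_matrix(term)
  new_energy_map(vals, "combined")
}
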