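# Gradient vector flow (GVF): diffuses edge-map gradients across the image
# so that boundary forces reach into homogeneous regions and concavities,
# extending the snake's capture range far beyond the raw gradient's.

#' GVF parameters
#'
#' @param mu Regularization weight (`> 0`): larger values smooth the field
#'   more and carry it further from edges.
#' @param iters Number of diffusion iterations (`>= 0`).
#' @param dt Diffusion time step; the explicit scheme requires
#'   `dt * 4 * mu < 1`, enforced here.
#' @return A `gvf_params` list.
#' @export
gvf_params <- function(mu = 0.2, iters = 200L, dt = 0.25) {
  if (!is.numeric(mu) || mu <= 0) {
    abort("`mu` must be > 0.", class = "snakeseg_param_error")
  }
  if (!is.numeric(iters) || iters < 0) {
    abort("`iters` must be >= 0.", class = "snakeseg_param_error")
  }
  if (!is.numeric(dt) || dt <= 0) {
    abort("`dt` must be > 0.", class = "snakeseg_param_error")
  }
  if (dt * 4 * mu >= 1) {
    abort("unstable GVF step: need dt * 4 * mu < 1.",
          class = "snakeseg_param_error")
  }
  structure(list(mu = mu, iters = as.integer(iters), dt = dt),
            class = "gvf_params")
}

#' Edge map for GVF
#'
#' `f(x, y) = |grad(G_sigma * A)|^2`, rescaled to a maximum of 1 when
#' nonzero. This non-negative map is the "edge likelihood" whose gradient
#' seeds the GVF diffusion.
#'
#' @param img A [gray_image()].
#' @param sigma Gaussian pre-smoothing in pixels (`>= 0`).
#' @return An energy map (kind `"edge"`), values in `[0, 1]`.
#' @export
edge_map <- function(img, sigma = 1) {
  sm <- gaussian_smooth(img, sigma, clip = FALSE)
  g <- image_gradient(sm)
  f <- g$u^2 + g$v^2
  mx <- max(f)
  if (mx > 0) f <- f / mx
  new_energy_map(f, "edge")
}

# 5-point Laplacian with reflective borders (border neighbor = the border
# pixel itself, i.e. zero-flux).
laplacian5 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up    <- m[c(1L, 1:(h - 1L)), , drop = FALSE]
  down  <- m[c(2:h, h), , drop = FALSE]
  left  <- m[, c(1L, 1:(w - 1L)), drop = FALSE]
  right <- m[, c(2:w, w), drop = FALSE]
  up + down + left + right - 4 * m
}

#' Compute the gradient vector flow field
#'
#' Minimizes the GVF energy — a trade-off between field smoothness
#' (weight `mu`) and fidelity to the edge-map gradient where that gradient
#' is strong — by explicit diffusion iterations
#' `u <- u + dt * (mu * lap(u) - (u - f_x) * (f_x^2 + f_y^2))` (and likewise
#' for `v`), initialized at `grad f`. With `iters = 0` the returned field is
#' exactly `grad f`.
#'
#' @param f Edge map from [edge_map()] (non-negative matrix).
#' @param params A [gvf_params()].
#' @return A [vector_field()].
#' @export
compute_gvf <- function(f, params = gvf_params()) {
  f <- as_plain_matrix(f)
  if (any(!is.finite(f)) || min(f) < 0) {
    abort("edge map must be finite and non-negative.",
          class = "snakeseg_input_error")
  }
  g <- image_gradient(f)
  fx <- g$u; fy <- g$v
  b <- fx^2 + fy^2
  u <- fx; v <- fy
  for (it in seq_len(params$iters)) {
    u <- u + params$dt * (params$mu * laplacian5(u) - (u - fx) * b)
    v <- v + params$dt * (params$mu * laplacian5(v) - (v - fy) * b)
    if (!all(is.finite(u)) || !all(is.finite(v))) {
      abort(sprintf("GVF diffusion diverged at iteration %d.", it),
            class = "snakeseg_numeric_error")
    }
  }
  vector_field(u, v)
}

#' Normalize a vector field to (at most) unit magnitude
#'
#' With `soft = 0`, divides each vector by its norm (vectors shorter than
#' `eps` are left at zero), giving a unit-magnitude field. With `soft > 0`,
#' applies the soft normalization `B / (|B| + soft)`: vectors much longer
#' than `soft` become unit, while vectors much shorter — numerically
#' meaningless directions deep in homogeneous regions — shrink toward zero
#' instead of being amplified to full speed. A normalized GVF field acts
#' like a spatially informed balloon force: direction from the diffused
#' edge information, bounded speed.
#'
#' @param field A [vector_field()].
#' @param eps Magnitude below which a vector is treated as zero (hard
#'   normalization only).
#' @param soft Soft-normalization knee magnitude (`>= 0`).
#' @return A [vector_field()].
#' @export
normalize_field <- function(field, eps = 1e-12, soft = 0) {
  mag <- sqrt(field$u^2 + field$v^2)
  scale <- if (soft > 0) 1 / (mag + soft) else ifelse(mag > eps, 1 / mag, 0)
  vector_field(field$u * scale, field$v * scale)
}

#' Sample a vector field at continuous points
#'
#' Independent bilinear interpolation of `u` and `v`. Points must lie inside
#' the field domain `[0, w-1] x [0, h-1]`.
#'
#' @param field A [vector_field()].
#' @param x,y Numeric vectors of coordinates (x = column, y = row, 0-based).
#' @return A tibble with columns `fx`, `fy`.
#' @export
sample_field <- function(field, x, y) {
  s <- .sample_field(field, x, y)
  tibble(fx = s[, 1], fy = s[, 2])
}

# Matrix-core bilinear sampler (hot path); returns an n x 2 matrix.
.sample_field <- function(field, x, y) {
  h <- nrow(field$u); w <- ncol(field$u)
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(x < 0 | x > w - 1 | y < 0 | y > h - 1)) {
    abort("sample point outside the field domain.",
          class = "snakeseg_domain_error")
  }
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  tx <- x - x0; ty <- y - y0
  i <- y0 + 1; j <- x0 + 1   # 1-based matrix indices
  i00 <- i + (j - 1) * h
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  bl <- function(m) {
    m[i00] * w00 + m[i00 + h] * w10 + m[i00 + 1] * w01 + m[i00 + h + 1] * w11
  }
  cbind(bl(field$u), bl(field$v))
}
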