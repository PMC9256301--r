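# Prior-knowledge external force: a centroid-distance-weighted combination
# of the GVF field and the outward contour normal. The reciprocal-distance
# weight damps the force as the contour grows, and the normal (balloon)
# term keeps the contour moving where diffused edge information is weak.

#' Prior-knowledge external force
#'
#' Per contour point `i`, with `C` the contour centroid and
#' `d_i = max(|p_i - C|, dist_clamp)`:
#' `F_i = (1 / d_i) * (k1 * B(p_i) + k2 * N_i)`,
#' where `B` is the external vector field (typically GVF) sampled
#' bilinearly at the point and `N_i` is the outward unit normal. The clamp
#' keeps the weight finite for points near the centroid.
#'
#' @param c A `snake_contour`; all points must lie inside the field domain.
#' @param field A [vector_field()] covering the contour.
#' @param k1 Coefficient on the field term.
#' @param k2 Coefficient on the normal term (negative deflates).
#' @param dist_clamp Minimum centroid distance in pixels (`> 0`).
#' @param center Optional fixed `(x, y)` center; by default the centroid of
#'   the current contour is used (the prior tracks the evolving contour).
#' @return A tibble with columns `fx`, `fy`, one row per point.
#' @export
prior_external_force <- function(c, field, k1 = 20, k2 = 7,
                                 dist_clamp = 1, center = NULL) {
  c <- as_contour(c)
  if (!is.finite(k1) || !is.finite(k2)) {
    abort("`k1` and `k2` must be finite.", class = "snakeseg_param_error")
  }
  if (dist_clamp <= 0) {
    abort("`dist_clamp` must be > 0.", class = "snakeseg_param_error")
  }
  f <- .prior_force(contour_matrix(c), field, k1, k2, dist_clamp, center)
  tibble(fx = f[, 1], fy = f[, 2])
}

# Matrix-core prior force (hot path); p is an n x 2 point matrix.
.prior_force <- function(p, field, k1, k2, dist_clamp, center = NULL) {
  ctr <- if (is.null(center)) colMeans(p) else center
  d <- pmax(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2), dist_clamp)
  b <- .sample_field(field, p[, 1], p[, 2])
  nrm <- .normals(p)
  cbind((k1 * b[, 1] + k2 * nrm[, 1]) / d,
        (k1 * b[, 2] + k2 * nrm[, 2]) / d)
}

#' Blend two per-point force sets
#'
#' `weight * prior + (1 - weight) * classic`, letting users interpolate
#' between the prior-guided and a plain force model.
#'
#' @param prior,classic Tibbles with columns `fx`, `fy` of equal length.
#' @param weight Blend weight in `[0, 1]`.
#' @return A tibble with columns `fx`, `fy`.
#' @export
blend_forces <- function(prior, classic, weight) {
  if (nrow(prior) != nrow(classic)) {
    abort("force sets must have equal lengths.",
          class = "snakeseg_input_error")
  }
  if (!is.numeric(weight) || weight < 0 || weight > 1) {
    abort("`weight` must lie in [0, 1].", class = "snakeseg_param_error")
  }
  tibble(fx = weight * prior$fx + (1 - weight) * classic$fx,
         fy = weight * prior$fy + (1 - weight) * classic$fy)
}
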