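# Snake evolution: the discrete contour L(s) moves under internal
# elasticity/rigidity forces and an image-derived external force until the
# mean point displacement falls below tolerance.

#' Snake evolution parameters
#'
#' All coefficients governing contour evolution. Defaults are tuned for
#' 128 x 128 phantoms with structures a few tens of pixels across; the
#' reciprocal centroid-distance weight of the prior force divides by a
#' length of that order, which is why `k1` and `k2` are of order the
#' structure radius rather than of order 1.
#'
#' @param alpha Elasticity weight (`>= 0`); penalizes contour stretching.
#' @param beta Rigidity weight (`>= 0`); penalizes bending.
#' @param tau Explicit-Euler time step (`> 0`). Stability is the caller's
#'   responsibility; the evolution aborts if coordinates become non-finite.
#' @param k1 Prior-force coefficient on the GVF term.
#' @param k2 Prior-force coefficient on the outward-normal (balloon) term;
#'   negative values deflate instead of inflate.
#' @param w_line,w_edge,w_term External-energy weights for the classic
#'   force model.
#' @param sigma Gaussian smoothing (pixels) used when building energy and
#'   edge maps.
#' @param dist_clamp Minimum centroid distance (pixels) in the prior
#'   force's `1 / |L - C|` weight (`> 0`).
#' @param max_iter Iteration cap (`>= 0`).
#' @param tol Stop when the mean per-point displacement (pixels) of an
#'   iteration falls below this.
#' @param resample_every Iterations between arc-length resampling passes;
#'   `0` disables resampling.
#' @param spacing Target point spacing (pixels) for resampling.
#' @param smooth Laplacian point-smoothing factor in `[0, 1]` applied at
#'   each resampling pass (`p_i <- p_i + smooth * ((p_{i-1} + p_{i+1}) / 2 -
#'   p_i)`); damps the sawtooth oscillation an explicit scheme develops
#'   where opposing forces meet at a boundary.
#' @param unit_gvf Soft-normalize the GVF field (see [normalize_field()])
#'   before use as a snake force: unit speed near edges, vanishing where
#'   the diffused field is numerically negligible. Applies to the `gvf`
#'   and `prior_gvf` force models.
#' @param gvf_soft Knee magnitude of the soft normalization.
#' @param fixed_center Use the initial contour's centroid as the prior
#'   force's center `C` for the whole run (a true fixed prior) instead of
#'   tracking the evolving contour's centroid.
#' @param track_energy Record the total snake energy per iteration.
#' @return A `snake_params` list.
#' @export
snake_params <- function(alpha = 0.2, beta = 0.01, tau = 0.25,
                         k1 = 10, k2 = 3,
                         w_line = 0, w_edge = 1, w_term = 0,
                         sigma = 1, dist_clamp = 1,
                         max_iter = 3000L, tol = 1e-3,
                         resample_every = 5L, spacing = 1.5, smooth = 0.3,
                         unit_gvf = TRUE, gvf_soft = 0.01,
                         fixed_center = FALSE, track_energy = FALSE) {
  p <- list(alpha = alpha, beta = beta, tau = tau, k1 = k1, k2 = k2,
            w_line = w_line, w_edge = w_edge, w_term = w_term,
            sigma = sigma, dist_clamp = dist_clamp,
            max_iter = as.integer(max_iter), tol = tol,
            resample_every = as.integer(resample_every), spacing = spacing,
            smooth = smooth,
            unit_gvf = isTRUE(unit_gvf), gvf_soft = gvf_soft,
            fixed_center = isTRUE(fixed_center),
            track_energy = isTRUE(track_energy))
  if (p$alpha < 0 || p$beta < 0) {
    abort("`alpha` and `beta` must be >= 0.", class = "snakeseg_param_error")
  }
  if (p$tau <= 0) abort("`tau` must be > 0.", class = "snakeseg_param_error")
  if (p$dist_clamp <= 0) {
    abort("`dist_clamp` must be > 0.", class = "snakeseg_param_error")
  }
  if (p$max_iter < 0) abort("`max_iter` must be >= 0.",
                            class = "snakeseg_param_error")
  if (p$tol < 0) abort("`tol` must be >= 0.", class = "snakeseg_param_error")
  if (p$spacing <= 0) abort("`spacing` must be > 0.",
                            class = "snakeseg_param_error")
  if (p$smooth < 0 || p$smooth > 1) {
    abort("`smooth` must lie in [0, 1].", class = "snakeseg_param_error")
  }
  structure(p, class = "snake_params")
}

# Cyclic index shifts for periodic finite differences.
cyc <- function(n, k) ((seq_len(n) - 1L + k) %% n) + 1L

#' Internal snake force
#'
#' Per-point `alpha * L'' - beta * L''''` with periodic (cyclic) second and
#' fourth central differences at unit index spacing. Elasticity contracts
#' the contour; rigidity straightens it.
#'
#' @param c A `snake_contour`.
#' @param alpha,beta Elasticity and rigidity weights.
#' @return A tibble with columns `fx`, `fy` (one row per contour point).
#' @export
internal_force <- function(c, alpha, beta) {
  c <- as_contour(c)
  f <- .internal_force(contour_matrix(c), alpha, beta)
  tibble(fx = f[, 1], fy = f[, 2])
}

# Matrix-core internal force (hot path).
.internal_force <- function(p, alpha, beta) {
  n <- nrow(p)
  d2 <- p[cyc(n, -1L), ] - 2 * p + p[cyc(n, 1L), ]
  d4 <- p[cyc(n, -2L), ] - 4 * p[cyc(n, -1L), ] + 6 * p -
    4 * p[cyc(n, 1L), ] + p[cyc(n, 2L), ]
  alpha * d2 - beta * d4
}

#' One explicit evolution step
#'
#' `point_i <- point_i + tau * (internal_force_i + external_force_i)`,
#' with points clamped to `[0, w-1] x [0, h-1]` when `domain` is given.
#'
#' @param c A `snake_contour`.
#' @param external_force Tibble (or data frame) with columns `fx`, `fy`,
#'   one row per contour point.
#' @param params A [snake_params()].
#' @param domain Optional `c(h, w)` image shape for clamping.
#' @return The updated `snake_contour`.
#' @export
evolve_step <- function(c, external_force, params = snake_params(),
                        domain = NULL) {
  c <- as_contour(c)
  n <- nrow(c)
  if (nrow(external_force) != n) {
    abort("external force must have one vector per contour point.",
          class = "snakeseg_input_error")
  }
  fi <- internal_force(c, params$alpha, params$beta)
  fx <- fi$fx + external_force$fx
  fy <- fi$fy + external_force$fy
  bad <- which(!is.finite(fx) | !is.finite(fy))
  if (length(bad)) {
    abort(sprintf("non-finite force at contour point %d.", bad[1]),
          class = "snakeseg_numeric_error")
  }
  x <- c$x + params$tau * fx
  y <- c$y + params$tau * fy
  if (!is.null(domain)) {
    x <- pmin(pmax(x, 0), domain[2] - 1)
    y <- pmin(pmax(y, 0), domain[1] - 1)
  }
  as_contour(tibble(x = x, y = y))
}

# Total snake energy (internal quadratic terms plus external energy sampled
# at the points), used for the optional energy trace.
snake_energy <- function(c, emap, params) {
  p <- contour_matrix(c)
  n <- nrow(p)
  d1 <- (p[cyc(n, 1L), ] - p[cyc(n, -1L), ]) / 2
  d2 <- p[cyc(n, -1L), ] - 2 * p + p[cyc(n, 1L), ]
  eint <- 0.5 * sum(params$alpha * rowSums(d1^2) +
                    params$beta * rowSums(d2^2))
  f <- vector_field(as_plain_matrix(emap), as_plain_matrix(emap))
  eext <- sum(sample_field(f, pmin(pmax(p[, 1], 0), ncol(emap) - 1),
                           pmin(pmax(p[, 2], 0), nrow(emap) - 1))$fx)
  eint + eext
}

# Build the per-iteration external force closure for a force model.
# Returns function(contour) -> tibble(fx, fy).
make_force_fn <- function(img, params, force_model,
                          gvf = gvf_params(), field = NULL,
                          init_center = NULL) {
  m <- as_plain_matrix(img)
  h <- nrow(m); w <- ncol(m)
  clamp_xy <- function(p) {
    cbind(pmin(pmax(p[, 1], 0), w - 1), pmin(pmax(p[, 2], 0), h - 1))
  }
  if (force_model == "classic") {
    emap <- combine_external_energy(
      line_energy(gray_image(m)),
      edge_energy(gray_image(m), params$sigma),
      termination_energy(gray_image(m), max(params$sigma, 0.5)),
      params$w_line, params$w_edge, params$w_term)
    g <- image_gradient(emap)
    ffield <- vector_field(-g$u, -g$v)   # descend the energy
    attr_field <- ffield
    fn <- function(p) {
      q <- clamp_xy(p)
      .sample_field(ffield, q[, 1], q[, 2])
    }
  } else {
    if (is.null(field)) {
      f <- edge_map(gray_image(m), params$sigma)
      field <- compute_gvf(f, gvf)
    }
    if (params$unit_gvf) field <- normalize_field(field, soft = params$gvf_soft)
    attr_field <- field
    if (force_model == "gvf") {
      fn <- function(p) {
        q <- clamp_xy(p)
        .sample_field(field, q[, 1], q[, 2])
      }
    } else if (force_model == "prior_gvf") {
      ctr <- if (params$fixed_center) init_center else NULL
      fn <- function(p) {
        .prior_force(p, field, k1 = params$k1, k2 = params$k2,
                     dist_clamp = params$dist_clamp, center = ctr)
      }
    } else {
      abort(sprintf("unknown force model '%s'.", force_model),
            class = "snakeseg_param_error")
    }
  }
  attr(fn, "field") <- attr_field
  fn
}

#' Run a snake to convergence
#'
#' Iterates [evolve_step()] with the selected external force model until the
#' mean per-point displacement drops below `params$tol` or `params$max_iter`
#' iterations have run, resampling the contour by arc length every
#' `params$resample_every` iterations.
#'
#' Force models:
#' \describe{
#'   \item{`classic`}{minus the gradient of the combined external energy,
#'     sampled bilinearly at the contour points. Capture range is limited to
#'     the immediate neighborhood of edges.}
#'   \item{`gvf`}{the gradient vector flow field sampled at the points;
#'     edge information diffused across the image reaches into concavities.}
#'   \item{`prior_gvf`}{the prior-knowledge force: per point,
#'     `(1 / max(|L - C|, dist_clamp)) * (k1 * B + k2 * N)` with `B` the GVF
#'     field, `N` the outward unit normal and `C` the current contour
#'     centroid.}
#' }
#'
#' @param img A [gray_image()].
#' @param init Initial `snake_contour`, inside the image domain.
#' @param params A [snake_params()].
#' @param force_model One of `"classic"`, `"gvf"`, `"prior_gvf"`.
#' @param gvf A [gvf_params()] used when the force model needs a GVF field.
#' @param field Optional precomputed [vector_field()] (e.g. a cached GVF
#'   field); skips the internal GVF computation.
#' @return A `snake_fit` object: list with `final_contour`, `iterations_run`,
#'   `converged`, `displacement_trace`, `energy_trace` (if tracked),
#'   `force_model`, `params`, and the input `img`.
#' @export
run_snake <- function(img, init, params = snake_params(),
                      force_model = c("prior_gvf", "gvf", "classic"),
                      gvf = gvf_params(), field = NULL) {
  force_model <- match.arg(force_model)
  m <- as_plain_matrix(gray_image(as_plain_matrix(img)))
  h <- nrow(m); w <- ncol(m)
  c <- as_contour(init)
  if (any(c$x < 0 | c$x > w - 1 | c$y < 0 | c$y > h - 1)) {
    abort("initial contour lies outside the image domain.",
          class = "snakeseg_input_error")
  }
  force_fn <- make_force_fn(m, params, force_model, gvf, field,
                            init_center = contour_centroid(c))
  emap <- if (params$track_energy) {
    combine_external_energy(line_energy(gray_image(m)),
                            edge_energy(gray_image(m), params$sigma),
                            termination_energy(gray_image(m),
                                               max(params$sigma, 0.5)),
                            params$w_line, params$w_edge, params$w_term)
  } else NULL
  disp <- numeric(0)
  energy <- numeric(0)
  converged <- FALSE
  iters <- 0L
  p <- contour_matrix(c)
  while (iters < params$max_iter) {
    fext <- force_fn(p)
    fint <- .internal_force(p, params$alpha, params$beta)
    ftot <- fint + fext
    bad <- which(!is.finite(ftot[, 1]) | !is.finite(ftot[, 2]))
    if (length(bad)) {
      abort(sprintf("non-finite force at contour point %d.", bad[1]),
            class = "snakeseg_numeric_error")
    }
    p_new <- p + params$tau * ftot
    p_new[, 1] <- pmin(pmax(p_new[, 1], 0), w - 1)
    p_new[, 2] <- pmin(pmax(p_new[, 2], 0), h - 1)
    iters <- iters + 1L
    # displacement measured before any resampling reshuffles the points
    d <- mean(sqrt(rowSums((p_new - p)^2)))
    disp[iters] <- d
    p <- p_new
    if (params$resample_every > 0L && iters %% params$resample_every == 0L) {
      per <- .perimeter(p)
      if (per > 6 * (h + w)) {
        abort(sprintf(
          "contour diverged at iteration %d (perimeter %.0f px).", iters, per),
          class = "snakeseg_numeric_error")
      }
      if (params$spacing <= per / 4) {
        p <- .resample(p, params$spacing)
        if (params$smooth > 0) {
          n_p <- nrow(p)
          nb <- (p[cyc(n_p, -1L), ] + p[cyc(n_p, 1L), ]) / 2
          p <- p + params$smooth * (nb - p)
        }
      }
    }
    if (params$track_energy) {
      energy[iters] <- snake_energy(matrix_contour(p), emap, params)
    }
    if (d < params$tol) {
      converged <- TRUE
      break
    }
  }
  c <- matrix_contour(p)
  structure(list(final_contour = c,
                 iterations_run = iters,
                 converged = converged,
                 displacement_trace = disp,
                 energy_trace = if (params$track_energy) energy else NULL,
                 force_model = force_model,
                 params = params,
                 img = gray_image(m)),
            class = "snake_fit")
}

#' @export
print.snake_fit <- function(x, ...) {
  cat(sprintf(
    "<snake_fit> %s: %d points, %d iterations, %s (final displacement %.4g px)\n",
    x$force_model, nrow(x$final_contour), x$iterations_run,
    if (x$converged) "converged" else "iteration cap reached",
    if (x$iterations_run > 0) x$displacement_trace[x$iterations_run] else NA))
  invisible(x)
}

#' Tidy a snake fit: the final contour points
#'
#' @param x A `snake_fit`.
#' @param ... Unused.
#' @return A tibble with columns `point`, `x`, `y`.
#' @method tidy snake_fit
#' @export
tidy.snake_fit <- function(x, ...) {
  fc <- x$final_contour
  tibble(point = seq_len(nrow(fc)), x = fc$x, y = fc$y)
}

#' One-row summary of a snake fit
#'
#' @param x A `snake_fit`.
#' @param truth Optional ground-truth `BinaryMask`; adds a `dice` column.
#' @param ... Unused.
#' @return A one-row tibble: `force_model`, `n_points`, `iterations`,
#'   `converged`, `final_displacement`, and `dice` when truth is given.
#' @method glance snake_fit
#' @export
glance.snake_fit <- function(x, truth = NULL, ...) {
  out <- tibble(
    force_model = x$force_model,
    n_points = nrow(x$final_contour),
    iterations = x$iterations_run,
    converged = x$converged,
    final_displacement = if (x$iterations_run > 0)
      x$displacement_trace[x$iterations_run] else NA_real_)
  if (!is.null(truth)) {
    mask <- contour_to_mask(x$final_contour, dim(truth), check = FALSE)
    out$dice <- dice(mask, truth)
  }
  out
}

#' Plot a snake fit over its image
#'
#' @param object A `snake_fit`.
#' @param init Optional initial contour to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snake_fit
#' @export
autoplot.snake_fit <- function(object, init = NULL, ...) {
  m <- as_plain_matrix(object$img)
  df <- tibble(x = rep(0:(ncol(m) - 1), each = nrow(m)),
               y = rep(0:(nrow(m) - 1), times = ncol(m)),
               value = as.vector(m))
  cc <- object$final_contour
  closed <- tibble(x = c(cc$x, cc$x[1]), y = c(cc$y, cc$y[1]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::geom_path(data = closed, color = "red", linewidth = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("snake (%s), %d iterations",
                                  object$force_model,
                                  object$iterations_run),
                  fill = "intensity")
  if (!is.null(init)) {
    init <- as_contour(init)
    ci <- tibble(x = c(init$x, init$x[1]), y = c(init$y, init$y[1]))
    p <- p + ggplot2::geom_path(data = ci, color = "cyan",
                                linetype = "dashed", linewidth = 0.5)
  }
  p
}
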