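# Synthetic phantoms with analytic ground truth. Each phantom emulates a
# condition a snake meets on spinal MRI slices: a smooth convex body, a
# concave ("sag") boundary, a bumpy noisy boundary, or a nearby distractor
# structure with a stronger edge. Ground truth comes from the analytic
# shape via the same pixel-center rule the evaluator uses, so truth is
# exact and noise-independent.

phantom_geometry_defaults <- function(kind, h, w) {
  s <- min(h, w) / 128
  switch(kind,
    disk = list(radius = 30 * s),
    u_shape = list(half_width = 34 * s, half_height = 34 * s,
                   notch_half_width = 10 * s, notch_depth = 44 * s),
    vertebra = list(a = 34 * s, b = 22 * s, power = 4,
                    perturb_amp = 0.06, perturb_freq = 7,
                    perturb_phase = 0.7),
    two_vertebra = list(a = 30 * s, b = 18 * s, offset = 14.5 * s,
                        distractor_a = 30 * s, distractor_b = 16 * s,
                        distractor_offset = -25.5 * s, distractor_fg = 0.95,
                        power = 4),
    abort(sprintf("unknown phantom kind '%s'.", kind),
          class = "snakeseg_spec_error"))
}

#' Phantom specification
#'
#' @param kind One of `"disk"`, `"u_shape"`, `"vertebra"`,
#'   `"two_vertebra"`.
#' @param image_size `c(h, w)` in pixels.
#' @param fg,bg Foreground / background intensity in `[0, 1]`. For
#'   `two_vertebra` the foreground is deliberately low-contrast while the
#'   distractor body (geometry `distractor_fg`) has a strong edge.
#' @param noise_sigma Additive Gaussian noise standard deviation (`>= 0`).
#' @param blur_sigma Gaussian blur in pixels applied to the clean intensity
#'   map (`>= 0`).
#' @param seed Random seed driving the noise realization.
#' @param geometry Named list overriding the kind's geometry defaults
#'   (see `snakeseg:::phantom_geometry_defaults`); lengths scale with image
#'   size.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(kind, image_size = c(128L, 128L),
                         fg = 0.9, bg = 0.1,
                         noise_sigma = 0, blur_sigma = 0, seed = 1L,
                         geometry = list()) {
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  if (any(c(fg, bg) < 0) || any(c(fg, bg) > 1)) {
    abort("intensities must lie in [0, 1].", class = "snakeseg_spec_error")
  }
  if (noise_sigma < 0 || blur_sigma < 0) {
    abort("noise_sigma and blur_sigma must be >= 0.",
          class = "snakeseg_spec_error")
  }
  geo <- utils::modifyList(phantom_geometry_defaults(kind, h, w), geometry)
  structure(list(kind = kind, image_size = c(h, w), fg = fg, bg = bg,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = as.integer(seed), geometry = geo),
            class = "phantom_spec")
}

# Evaluate RNG-dependent code under a seed, restoring the caller's RNG
# state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Pixel-center membership grids (h x w logical) for each analytic shape.
phantom_membership <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  X <- matrix(rep(0:(w - 1L), each = h), h, w)
  Y <- matrix(rep(0:(h - 1L), times = w), h, w)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  g <- spec$geometry
  superellipse <- function(dx, dy, a, b, p, amp = 0, freq = 0, phase = 0) {
    r <- (abs(dx / a)^p + abs(dy / b)^p)^(1 / p)
    lim <- 1 + if (amp > 0) amp * sin(freq * atan2(dy, dx) + phase) else 0
    r <= lim
  }
  switch(spec$kind,
    disk = {
      member <- (X - cx)^2 + (Y - cy)^2 <= g$radius^2
      list(truth = member, target = member)
    },
    u_shape = {
      dx <- X - cx; dy <- Y - cy
      body <- abs(dx) <= g$half_width & abs(dy) <= g$half_height
      notch <- abs(dx) < g$notch_half_width &
        dy > g$half_height - g$notch_depth
      member <- body & !notch
      list(truth = member, target = member)
    },
    vertebra = {
      member <- superellipse(X - cx, Y - cy, g$a, g$b, g$power,
                             g$perturb_amp, g$perturb_freq, g$perturb_phase)
      list(truth = member, target = member)
    },
    two_vertebra = {
      main <- superellipse(X - cx, Y - (cy + g$offset), g$a, g$b, g$power)
      distractor <- superellipse(X - cx, Y - (cy + g$distractor_offset),
                                 g$distractor_a, g$distractor_b, g$power)
      list(truth = main | distractor, target = main, distractor = distractor)
    })
}

phantom_init_contour <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  s <- min(h, w) / 128
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  g <- spec$geometry
  ctr_r <- switch(spec$kind,
    disk = list(c(cx, cy), g$radius * 0.5),
    u_shape = list(c(cx, cy - 22 * s), 8 * s),
    vertebra = list(c(cx, cy), 10 * s),
    two_vertebra = list(c(cx, cy + g$offset), 9 * s))
  n <- max(16L, as.integer(round(2 * pi * ctr_r[[2]] / 1.5)))
  make_circle_contour(ctr_r[[1]], ctr_r[[2]], n)
}

#' Generate a phantom
#'
#' Rasterizes the analytic shape to an exact ground-truth mask, then builds
#' the image as `clip(blur(intensity map) + noise)`. Identical spec and
#' seed give bit-identical output; the truth mask never depends on seed,
#' noise or blur.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` list: `image` ([gray_image()]), `truth` and `target`
#'   ([binary_mask()]s; `target` is the structure the suggested init sits
#'   in — for single-structure phantoms it equals `truth`), `structure_id`,
#'   `suggested_init` (a circle strictly inside the target), and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  mem <- phantom_membership(spec)
  truth <- mem$truth
  if (!any(truth)) abort("phantom geometry produced an empty truth mask.",
                         class = "snakeseg_spec_error")
  border <- truth
  border[6:(h - 5L), 6:(w - 5L)] <- FALSE
  if (any(border)) {
    abort("phantom geometry violates the 5-pixel image margin.",
          class = "snakeseg_spec_error")
  }
  intensity <- matrix(spec$bg, h, w)
  intensity[truth] <- spec$fg
  if (spec$kind == "two_vertebra") {
    intensity[mem$distractor] <- spec$geometry$distractor_fg
  }
  img <- if (spec$blur_sigma > 0) {
    gaussian_smooth(intensity, spec$blur_sigma, clip = FALSE)
  } else intensity
  if (spec$noise_sigma > 0) {
    noise <- with_local_seed(spec$seed,
      matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w))
    img <- img + noise
  }
  img <- gray_image(pmin(pmax(img, 0), 1))
  init <- phantom_init_contour(spec)
  init_mask <- contour_to_mask(init, c(h, w))
  if (any(init_mask & !mem$target)) {
    abort("suggested init is not strictly inside the target structure.",
          class = "snakeseg_spec_error")
  }
  structure(list(image = img,
                 truth = binary_mask(truth),
                 target = binary_mask(mem$target),
                 structure_id = 1L,
                 suggested_init = init,
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom:%s> %d x %d, fg %.2f / bg %.2f, noise %.3f, blur %.1f, %d truth px\n",
    x$spec$kind, x$spec$image_size[1], x$spec$image_size[2], x$spec$fg,
    x$spec$bg, x$spec$noise_sigma, x$spec$blur_sigma, sum(x$truth)))
  invisible(x)
}

#' The standard phantom battery
#'
#' A fixed four-phantom suite covering the behaviors a snake must handle:
#' a noiseless disk (baseline convergence), a noiseless blurred U-shape
#' (concave boundary), a noisy perturbed vertebral body (bumpy boundary
#' under noise), and a low-contrast body next to a strong-edged distractor
#' (boundary leaking). Geometry is seed-independent; only the noise
#' realizations follow the seed.
#'
#' @param seed Integer seed; phantom `i` uses `seed + i`.
#' @param image_size `c(h, w)`, default 128 x 128.
#' @return Named list of 4 phantoms
#'   (`disk`, `u_shape`, `vertebra`, `two_vertebra`).
#' @export
phantom_suite <- function(seed = 1L, image_size = c(128L, 128L)) {
  base <- as.integer(seed) %% 1000000000L
  specs <- list(
    disk = phantom_spec("disk", image_size, fg = 0.9, bg = 0.1,
                        noise_sigma = 0, blur_sigma = 0, seed = base + 1L),
    u_shape = phantom_spec("u_shape", image_size, fg = 0.9, bg = 0.1,
                           noise_sigma = 0, blur_sigma = 1,
                           seed = base + 2L),
    vertebra = phantom_spec("vertebra", image_size, fg = 0.9, bg = 0.1,
                            noise_sigma = 0.12, blur_sigma = 1,
                            seed = base + 3L),
    two_vertebra = phantom_spec("two_vertebra", image_size,
                                fg = 0.55, bg = 0.1,
                                noise_sigma = 0.05, blur_sigma = 1,
                                seed = base + 4L))
  lapply(specs, generate_phantom)
}
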