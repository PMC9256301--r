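# Independent loop-based oracles. These deliberately avoid the package's
# vectorized code paths: plain per-pixel / per-point loops implementing the
# defining formulas directly.

# Finite-difference gradient: central in the interior, one-sided at borders.
oracle_gradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  u <- matrix(0, h, w); v <- matrix(0, h, w)
  for (r in 1:h) for (cl in 1:w) {
    u[r, cl] <- if (cl == 1) m[r, 2] - m[r, 1]
      else if (cl == w) m[r, w] - m[r, w - 1]
      else (m[r, cl + 1] - m[r, cl - 1]) / 2
    v[r, cl] <- if (r == 1) m[2, cl] - m[1, cl]
      else if (r == h) m[h, cl] - m[h - 1, cl]
      else (m[r + 1, cl] - m[r - 1, cl]) / 2
  }
  list(u = u, v = v)
}

# Direct kernel-sum Gaussian convolution at a single pixel (r, cl),
# reflective (half-sample symmetric) borders.
oracle_gauss_at <- function(m, sigma, r, cl) {
  rad <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  acc <- 0
  for (dy in -rad:rad) for (dx in -rad:rad) {
    acc <- acc + k[dy + rad + 1] * k[dx + rad + 1] *
      m[refl(r + dy, nrow(m)), refl(cl + dx, ncol(m))]
  }
  acc
}

# Even-odd point-in-polygon by ray casting, one point at a time.
oracle_point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in 1:n) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_mask <- function(xs, ys, h, w) {
  m <- matrix(FALSE, h, w)
  for (r in 1:h) for (cl in 1:w) {
    m[r, cl] <- oracle_point_in_polygon(cl - 1, r - 1, xs, ys)
  }
  m
}

# Dice by explicit pixel iteration with integer counters.
oracle_dice <- function(a, b) {
  inter <- 0L; na <- 0L; nb <- 0L
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1L
    if (b[i]) nb <- nb + 1L
    if (a[i] && b[i]) inter <- inter + 1L
  }
  2 * inter / (na + nb)
}

# Cyclic second/fourth differences for the internal force, per point.
oracle_internal_force <- function(xs, ys, alpha, beta) {
  n <- length(xs)
  w <- function(i) ((i - 1) %% n) + 1
  fx <- numeric(n); fy <- numeric(n)
  for (i in 1:n) {
    d2x <- xs[w(i - 1)] - 2 * xs[i] + xs[w(i + 1)]
    d2y <- ys[w(i - 1)] - 2 * ys[i] + ys[w(i + 1)]
    d4x <- xs[w(i - 2)] - 4 * xs[w(i - 1)] + 6 * xs[i] -
      4 * xs[w(i + 1)] + xs[w(i + 2)]
    d4y <- ys[w(i - 2)] - 4 * ys[w(i - 1)] + 6 * ys[i] -
      4 * ys[w(i + 1)] + ys[w(i + 2)]
    fx[i] <- alpha * d2x - beta * d4x
    fy[i] <- alpha * d2y - beta * d4y
  }
  list(fx = fx, fy = fy)
}

# Bilinear interpolation at one point from the four surrounding pixels.
oracle_bilinear <- function(m, x, y) {
  x0 <- min(floor(x), ncol(m) - 2); y0 <- min(floor(y), nrow(m) - 2)
  tx <- x - x0; ty <- y - y0
  m[y0 + 1, x0 + 1] * (1 - tx) * (1 - ty) +
    m[y0 + 1, x0 + 2] * tx * (1 - ty) +
    m[y0 + 2, x0 + 1] * (1 - tx) * ty +
    m[y0 + 2, x0 + 2] * tx * ty
}

# Prior force at each point by direct substitution, loop form.
oracle_prior_force <- function(xs, ys, field, k1, k2, clamp) {
  n <- length(xs)
  cx <- mean(xs); cy <- mean(ys)
  # outward normals via tangent rotation + orientation sign
  area <- 0
  for (i in 1:n) {
    j <- (i %% n) + 1
    area <- area + xs[i] * ys[j] - xs[j] * ys[i]
  }
  s <- if (area >= 0) 1 else -1
  fx <- numeric(n); fy <- numeric(n)
  for (i in 1:n) {
    ip <- (i %% n) + 1; im <- ((i - 2) %% n) + 1
    tx <- (xs[ip] - xs[im]) / 2; ty <- (ys[ip] - ys[im]) / 2
    tl <- sqrt(tx^2 + ty^2)
    nx <- s * ty / tl; ny <- -s * tx / tl
    d <- max(sqrt((xs[i] - cx)^2 + (ys[i] - cy)^2), clamp)
    bx <- oracle_bilinear(field$u, xs[i], ys[i])
    by <- oracle_bilinear(field$v, xs[i], ys[i])
    fx[i] <- (k1 * bx + k2 * nx) / d
    fy[i] <- (k1 * by + k2 * ny) / d
  }
  list(fx = fx, fy = fy)
}

# Level-line curvature at interior pixels from finite differences of the
# (already smoothed) image.
oracle_curvature <- function(cs, eps_grad = 1e-8) {
  g <- oracle_gradient(cs)
  gx <- oracle_gradient(g$u)
  gy <- oracle_gradient(g$v)
  out <- matrix(0, nrow(cs), ncol(cs))
  for (i in seq_along(out)) {
    den2 <- g$u[i]^2 + g$v[i]^2
    if (den2 >= eps_grad) {
      out[i] <- (gy$v[i] * g$u[i]^2 - 2 * gx$v[i] * g$u[i] * g$v[i] +
                   gx$u[i] * g$v[i]^2) / den2^1.5
    }
  }
  out
}

random_gray <- function(h, w) {
  gray_image(matrix(runif(h * w), h, w))
}

random_mask <- function(h, w, p = 0.5) {
  binary_mask(matrix(runif(h * w) < p, h, w))
}

as_plain <- function(m) {
  attr(m, "kind") <- NULL
  class(m) <- c("matrix", "array")
  m
}
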