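test_that("internal force matches the cyclic-difference oracle", {
  circ <- make_circle_contour(c(0, 0), 9, 24)
  f0 <- internal_force(circ, 0, 0)
  expect_true(all(f0$fx == 0) && all(f0$fy == 0))
  # circle: forces radial inward with identical magnitude
  f <- internal_force(circ, 0.3, 0.02)
  mag <- sqrt(f$fx^2 + f$fy^2)
  expect_lt(diff(range(mag)), 1e-10)
  inward <- f$fx * circ$x + f$fy * circ$y
  expect_true(all(inward < 0))
  want <- oracle_internal_force(circ$x, circ$y, 0.3, 0.02)
  expect_equal(f$fx, want$fx, tolerance = 1e-10)
  expect_equal(f$fy, want$fy, tolerance = 1e-10)
  # straight evenly spaced run on a closed polygon: zero elasticity force
  # at interior points of the run
  xs <- c(0:6, 3); ys <- c(rep(0, 7), -4)
  frun <- internal_force(as_contour(tibble::tibble(x = xs, y = ys)), 0.5, 0)
  expect_equal(frun$fx[2:6], rep(0, 5), tolerance = 1e-12)
  expect_equal(frun$fy[2:6], rep(0, 5), tolerance = 1e-12)
  set.seed(13)
  rc <- as_contour(tibble::tibble(x = runif(11, 0, 10),
                                  y = runif(11, 0, 10)))
  got <- internal_force(rc, 0.7, 0.13)
  want <- oracle_internal_force(rc$x, rc$y, 0.7, 0.13)
  expect_equal(got$fx, want$fx, tolerance = 1e-10)
  expect_equal(got$fy, want$fy, tolerance = 1e-10)
})

test_that("internal force is equivariant under exact 90-degree rotation", {
  set.seed(17)
  c1 <- as_contour(tibble::tibble(x = runif(9, 0, 10), y = runif(9, 0, 10)))
  f1 <- internal_force(c1, 0.4, 0.05)
  c2 <- as_contour(tibble::tibble(x = -c1$y, y = c1$x))  # rotate +90 deg
  f2 <- internal_force(c2, 0.4, 0.05)
  expect_equal(f2$fx, -f1$fy, tolerance = 1e-12)
  expect_equal(f2$fy, f1$fx, tolerance = 1e-12)
})

test_that("evolve_step performs the explicit update and clamps to the domain", {
  sq <- as_contour(tibble::tibble(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2)))
  zero <- tibble::tibble(fx = rep(0, 4), fy = rep(0, 4))
  p0 <- snake_params(alpha = 0, beta = 0)
  same <- evolve_step(sq, zero, p0)
  expect_equal(same$x, sq$x)
  expect_equal(same$y, sq$y)
  # hand-checkable single step: alpha=0, so new = old + tau * F_ext
  fext <- tibble::tibble(fx = c(1, -2, 0.5, 0), fy = c(0, 1, -1, 2))
  p1 <- snake_params(alpha = 0, beta = 0, tau = 0.2)
  stepped <- evolve_step(sq, fext, p1)
  expect_equal(stepped$x, sq$x + 0.2 * fext$fx, tolerance = 1e-12)
  expect_equal(stepped$y, sq$y + 0.2 * fext$fy, tolerance = 1e-12)
  # with internal force included, matches the loop oracle arithmetic
  p2 <- snake_params(alpha = 0.3, beta = 0.1, tau = 0.5)
  stepped2 <- evolve_step(sq, fext, p2)
  fint <- oracle_internal_force(sq$x, sq$y, 0.3, 0.1)
  expect_equal(stepped2$x, sq$x + 0.5 * (fint$fx + fext$fx),
               tolerance = 1e-12)
  expect_equal(stepped2$y, sq$y + 0.5 * (fint$fy + fext$fy),
               tolerance = 1e-12)
  # clamping to an image domain
  cl <- evolve_step(as_contour(tibble::tibble(x = c(0, 4, 4, 0),
                                              y = c(0, 0, 4, 4))),
                    tibble::tibble(fx = c(-10, 10, 10, -10),
                                   fy = c(-10, -10, 10, 10)),
                    snake_params(alpha = 0, beta = 0, tau = 1),
                    domain = c(5, 5))
  expect_true(all(cl$x >= 0 & cl$x <= 4 & cl$y >= 0 & cl$y <= 4))
  expect_error(evolve_step(sq, tibble::tibble(fx = c(1, NaN, 0, 0),
                                              fy = rep(0, 4)), p1),
               class = "snakeseg_numeric_error")
  expect_error(evolve_step(sq, zero[1:3, ], p1),
               class = "snakeseg_input_error")
})

test_that("pure elasticity shrinks a circle concentrically, area non-increasing", {
  circ <- make_circle_contour(c(20, 20), 10, 40)
  params <- snake_params(alpha = 0.2, beta = 0, tau = 0.25)
  zero <- tibble::tibble(fx = rep(0, 40), fy = rep(0, 40))
  shoelace <- function(c) {
    n <- nrow(c); nxt <- c(2:n, 1)
    abs(sum(c$x * c$y[nxt] - c$x[nxt] * c$y) / 2)
  }
  one <- evolve_step(circ, zero, params)
  r1 <- sqrt((one$x - 20)^2 + (one$y - 20)^2)
  expect_lt(diff(range(r1)), 1e-10)          # still a circle
  expect_lt(max(r1), 10)                     # strictly smaller radius
  expect_equal(unname(contour_centroid(one)), c(20, 20), tolerance = 1e-9)
  areas <- numeric(101)
  c <- circ
  areas[1] <- shoelace(c)
  for (i in 1:100) {
    c <- evolve_step(c, zero, params)
    areas[i + 1] <- shoelace(c)
  }
  expect_true(all(diff(areas) <= 1e-12))
})

test_that("run_snake honors iteration and tolerance contracts", {
  ph <- generate_phantom(phantom_spec("disk"))
  p0 <- snake_params(max_iter = 0)
  fit0 <- run_snake(ph$image, ph$suggested_init, p0, "prior_gvf",
                    gvf = gvf_params(iters = 5))
  expect_equal(fit0$iterations_run, 0L)
  expect_false(fit0$converged)
  expect_length(fit0$displacement_trace, 0)
  expect_equal(fit0$final_contour$x, ph$suggested_init$x)
  expect_equal(fit0$final_contour$y, ph$suggested_init$y)
  pInf <- snake_params(max_iter = 50, tol = Inf)
  fitI <- run_snake(ph$image, ph$suggested_init, pInf, "prior_gvf",
                    gvf = gvf_params(iters = 5))
  expect_equal(fitI$iterations_run, 1L)
  expect_true(fitI$converged)
  pZ <- snake_params(max_iter = 7, tol = 0)
  fitZ <- run_snake(ph$image, ph$suggested_init, pZ, "prior_gvf",
                    gvf = gvf_params(iters = 5))
  expect_equal(fitZ$iterations_run, 7L)
  expect_false(fitZ$converged)
  expect_length(fitZ$displacement_trace, 7)
  expect_true(all(is.finite(fitZ$displacement_trace)))
  expect_true(all(fitZ$displacement_trace >= 0))
  out <- make_circle_contour(c(200, 200), 5, 16)
  expect_error(run_snake(ph$image, out, pZ, "gvf"),
               class = "snakeseg_input_error")
})

test_that("run_snake is deterministic: identical inputs, identical fits", {
  ph <- generate_phantom(phantom_spec("vertebra", noise_sigma = 0.1,
                                      blur_sigma = 1, seed = 42))
  p <- snake_params(max_iter = 120)
  g <- gvf_params(iters = 60)
  f1 <- run_snake(ph$image, ph$suggested_init, p, "prior_gvf", gvf = g)
  f2 <- run_snake(ph$image, ph$suggested_init, p, "prior_gvf", gvf = g)
  expect_identical(f1$final_contour, f2$final_contour)
  expect_identical(f1$displacement_trace, f2$displacement_trace)
  expect_identical(f1$iterations_run, f2$iterations_run)
})

test_that("snake_fit methods: tidy, glance, autoplot", {
  ph <- generate_phantom(phantom_spec("disk"))
  p <- snake_params(max_iter = 200)
  fit <- run_snake(ph$image, ph$suggested_init, p, "prior_gvf",
                   gvf = gvf_params(iters = 80))
  td <- tidy(fit)
  expect_true(tibble::is_tibble(td))
  expect_named(td, c("point", "x", "y"))
  expect_equal(nrow(td), nrow(fit$final_contour))
  gl <- glance(fit, truth = ph$target)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$dice > 0.5)
  expect_equal(gl$iterations, fit$iterations_run)
  pl <- autoplot(fit, init = ph$suggested_init)
  expect_s3_class(pl, "ggplot")
})

test_that("energy trace is recorded when requested and decreases on a disk", {
  ph <- generate_phantom(phantom_spec("disk"))
  p <- snake_params(max_iter = 150, track_energy = TRUE)
  fit <- run_snake(ph$image, ph$suggested_init, p, "prior_gvf",
                   gvf = gvf_params(iters = 80))
  expect_length(fit$energy_trace, fit$iterations_run)
  expect_true(all(is.finite(fit$energy_trace)))
})
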