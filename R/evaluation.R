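# Evaluation: rasterize contours to binary masks by the pixel-center
# even-odd rule and score segmentations with the Dice overlap coefficient.

#' Binary mask container
#'
#' @param values Logical or 0/1 numeric matrix.
#' @return A logical matrix of class `binary_mask`.
#' @export
binary_mask <- function(values) {
  if (!is.matrix(values)) {
    abort("`values` must be a matrix.", class = "snakeseg_input_error")
  }
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1))) {
      abort("mask values must be strictly 0/1.",
            class = "snakeseg_input_error")
    }
    values <- values == 1
  }
  if (!is.logical(values) || anyNA(values)) {
    abort("mask must be logical with no NA.", class = "snakeseg_input_error")
  }
  structure(values, class = c("binary_mask", "matrix", "array"))
}

# Proper self-intersection test between non-adjacent edges of the closed
# polygon (strict crossings only; shared endpoints of adjacent edges are
# legal by construction).
contour_self_intersects <- function(c) {
  p <- contour_matrix(c)
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  a <- p; b <- p[nxt, , drop = FALSE]
  crossp <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in 1:(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]   # wrap-adjacent pair
    if (!length(js)) next
    d1 <- crossp(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- crossp(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- crossp(a[js, 1], a[js, 2], b[js, 1], b[js, 2], a[i, 1], a[i, 2])
    d4 <- crossp(a[js, 1], a[js, 2], b[js, 1], b[js, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Rasterize a closed contour to a binary mask
#'
#' A pixel belongs to the mask iff its center (integer coordinates) lies
#' inside the closed polygon under the even-odd rule — a deterministic,
#' exactly testable convention. A contour entirely outside the grid yields
#' an empty mask.
#'
#' @param c A `snake_contour`.
#' @param shape Integer `c(h, w)` grid shape.
#' @param check Reject self-intersecting contours (proper edge crossings)
#'   with a geometry error. The even-odd rule itself is defined for any
#'   polygon, so pipelines that must not fail can disable the check.
#' @return A [binary_mask()] of the given shape.
#' @export
contour_to_mask <- function(c, shape, check = TRUE) {
  c <- as_contour(c)
  if (check && contour_self_intersects(c)) {
    abort("contour is self-intersecting.", class = "snakeseg_geometry_error")
  }
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  parity <- matrix(0L, h, w)
  p <- contour_matrix(c)
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  yc <- 0:(h - 1L)
  for (e in seq_len(n)) {
    y1 <- p[e, 2]; y2 <- p[nxt[e], 2]
    if (y1 == y2) next
    rows <- which((y1 > yc) != (y2 > yc))
    if (!length(rows)) next
    x1 <- p[e, 1]; x2 <- p[nxt[e], 1]
    xint <- x1 + (yc[rows] - y1) * (x2 - x1) / (y2 - y1)
    k <- pmax(0L, pmin(w, as.integer(ceiling(xint))))
    for (idx in seq_along(rows)) {
      if (k[idx] > 0L) {
        cols <- seq_len(k[idx])
        parity[rows[idx], cols] <- parity[rows[idx], cols] + 1L
      }
    }
  }
  binary_mask(parity %% 2L == 1L)
}

#' Dice overlap coefficient
#'
#' `2 |A ∩ B| / (|A| + |B|)` by pixel counting: 1 for identical non-empty
#' masks, 0 for disjoint masks.
#'
#' @param a,b [binary_mask()]s (or logical matrices) of one shape, not both
#'   empty.
#' @return A ratio in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    abort("masks must share one shape.", class = "snakeseg_input_error")
  }
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    abort("Dice is undefined for two empty masks.",
          class = "snakeseg_input_error")
  }
  2 * sum(a & b) / (na + nb)
}

# Connected components (4-connectivity) by flood fill; returns an integer
# label matrix, 0 = background.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    queue <- todo[1]
    lab[queue] <- cur
    while (length(queue)) {
      idx <- queue
      queue <- integer(0)
      r <- ((idx - 1L) %% h) + 1L
      cl <- ((idx - 1L) %/% h) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- cl + d[2]
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        ni <- (cc[ok] - 1L) * h + rr[ok]
        ni <- ni[mask[ni] & lab[ni] == 0L]
        if (length(ni)) {
          lab[ni] <- cur
          queue <- c(queue, unique(ni))
        }
      }
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Run several force models over a phantom set and score them
#'
#' Each phantom is segmented from its suggested initial contour by every
#' requested force model; the final contour is rasterized and scored with
#' Dice against the phantom's target structure (for multi-structure
#' phantoms, the structure containing the initial contour). A failing run
#' is recorded as `NaN` with a message, never a crash.
#'
#' @param phantoms List of phantoms from [generate_phantom()] /
#'   [phantom_suite()].
#' @param methods Character vector of force models (subset of
#'   `c("classic", "gvf", "prior_gvf")`).
#' @param params A [snake_params()].
#' @param gvf A [gvf_params()].
#' @return A tibble: `phantom_id`, `structure_id`, `method`, `dice`,
#'   `iterations`, `converged`.
#' @export
evaluate_methods <- function(phantoms, methods = c("classic", "gvf",
                                                   "prior_gvf"),
                             params = snake_params(), gvf = gvf_params()) {
  rows <- list()
  for (pi in seq_along(phantoms)) {
    ph <- phantoms[[pi]]
    shape <- dim(ph$image)
    field <- NULL
    if (any(methods %in% c("gvf", "prior_gvf"))) {
      field <- compute_gvf(edge_map(ph$image, params$sigma), gvf)
    }
    for (mth in methods) {
      res <- tryCatch({
        fit <- run_snake(ph$image, ph$suggested_init, params, mth,
                         gvf = gvf,
                         field = if (mth == "classic") NULL else field)
        mask <- contour_to_mask(fit$final_contour, shape, check = FALSE)
        list(dice = dice(mask, ph$target),
             iterations = fit$iterations_run, converged = fit$converged)
      }, error = function(e) {
        message(sprintf("phantom %d (%s), method %s failed: %s",
                        pi, ph$spec$kind, mth, conditionMessage(e)))
        list(dice = NaN, iterations = NA_integer_, converged = NA)
      })
      rows[[length(rows) + 1L]] <- tibble(
        phantom_id = pi, structure_id = ph$structure_id,
        method = mth, dice = res$dice,
        iterations = res$iterations, converged = res$converged,
        kind = ph$spec$kind)
    }
  }
  if (!length(rows)) {
    return(tibble(phantom_id = integer(0), structure_id = integer(0),
                  method = character(0), dice = numeric(0),
                  iterations = integer(0), converged = logical(0),
                  kind = character(0)))
  }
  dplyr::bind_rows(rows)
}

#' Write / read a mask as PNG (0/255)
#'
#' @param mask A [binary_mask()].
#' @param path PNG path.
#' @return `path` invisibly; `read_mask_png()` returns a [binary_mask()].
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  binary_mask(m > 0.5)
}
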