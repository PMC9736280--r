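# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched. `seed = NULL` runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "feesxai_config_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a child seed from a base seed, kept below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 1009 * k) %% 2147483647
}

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask <- function(m, what = "mask") {
  if (!is.matrix(m)) abort(sprintf("`%s` must be a matrix.", what),
                           class = "feesxai_validation_error")
  if (is.logical(m)) {
    m[is.na(m)] <- FALSE
    return(m)
  }
  if (!all(m %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (0/1).", what),
          class = "feesxai_validation_error")
  }
  matrix(as.logical(m), nrow(m), ncol(m))
}

check_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    abort(sprintf("Shape mismatch between %s: %s vs %s.", what,
                  paste(dim(a)[1:2], collapse = "x"),
                  paste(dim(b)[1:2], collapse = "x")),
          class = "feesxai_validation_error")
  }
  invisible(TRUE)
}

# Separable Gaussian blur of a matrix with edge replication; sigma in pixels.
gaussian_blur_mat <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_along <- function(m, kern, r) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(kern)) {
      off <- i - r - 1L
      rows <- clamp(seq_len(n) + off, 1L, n)
      out <- out + kern[i] * m[rows, , drop = FALSE]
    }
    out
  }
  t(blur_along(t(blur_along(x, k, r)), k, r))
}

# Filled-ellipse mask: centre (ci, cj) in pixels, semi-axes (a_i, a_j) along the
# rotated frame, rotation theta in radians (row/col coordinates, row-major).
ellipse_mask <- function(h, w, ci, cj, ai, aj, theta = 0) {
  if (ai <= 0 || aj <= 0) return(matrix(FALSE, h, w))
  di <- matrix(seq_len(h) - ci, h, w)
  dj <- matrix(seq_len(w) - cj, h, w, byrow = TRUE)
  u <- cos(theta) * di + sin(theta) * dj
  v <- -sin(theta) * di + cos(theta) * dj
  (u / ai)^2 + (v / aj)^2 <= 1
}

disk_mask <- function(h, w, ci, cj, radius) {
  ellipse_mask(h, w, ci, cj, radius, radius, 0)
}

# Low-frequency multiplicative field used for scene shading.
smooth_noise <- function(h, w, scale = 8L) {
  hh <- max(2L, ceiling(h / scale))
  ww <- max(2L, ceiling(w / scale))
  coarse <- matrix(runif(hh * ww), hh, ww)
  ri <- clamp(round(seq(1, hh, length.out = h)), 1L, hh)
  rj <- clamp(round(seq(1, ww, length.out = w)), 1L, ww)
  gaussian_blur_mat(coarse[ri, rj, drop = FALSE], 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
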