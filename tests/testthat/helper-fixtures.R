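# Analytic fixtures and brute-force oracles shared across test files.

# Height grid with flat-bottomed elliptical pits at exactly the pixels whose
# centres fall inside the ellipse. Geometry is exact, no taper and no noise,
# so the true footprint mask is known.
make_pit_grid <- function(n, px, pits, depth = 20, base = 0) {
  h <- matrix(base, n, n)
  mask <- matrix(FALSE, n, n)
  xc <- (seq_len(n) - 0.5) * px
  for (p in pits) {
    a <- p$a; b <- if (is.null(p$b)) p$a else p$b
    th <- if (is.null(p$theta)) 0 else p$theta
    X <- matrix(xc, n, n, byrow = TRUE) - p$cx
    Y <- matrix(xc, n, n) - p$cy
    xr <- X * cos(th) + Y * sin(th)
    yr <- -X * sin(th) + Y * cos(th)
    mask <- mask | ((xr / a)^2 + (yr / b)^2 <= 1)
  }
  h[mask] <- base - depth
  list(heights = h, mask = mask)
}

pit_topography <- function(n, px, pits, depth = 20) {
  g <- make_pit_grid(n, px, pits, depth)
  topography(g$heights, scan_size_x_nm = n * px)
}

# Corner coordinates of a logical mask, in nm (same convention as the
# package: pixel (r, c) spans [(c-1) px, c px] x [(r-1) px, r px]).
mask_corners <- function(mask, px) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  cbind(x = c(c - 1, c, c - 1, c) * px,
        y = c(r - 1, r - 1, r, r) * px)
}

# Brute-force maximum Feret: max distance over ALL corner pairs (no hull).
feret_max_oracle <- function(pts) {
  best <- 0
  n <- nrow(pts)
  for (i in seq_len(n - 1)) {
    d2 <- (pts[(i + 1):n, 1] - pts[i, 1])^2 +
          (pts[(i + 1):n, 2] - pts[i, 2])^2
    best <- max(best, d2)
  }
  sqrt(best)
}

# Brute-force minimum Feret: minimum projection width over a fine sweep of
# caliper orientations.
feret_min_oracle <- function(pts, n_angles = 1800) {
  ang <- seq(0, pi, length.out = n_angles)
  widths <- vapply(ang, function(a) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  min(widths)
}

# Reference segmentation + measurement of a single-pit grid built with
# make_pit_grid, bypassing the package pipeline.
default_spec <- function(...) {
  membrane_spec("test", wall_thickness_um = 30, water_content = 0.79,
                tortuosity = 1.6, ...)
}
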