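#' Specification for a synthetic SPM topography
#'
#' Describes a synthetic scan of a rough polymer membrane surface carrying
#' elliptical nanopores, emulating the statistical structure of dynamic
#' force microscopy scans of hemoconcentration membranes: nm-scale
#' non-circular pores on a rough polyethersulfone surface, at field sizes
#' such as 2000, 500 or 200 nm. Axis lengths are drawn from truncated
#' lognormal distributions (truncation to [4 pixels, scan/3] keeps every
#' pore resolvable and well inside the field), orientations are uniform on
#' [0, 180) degrees, and pores are placed without overlap by rejection
#' sampling.
#'
#' Roughness is modelled as a Gaussian random field: white noise, convolved
#' to `roughness_correlation_nm` when that length exceeds the pixel size
#' (sub-pixel correlation is unresolvable and the field is then left white,
#' which matches the pixel-uncorrelated appearance of instrument noise).
#' Coarser surface texture from the polymer particles is modelled separately
#' as superposed spherical-cap bumps (`particle_texture`).
#'
#' @param grid_n Pixels per side; default 512.
#' @param scan_size_nm Field size, nm; default 2000.
#' @param n_pores Number of pores; default 15.
#' @param major_median_nm,major_sigma Median (nm) and lognormal sigma of the
#'   major-axis distribution; defaults 27 nm and 0.45, matching the wide
#'   right-skewed axis distributions seen on high-permeability membranes.
#' @param minor_median_nm,minor_sigma Same for the minor axis; defaults
#'   15 nm and 0.45. Each pore's minor axis is capped at its major axis.
#' @param pore_depth_nm Pit depth, nm; default 20 (deep relative to the
#'   roughness, as for through-pores profiled by a sharp tip).
#' @param roughness_sigma_nm RMS roughness, nm; default 1.
#' @param roughness_correlation_nm Roughness correlation length, nm;
#'   default 2.
#' @param particle_texture Optional list `(radius_nm, density_um2,
#'   height_nm)` of spherical-cap bumps; default `NULL` (off).
#' @param seed Integer seed; mandatory (the generator is fully
#'   deterministic given the spec).
#' @param allow_edge If `TRUE`, pore centres may fall anywhere in the field
#'   so pores can intersect the border (edge-case generation);
#'   default `FALSE` (all pores fully inside).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_n = 512, scan_size_nm = 2000, n_pores = 15,
                           major_median_nm = 27, major_sigma = 0.45,
                           minor_median_nm = 15, minor_sigma = 0.45,
                           pore_depth_nm = 20, roughness_sigma_nm = 1,
                           roughness_correlation_nm = 2,
                           particle_texture = NULL, seed,
                           allow_edge = FALSE) {
  if (missing(seed)) stop_domain("'seed' is mandatory for synthetic_spec")
  check_scalar(seed, "seed")
  check_scalar(grid_n, "grid_n"); check_scalar(scan_size_nm, "scan_size_nm")
  check_scalar(n_pores, "n_pores")
  if (grid_n < 8) stop_domain("'grid_n' must be >= 8 (got %g)", grid_n)
  if (scan_size_nm <= 0) stop_domain("'scan_size_nm' must be > 0")
  if (n_pores < 0) stop_domain("'n_pores' must be >= 0")
  if (pore_depth_nm < 0) stop_domain("'pore_depth_nm' must be >= 0")
  if (roughness_sigma_nm < 0) stop_domain("'roughness_sigma_nm' must be >= 0")
  structure(list(grid_n = as.integer(grid_n), scan_size_nm = scan_size_nm,
                 n_pores = as.integer(n_pores),
                 major_median_nm = major_median_nm, major_sigma = major_sigma,
                 minor_median_nm = minor_median_nm, minor_sigma = minor_sigma,
                 pore_depth_nm = pore_depth_nm,
                 roughness_sigma_nm = roughness_sigma_nm,
                 roughness_correlation_nm = roughness_correlation_nm,
                 particle_texture = particle_texture,
                 seed = as.integer(seed), allow_edge = allow_edge,
                 pixel_size_nm = scan_size_nm / grid_n),
            class = "synthetic_spec")
}

# Pit depth multiplier on a pixel window around one elliptical pore.
# rho is the normalised elliptical coordinate (1 on the rim); the rim is
# cosine-tapered over a band of true width `taper_nm` measured as the
# first-order distance to the rim, so the taper is ~1 px wide regardless of
# eccentricity.
.pit_window <- function(grid_n, px, cx, cy, a, b, theta_rad, taper_nm,
                        rho_max = 1) {
  half <- max(a, b) * max(rho_max, 1) + taper_nm + px
  cols <- max(1L, floor((cx - half) / px)):min(grid_n, ceiling((cx + half) / px))
  rows <- max(1L, floor((cy - half) / px)):min(grid_n, ceiling((cy + half) / px))
  xc <- (cols - 0.5) * px - cx
  yc <- (rows - 0.5) * px - cy
  X <- matrix(xc, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(yc, length(rows), length(cols))
  xr <- X * cos(theta_rad) + Y * sin(theta_rad)
  yr <- -X * sin(theta_rad) + Y * cos(theta_rad)
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  grad <- sqrt((xr / a^2)^2 + (yr / b^2)^2) / pmax(rho, 1e-12)
  d <- (1 - rho) / pmax(grad, 1e-12)   # >0 inside the rim, in nm
  f <- ifelse(d >= taper_nm, 1,
              ifelse(d <= 0, 0, 0.5 * (1 - cos(pi * d / taper_nm))))
  list(rows = rows, cols = cols, factor = f, rho = rho)
}

#' Generate a synthetic topography with ground truth
#'
#' Builds the surface described by a [synthetic_spec()]: Gaussian roughness,
#' optional particle bumps, and elliptical-cylindrical pits with a
#' one-pixel cosine-tapered rim (the taper avoids aliasing artefacts in the
#' downstream caliper measurement). Placement is rejection sampling with up
#' to 1000 attempts per pore; pores are pairwise non-overlapping (centre
#' distance greater than the sum of the semi-major axes). Deterministic
#' given the spec (including its seed).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `topography` (a [topography()], provenance
#'   `"synthetic"`) and `truth` (data frame: `pore_id, centroid_x_nm,
#'   centroid_y_nm, major_nm, minor_nm, orientation_deg, depth_nm`).
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$grid_n; px <- spec$pixel_size_nm; scan <- spec$scan_size_nm
  with_seed(spec$seed, {
    h <- matrix(0, n, n)
    if (spec$roughness_sigma_nm > 0) {
      z <- matrix(rnorm(n * n), n, n)
      if (spec$roughness_correlation_nm > px) {
        z <- EBImage::gblur(z, sigma = spec$roughness_correlation_nm / px)
        z <- matrix(as.numeric(z), n, n)
      }
      h <- h + z * (spec$roughness_sigma_nm / sd(z))
    }
    if (!is.null(spec$particle_texture)) {
      pt <- spec$particle_texture
      area_um2 <- (scan / 1000)^2
      nb <- max(0L, round(pt$density_um2 * area_um2))
      hb <- if (is.null(pt$height_nm)) pt$radius_nm / 2 else pt$height_nm
      for (i in seq_len(nb)) {
        bx <- runif(1, 0, scan); by <- runif(1, 0, scan)
        w <- .pit_window(n, px, bx, by, pt$radius_nm, pt$radius_nm, 0, px)
        cap <- hb * sqrt(pmax(0, 1 - pmin(w$rho, 1)^2))
        h[w$rows, w$cols] <- h[w$rows, w$cols] + cap
      }
    }
    # pore axis draws (truncated lognormal), then rejection placement
    lo <- 4 * px; hi <- scan / 3
    if (lo >= hi)
      stop_domain("grid too coarse: 4 px (%.3g nm) >= scan/3 (%.3g nm)",
                  lo, hi)
    draw_trunc <- function(median_nm, sigma) {
      for (i in 1:1000) {
        v <- rlnorm(1, log(median_nm), sigma)
        if (v >= lo && v <= hi) return(v)
      }
      min(max(median_nm, lo), hi)
    }
    truth <- NULL
    if (spec$n_pores > 0L) {
      maj <- numeric(spec$n_pores); mnr <- numeric(spec$n_pores)
      ori <- numeric(spec$n_pores)
      cx <- numeric(spec$n_pores); cy <- numeric(spec$n_pores)
      for (i in seq_len(spec$n_pores)) {
        maj[i] <- draw_trunc(spec$major_median_nm, spec$major_sigma)
        mnr[i] <- min(draw_trunc(spec$minor_median_nm, spec$minor_sigma),
                      maj[i])
        ori[i] <- runif(1, 0, 180)
        margin <- if (spec$allow_edge) 0 else maj[i] / 2 + 2 * px
        if (2 * margin >= scan)
          stop_domain("pore %d (major %.3g nm) cannot fit in a %g nm field",
                      i, maj[i], scan)
        placed <- FALSE
        for (attempt in 1:1000) {
          x <- runif(1, margin, scan - margin)
          y <- runif(1, margin, scan - margin)
          prev <- seq_len(i - 1L)
          if (i == 1L ||
              all(sqrt((cx[prev] - x)^2 + (cy[prev] - y)^2) >
                  (maj[prev] + maj[i]) / 2)) {
            cx[i] <- x; cy[i] <- y; placed <- TRUE; break
          }
        }
        if (!placed)
          stop_domain(paste("could not place pore %d without overlap in 1000",
                            "attempts; request fewer or smaller pores"), i)
      }
      for (i in seq_len(spec$n_pores)) {
        w <- .pit_window(n, px, cx[i], cy[i], maj[i] / 2, mnr[i] / 2,
                         ori[i] * pi / 180, px)
        h[w$rows, w$cols] <- h[w$rows, w$cols] - spec$pore_depth_nm * w$factor
      }
      truth <- data.frame(pore_id = seq_len(spec$n_pores),
                          centroid_x_nm = cx, centroid_y_nm = cy,
                          major_nm = maj, minor_nm = mnr,
                          orientation_deg = ori,
                          depth_nm = spec$pore_depth_nm)
    } else {
      truth <- data.frame(pore_id = integer(), centroid_x_nm = numeric(),
                          centroid_y_nm = numeric(), major_nm = numeric(),
                          minor_nm = numeric(), orientation_deg = numeric(),
                          depth_nm = numeric())
    }
    list(topography = topography(h, scan, scan,
                                 label = sprintf("synthetic seed %d",
                                                 spec$seed),
                                 provenance = "synthetic"),
         truth = truth)
  })
}

#' Apply a protein-fouling transform to a synthetic topography
#'
#' Emulates a protein adsorption layer occluding pore inlets: a seeded
#' random subset of pores (exactly `round(coverage_fraction * n)`) is
#' filled up to `layer_thickness_nm` below the local surface level (the
#' mean height of an annulus around the pore), and the field is optionally
#' smoothed with a Gaussian kernel of scale `smoothing_scale_nm`. The
#' occluded subsets are nested in `coverage_fraction` at a fixed seed, so
#' the number of surviving pores is non-increasing in the coverage. With
#' `coverage_fraction = 0` and no smoothing the topography is returned
#' bit-identical.
#'
#' @param t The synthetic [topography()].
#' @param truth Its ground-truth pore table (from [generate_surface()]).
#' @param coverage_fraction Fraction of pores to occlude, in [0, 1].
#' @param layer_thickness_nm Residual depression left by the layer over an
#'   occluded pore, nm; default 1 (the layer almost levels the pore mouth).
#' @param smoothing_scale_nm Gaussian smoothing scale, nm; default 0 (off).
#'   Note that smoothing the whole field also correlates the surrounding
#'   roughness, which lowers the robust detection threshold downstream.
#' @param seed Integer seed for the choice of occluded pores; mandatory.
#' @return List with `topography` and `occlusion` (data frame: `pore_id`,
#'   `occluded`).
#' @export
apply_fouling <- function(t, truth, coverage_fraction,
                          layer_thickness_nm = 1, smoothing_scale_nm = 0,
                          seed) {
  stopifnot(inherits(t, "topography"))
  if (missing(seed)) stop_domain("'seed' is mandatory for apply_fouling")
  check_scalar(coverage_fraction, "coverage_fraction")
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop_domain("'coverage_fraction' must lie in [0, 1] (got %g)",
                coverage_fraction)
  if (layer_thickness_nm < 0)
    stop_domain("'layer_thickness_nm' must be >= 0")
  np <- nrow(truth)
  n_occl <- round(coverage_fraction * np)
  perm <- with_seed(seed, sample.int(max(np, 1L)))
  occluded_ids <- if (np > 0L) sort(truth$pore_id[perm[seq_len(n_occl)]])
                  else integer()
  occl <- data.frame(pore_id = truth$pore_id,
                     occluded = truth$pore_id %in% occluded_ids)
  if (n_occl == 0L && smoothing_scale_nm <= 0)
    return(list(topography = t, occlusion = occl))
  h <- t$heights
  n <- nrow(h); px <- t$pixel_size_x_nm
  for (id in occluded_ids) {
    r <- truth[truth$pore_id == id, ]
    w <- .pit_window(n, px, r$centroid_x_nm, r$centroid_y_nm,
                     r$major_nm / 2, r$minor_nm / 2,
                     r$orientation_deg * pi / 180, px, rho_max = 1.6)
    ring <- w$rho > 1.1 & w$rho <= 1.6
    ref <- if (any(ring)) mean(h[w$rows, w$cols][ring]) else 0
    inside <- w$rho <= 1
    sub <- h[w$rows, w$cols]
    sub[inside] <- pmax(sub[inside], ref - layer_thickness_nm)
    h[w$rows, w$cols] <- sub
  }
  if (smoothing_scale_nm > 0) {
    h <- EBImage::gblur(h, sigma = smoothing_scale_nm / px)
    h <- matrix(as.numeric(h), n, ncol(t$heights))
  }
  out <- t
  out$heights <- h
  list(topography = out, occlusion = occl)
}

#' Detection and measurement recovery metrics against ground truth
#'
#' Matches measured pores to ground-truth pores greedily by nearest
#' centroid, accepting a match when the centroid distance is below
#' `max(truth major axis, 2 pixels)`. Precision is matched/measured, recall
#' matched/truth; bias and RMSE are computed over the matched major axes
#' (bias additionally reported relative to the mean true major axis).
#'
#' @param truth Ground-truth pore table from [generate_surface()].
#' @param measured Measurement table from [measure_pores()].
#' @param pixel_size_nm Pixel size used for the 2-pixel floor of the match
#'   radius; default 0 (no floor).
#' @return List with `n_truth`, `n_measured`, `n_matched`, `precision`,
#'   `recall`, `major_bias_nm`, `major_bias_rel`, `major_rmse_nm`,
#'   `no_detections` flag.
#' @export
recovery_metrics <- function(truth, measured, pixel_size_nm = 0) {
  truth <- as.data.frame(truth); measured <- as.data.frame(measured)
  if (nrow(truth) == 0L)
    stop_domain("empty ground truth: recovery metrics undefined")
  if (nrow(measured) == 0L)
    return(list(n_truth = nrow(truth), n_measured = 0L, n_matched = 0L,
                precision = 0, recall = 0, major_bias_nm = NA_real_,
                major_bias_rel = NA_real_, major_rmse_nm = NA_real_,
                no_detections = TRUE))
  D <- outer(measured$centroid_x_nm, truth$centroid_x_nm, "-")^2 +
       outer(measured$centroid_y_nm, truth$centroid_y_nm, "-")^2
  D <- sqrt(D)
  lim <- pmax(truth$major_nm, 2 * pixel_size_nm)
  ok <- sweep(D, 2L, lim, "<=")
  D[!ok] <- Inf
  matches <- NULL
  while (any(is.finite(D))) {
    ij <- arrayInd(which.min(D), dim(D))
    matches <- rbind(matches, ij)
    D[ij[1L], ] <- Inf; D[, ij[2L]] <- Inf
  }
  nm <- if (is.null(matches)) 0L else nrow(matches)
  if (nm == 0L)
    return(list(n_truth = nrow(truth), n_measured = nrow(measured),
                n_matched = 0L, precision = 0, recall = 0,
                major_bias_nm = NA_real_, major_bias_rel = NA_real_,
                major_rmse_nm = NA_real_, no_detections = FALSE))
  err <- measured$major_nm[matches[, 1L]] - truth$major_nm[matches[, 2L]]
  list(n_truth = nrow(truth), n_measured = nrow(measured), n_matched = nm,
       precision = nm / nrow(measured), recall = nm / nrow(truth),
       major_bias_nm = mean(err),
       major_bias_rel = mean(err) / mean(truth$major_nm[matches[, 2L]]),
       major_rmse_nm = sqrt(mean(err^2)),
       no_detections = FALSE)
}
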