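#' Flatten a topography
#'
#' Removes the least-squares plane (sample tilt) and optionally aligns scan
#' lines by subtracting each row's median (`method = "plane+lines"`, the
#' usual correction for line-to-line offsets in raster SPM data). The result
#' is re-centred so its median height is 0. Both corrections are linear or
#' per-row constant shifts, so local pit depths relative to their surround
#' are preserved.
#'
#' @param t A [topography()] with at least 2 rows and 2 columns.
#' @param method `"plane"` (default) or `"plane+lines"`.
#' @return Flattened [topography()].
#' @export
flatten_topography <- function(t, method = c("plane", "plane+lines")) {
  stopifnot(inherits(t, "topography"))
  method <- match.arg(method)
  h <- t$heights
  if (nrow(h) < 2L || ncol(h) < 2L)
    stop_domain("cannot flatten a single-row or single-column grid")
  nr <- nrow(h); nc <- ncol(h)
  x <- rep(seq_len(nc), each = nr)
  y <- rep(seq_len(nr), times = nc)
  fit <- stats::lm.fit(cbind(1, x, y), as.vector(h))
  h <- matrix(fit$residuals, nr, nc)
  if (method == "plane+lines")
    h <- h - apply(h, 1L, median)
  h <- h - median(h)
  out <- t
  out$heights <- h
  out
}

#' Segment pores in a flattened topography
#'
#' Pores are detected as connected components (4-connectivity) of pixels
#' deeper than a robust threshold \eqn{-k \cdot MAD(h)}, where MAD is the
#' median absolute deviation (scaled to be consistent with the standard
#' deviation for Gaussian heights) of the flattened height field.
#' Components smaller than `min_area_px` pixels are discarded. Components
#' touching the scan border are kept but flagged, and excluded from
#' distributions by default downstream. Labels are deterministic given the
#' input.
#'
#' @param t A flattened [topography()].
#' @param depth_threshold_k Threshold multiplier `k`; default 3.
#' @param min_area_px Minimum component area in pixels; default 4.
#' @return Object of class `pore_segmentation`: list with `labels` (integer
#'   matrix, 0 = background), `n_pores`, `threshold_nm`, `topography` and the
#'   parameters used. An empty segmentation (0 pores) is valid.
#' @export
segment_pores <- function(t, depth_threshold_k = 3, min_area_px = 4) {
  stopifnot(inherits(t, "topography"))
  check_scalar(depth_threshold_k, "depth_threshold_k")
  check_scalar(min_area_px, "min_area_px")
  h <- t$heights
  thr <- -depth_threshold_k * mad(h)
  lab <- EBImage::bwlabel(h < thr)
  lab <- matrix(as.integer(lab), nrow(h), ncol(h))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area_px)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  structure(list(labels = lab, n_pores = max(lab),
                 threshold_nm = thr, topography = t,
                 depth_threshold_k = depth_threshold_k,
                 min_area_px = min_area_px),
            class = "pore_segmentation")
}

#' @export
print.pore_segmentation <- function(x, ...) {
  cat(sprintf("Pore segmentation: %d pore(s) below %.3g nm (k = %g, min area %g px)\n",
              x$n_pores, x$threshold_nm, x$depth_threshold_k, x$min_area_px))
  invisible(x)
}

# Corner coordinates (nm) of the pixels in a mask index set; the convex
# hull of pixel corners is what caliper (Feret) measures operate on.
.pixel_corners <- function(idx, px, py) {
  r <- idx[, 1L]; c <- idx[, 2L]
  cbind(x = c(c - 1, c, c - 1, c) * px,
        y = c(r - 1, r - 1, r, r) * py)
}

# Max Feret = maximum pairwise distance over hull vertices; min Feret =
# rotating-calipers width (minimum over hull edges of the maximal distance
# of any vertex from the edge's supporting line).
.feret <- function(pts) {
  hull <- pts[chull(pts), , drop = FALSE]
  n <- nrow(hull)
  if (n == 1L) return(c(max = 0, min = 0))
  d2 <- 0
  for (i in seq_len(n - 1L)) {
    dx <- hull[(i + 1L):n, 1L] - hull[i, 1L]
    dy <- hull[(i + 1L):n, 2L] - hull[i, 2L]
    d2 <- max(d2, dx * dx + dy * dy)
  }
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hull[j, 1L] - hull[i, 1L]; ey <- hull[j, 2L] - hull[i, 2L]
    len <- sqrt(ex * ex + ey * ey)
    if (len == 0) next
    w <- max(abs((pts[, 1L] - hull[i, 1L]) * ey -
                 (pts[, 2L] - hull[i, 2L]) * ex)) / len
    wmin <- min(wmin, w)
  }
  c(max = sqrt(d2), min = if (is.finite(wmin)) wmin else 0)
}

#' Measure one segmented pore
#'
#' Line analysis of a labelled pore region: the major axis is the maximum
#' Feret (caliper) diameter of the region's pixel footprint, the minor axis
#' the minimum Feret width, both over the convex hull of pixel corners and
#' reported in nm. The equivalent diameter is the ellipse-area-equivalent
#' \eqn{\sqrt{major \times minor}} (see [equivalent_diameter()]), the area
#' is pixel count times pixel area, and the depth is the magnitude of the
#' deepest height in the region (the surround is at height ~0 after
#' flattening).
#'
#' @param seg A [segment_pores()] result.
#' @param id Pore label (1..`seg$n_pores`).
#' @return One-row data frame with columns `pore_id, centroid_x_nm,
#'   centroid_y_nm, major_nm, minor_nm, equiv_diameter_nm, area_nm2,
#'   depth_nm, edge_flag`.
#' @export
measure_pore <- function(seg, id) {
  stopifnot(inherits(seg, "pore_segmentation"))
  idx <- which(seg$labels == id, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_domain("no pixels labelled %s", format(id))
  t <- seg$topography
  px <- t$pixel_size_x_nm; py <- t$pixel_size_y_nm
  fer <- .feret(.pixel_corners(idx, px, py))
  major <- fer[["max"]]; minor <- fer[["min"]]
  if (minor > major) { tmp <- major; major <- minor; minor <- tmp }
  area <- nrow(idx) * px * py
  edge <- any(idx[, 1L] == 1L | idx[, 1L] == nrow(seg$labels) |
              idx[, 2L] == 1L | idx[, 2L] == ncol(seg$labels))
  data.frame(pore_id = as.integer(id),
             centroid_x_nm = mean((idx[, 2L] - 0.5) * px),
             centroid_y_nm = mean((idx[, 1L] - 0.5) * py),
             major_nm = major, minor_nm = minor,
             equiv_diameter_nm = sqrt(major * minor),
             area_nm2 = area,
             depth_nm = abs(min(t$heights[idx])),
             edge_flag = edge)
}

#' Measure all segmented pores
#'
#' @inheritParams measure_pore
#' @return Data frame with one row per pore (possibly zero rows), columns as
#'   in [measure_pore()].
#' @export
measure_pores <- function(seg) {
  stopifnot(inherits(seg, "pore_segmentation"))
  if (seg$n_pores == 0L) {
    out <- data.frame(pore_id = integer(), centroid_x_nm = numeric(),
                      centroid_y_nm = numeric(), major_nm = numeric(),
                      minor_nm = numeric(), equiv_diameter_nm = numeric(),
                      area_nm2 = numeric(), depth_nm = numeric(),
                      edge_flag = logical())
    return(out)
  }
  do.call(rbind, lapply(seq_len(seg$n_pores), measure_pore, seg = seg))
}

#' Ellipse-area equivalent diameter from major and minor axes
#'
#' The diameter of the circle whose area equals that of the ellipse with the
#' given axes: \eqn{\pi (d/2)^2 = \pi (major/2)(minor/2)}, i.e.
#' \eqn{d = \sqrt{major \times minor}}.
#'
#' @param major,minor Axis lengths, nm; `major >= minor > 0`.
#' @return Equivalent diameter, nm.
#' @examples
#' equivalent_diameter(27.1, 14.9)   # 20.09
#' @export
equivalent_diameter <- function(major, minor) {
  if (!is.numeric(major) || !is.numeric(minor) ||
      length(major) != length(minor))
    stop_domain("'major' and 'minor' must be numeric vectors of equal length")
  if (any(!is.finite(major)) || any(!is.finite(minor)) ||
      any(minor <= 0) || any(major < minor))
    stop_domain("axes must satisfy major >= minor > 0")
  sqrt(major * minor)
}

#' Pore-size distribution and summary statistics
#'
#' Histograms one pore metric into fixed-width bins starting at 0 and
#' summarises all four metrics (major axis, minor axis, equivalent diameter,
#' area) as mean and sample standard deviation (n - 1 denominator; reported
#' as 0 with an `n = 1` flag for a single pore). Edge-touching pores are
#' excluded by default, as their axes are censored by the scan border.
#'
#' @param measurements Data frame from [measure_pores()].
#' @param metric One of `"major"`, `"minor"`, `"equiv_diameter"`, `"area"`.
#' @param bin_width Bin width; default 5 nm for axis metrics, 100 nm^2 for
#'   area.
#' @param include_edge Include edge-flagged pores? Default `FALSE`.
#' @return Object of class `pore_size_distribution`: list with `metric`,
#'   `bin_edges`, `counts`, `n`, `single_pore` flag and `summary` (data
#'   frame of mean/sd/n per metric).
#' @export
build_distribution <- function(measurements,
                               metric = c("major", "minor",
                                          "equiv_diameter", "area"),
                               bin_width = NULL, include_edge = FALSE) {
  metric <- match.arg(metric)
  m <- as.data.frame(measurements)
  if (!include_edge && nrow(m) > 0L) m <- m[!m$edge_flag, , drop = FALSE]
  if (nrow(m) == 0L)
    stop_domain(paste("no pores to histogram; if pores were detected,",
                      "edge exclusion may have removed them all",
                      "(set include_edge = TRUE to keep them)"))
  col <- switch(metric, major = "major_nm", minor = "minor_nm",
                equiv_diameter = "equiv_diameter_nm", area = "area_nm2")
  if (is.null(bin_width)) bin_width <- if (metric == "area") 100 else 5
  v <- m[[col]]
  edges <- seq(0, bin_width * (floor(max(v) / bin_width) + 1L), by = bin_width)
  counts <- tabulate(findInterval(v, edges), nbins = length(edges) - 1L)
  summ <- do.call(rbind, lapply(
    c(major = "major_nm", minor = "minor_nm",
      equiv_diameter = "equiv_diameter_nm", area = "area_nm2"),
    function(cc) data.frame(mean = mean(m[[cc]]),
                            sd = if (nrow(m) > 1L) sd(m[[cc]]) else 0,
                            n = nrow(m))))
  summ <- cbind(metric = rownames(summ), summ)
  rownames(summ) <- NULL
  structure(list(metric = metric, bin_edges = edges, counts = counts,
                 n = nrow(m), single_pore = nrow(m) == 1L,
                 bin_width = bin_width, summary = summ),
            class = "pore_size_distribution")
}

#' @export
print.pore_size_distribution <- function(x, ...) {
  unit <- if (x$metric == "area") "nm^2" else "nm"
  cat(sprintf("Pore size distribution (%s, %d pore(s), bin width %g %s)%s\n",
              x$metric, x$n, x$bin_width, unit,
              if (x$single_pore) " [single pore: sd undefined, shown as 0]"
              else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pore_size_distribution <- function(x, ...) {
  unit <- if (x$metric == "area") "nm²" else "nm"
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  barplot(x$counts, names.arg = sprintf("%g", mids), space = 0,
          xlab = sprintf("%s (%s)", x$metric, unit), ylab = "count", ...)
  invisible(x)
}

#' Full pore-measurement pipeline on one topography
#'
#' Convenience wrapper running [flatten_topography()], [segment_pores()] and
#' [measure_pores()] in sequence.
#'
#' @param t A [topography()].
#' @param depth_threshold_k,min_area_px See [segment_pores()].
#' @param flatten_method See [flatten_topography()].
#' @return Object of class `pore_analysis`: list with `topography`
#'   (flattened), `segmentation`, `measurements` and the parameters used.
#' @export
analyze_topography <- function(t, depth_threshold_k = 3, min_area_px = 4,
                               flatten_method = "plane") {
  flat <- flatten_topography(t, flatten_method)
  seg <- segment_pores(flat, depth_threshold_k, min_area_px)
  structure(list(topography = flat, segmentation = seg,
                 measurements = measure_pores(seg),
                 depth_threshold_k = depth_threshold_k,
                 min_area_px = min_area_px,
                 flatten_method = flatten_method),
            class = "pore_analysis")
}

#' @export
print.pore_analysis <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("Pore analysis of %s scan (%g x %g nm): %d pore(s), %d at the border\n",
              x$topography$provenance, x$topography$scan_size_x_nm,
              x$topography$scan_size_y_nm, nrow(m), sum(m$edge_flag)))
  if (nrow(m) > 0L) {
    interior <- m[!m$edge_flag, , drop = FALSE]
    if (nrow(interior) > 0L)
      cat(sprintf("  interior pores: major %.1f +/- %.1f nm, minor %.1f +/- %.1f nm\n",
                  mean(interior$major_nm),
                  if (nrow(interior) > 1L) sd(interior$major_nm) else 0,
                  mean(interior$minor_nm),
                  if (nrow(interior) > 1L) sd(interior$minor_nm) else 0))
  }
  invisible(x)
}

#' @export
summary.pore_analysis <- function(object, ...) {
  if (nrow(object$measurements) == 0L) {
    cat("No pores detected.\n")
    return(invisible(NULL))
  }
  build_distribution(object$measurements, "major",
                     include_edge = all(object$measurements$edge_flag))
}

#' @export
plot.pore_analysis <- function(x, ...) {
  h <- x$topography$heights
  image(x = (seq_len(ncol(h)) - 0.5) * x$topography$pixel_size_x_nm,
        y = (seq_len(nrow(h)) - 0.5) * x$topography$pixel_size_y_nm,
        z = t(h)[, rev(seq_len(nrow(h))), drop = FALSE],
        xlab = "x (nm)", ylab = "y (nm)", useRaster = TRUE, ...)
  m <- x$measurements
  if (nrow(m) > 0L)
    points(m$centroid_x_nm, x$topography$scan_size_y_nm - m$centroid_y_nm,
           pch = 3, col = "red")
  invisible(x)
}
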