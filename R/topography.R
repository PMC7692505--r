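#' Construct a topography (SPM height map)
#'
#' A topography is a rectangular grid of surface heights in nm together with
#' the physical scan size. Orientation convention: row 1 is the top scan
#' line, x increases with column index (origin top-left). Pixel size is
#' derived as scan size / number of pixels spanning the field. Heights are
#' relative: the absolute offset carries no information and is removed by
#' [flatten_topography()].
#'
#' @param heights Numeric matrix of heights, nm. All values must be finite
#'   and the peak-to-valley range must not exceed `z_range_limit_nm` (the
#'   probe's vertical travel).
#' @param scan_size_x_nm,scan_size_y_nm Physical field size, nm. The y size
#'   defaults to the x size (square scans such as 2000, 500 or 200 nm
#'   fields).
#' @param label Free-text label.
#' @param provenance `"measured"` or `"synthetic"`.
#' @param z_range_limit_nm Instrument z-range cap, nm; default 12500
#'   (a 12.5 um probe tip).
#' @return Object of class `topography` with elements `heights`,
#'   `scan_size_x_nm`, `scan_size_y_nm`, `pixel_size_x_nm`,
#'   `pixel_size_y_nm`, `z_range_limit_nm`, `label`, `provenance`.
#' @export
topography <- function(heights, scan_size_x_nm,
                       scan_size_y_nm = scan_size_x_nm, label = "",
                       provenance = c("synthetic", "measured"),
                       z_range_limit_nm = 12500) {
  provenance <- match.arg(provenance)
  if (!is.matrix(heights) || !is.numeric(heights) ||
      nrow(heights) < 1L || ncol(heights) < 1L)
    stop_format("'heights' must be a non-empty numeric matrix")
  bad <- which(!is.finite(heights), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_format("non-finite height at cell(s): %s",
                paste(sprintf("[%d,%d]", bad[, 1], bad[, 2])[seq_len(min(5, nrow(bad)))],
                      collapse = ", "))
  check_scalar(scan_size_x_nm, "scan_size_x_nm")
  check_scalar(scan_size_y_nm, "scan_size_y_nm")
  if (scan_size_x_nm <= 0 || scan_size_y_nm <= 0)
    stop_domain("scan sizes must be > 0")
  check_scalar(z_range_limit_nm, "z_range_limit_nm")
  rng <- max(heights) - min(heights)
  if (rng > z_range_limit_nm)
    stop_domain("height range %.3g nm exceeds instrument z-range limit %g nm",
                rng, z_range_limit_nm)
  structure(list(heights = heights,
                 scan_size_x_nm = scan_size_x_nm,
                 scan_size_y_nm = scan_size_y_nm,
                 pixel_size_x_nm = scan_size_x_nm / ncol(heights),
                 pixel_size_y_nm = scan_size_y_nm / nrow(heights),
                 z_range_limit_nm = z_range_limit_nm,
                 label = label,
                 provenance = provenance),
            class = "topography")
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("Topography%s [%s]\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$provenance))
  cat(sprintf("  %d x %d px, %g x %g nm (pixel %.3g x %.3g nm)\n",
              nrow(x$heights), ncol(x$heights),
              x$scan_size_x_nm, x$scan_size_y_nm,
              x$pixel_size_x_nm, x$pixel_size_y_nm))
  cat(sprintf("  height range [%.3g, %.3g] nm\n",
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Read a topography from a plain-text grid and metadata sidecar
#'
#' The grid file is a rectangular numeric matrix, one scan line per row,
#' comma- or whitespace-separated. The metadata sidecar (default
#' `<grid>.meta.json`) is a JSON object with keys `scan_size_x_nm`,
#' `scan_size_y_nm` (falling back to `scan_size_x_nm` when absent), optional
#' `z_unit` (`"nm"`, `"um"` or `"m"`; heights are converted to nm), `label`
#' and `provenance`.
#'
#' @param path Path to the grid file.
#' @param metadata_path Path to the JSON sidecar; default `<path>.meta.json`.
#' @return A [topography()].
#' @export
read_topography <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop_format("grid file not found: %s", path)
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".meta.json")
  if (!file.exists(metadata_path))
    stop_format("metadata sidecar not found: %s", metadata_path)
  meta <- jsonlite::fromJSON(metadata_path)
  if (is.null(meta$scan_size_x_nm))
    stop_format("metadata %s lacks required key 'scan_size_x_nm'",
                metadata_path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format("grid file %s is empty", path)
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  rows <- lapply(lines, function(l) {
    v <- scan(text = l, what = numeric(), sep = if (sep == ",") "," else "",
              quiet = TRUE)
    v
  })
  nc <- lengths(rows)
  if (length(unique(nc)) != 1L)
    stop_format("ragged grid in %s: row %d has %d values, expected %d",
                path, which(nc != nc[[1]])[[1]], nc[which(nc != nc[[1]])[[1]]],
                nc[[1]])
  h <- do.call(rbind, rows)
  z_unit <- if (is.null(meta$z_unit)) "nm" else meta$z_unit
  fac <- switch(z_unit, nm = 1, um = 1e3, "µm" = 1e3, m = 1e9,
                stop_format("unknown z_unit '%s' in %s", z_unit, metadata_path))
  h <- h * fac
  topography(h,
             scan_size_x_nm = meta$scan_size_x_nm,
             scan_size_y_nm = if (is.null(meta$scan_size_y_nm))
               meta$scan_size_x_nm else meta$scan_size_y_nm,
             label = if (is.null(meta$label)) "" else meta$label,
             provenance = if (is.null(meta$provenance)) "measured"
             else meta$provenance)
}

#' Write a topography to a plain-text grid plus metadata sidecar
#'
#' Inverse of [read_topography()]: heights are written in nm at full double
#' precision (17 significant digits), so `read_topography(write_topography(t))`
#' is bit-identical.
#'
#' @param t A [topography()].
#' @param path Output grid path (CSV).
#' @param metadata_path Sidecar path; default `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_topography <- function(t, path, metadata_path = NULL) {
  stopifnot(inherits(t, "topography"))
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".meta.json")
  txt <- apply(t$heights, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
  jsonlite::write_json(
    list(scan_size_x_nm = t$scan_size_x_nm,
         scan_size_y_nm = t$scan_size_y_nm,
         z_unit = "nm", label = t$label, provenance = t$provenance),
    metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pore_table_columns <- c("pore_id", "centroid_x_nm", "centroid_y_nm",
                        "major_nm", "minor_nm", "equiv_diameter_nm",
                        "area_nm2", "depth_nm", "edge_flag")

#' Write a pore-measurement table to CSV
#'
#' Columns: `pore_id, centroid_x_nm, centroid_y_nm, major_nm, minor_nm,
#' equiv_diameter_nm, area_nm2, depth_nm, edge_flag`. Values are written at
#' full double precision so the [read_pore_table()] round trip is lossless.
#' An empty measurement set produces a header-only file.
#'
#' @param measurements Data frame of pore measurements (as produced by
#'   [measure_pores()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pore_table <- function(measurements, path) {
  m <- as.data.frame(measurements)
  missing_cols <- setdiff(pore_table_columns, names(m))
  if (length(missing_cols) > 0L && nrow(m) > 0L)
    stop_format("measurement table lacks column(s): %s",
                paste(missing_cols, collapse = ", "))
  header <- paste(pore_table_columns, collapse = ",")
  if (nrow(m) == 0L) { writeLines(header, path); return(invisible(path)) }
  num_cols <- setdiff(pore_table_columns, c("pore_id", "edge_flag"))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(sprintf("%d", as.integer(m$pore_id[[i]])),
            sprintf("%.17g", unlist(m[i, num_cols], use.names = FALSE)),
            tolower(as.character(m$edge_flag[[i]]))), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_pore_table
#' @export
read_pore_table <- function(path) {
  if (!file.exists(path)) stop_format("pore table not found: %s", path)
  df <- read.table(path, header = TRUE, sep = ",",
                   colClasses = c(pore_id = "integer", edge_flag = "logical",
                                  setNames(rep("numeric", 7),
                                           setdiff(pore_table_columns,
                                                   c("pore_id", "edge_flag")))))
  if (!identical(names(df), pore_table_columns))
    stop_format("unexpected pore-table header in %s", path)
  df
}
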