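#' Physical specification of a homogeneous membrane
#'
#' Bundles the structural constants of one hollow-fibre membrane type that the
#' tortuous pore diffusion (TPD) model needs: wall thickness \eqn{\Delta x},
#' volumetric water content \eqn{H}, tortuosity \eqn{\tau} and (optionally)
#' total membrane area and fibre inner diameter. The derived surface porosity
#' \eqn{A_K = H/\tau} must lie in (0, 1]; the constructor validates all
#' invariants and fails with a domain error naming the offending field.
#'
#' @param name Text label for the membrane (e.g. `"PUREMA A"`).
#' @param wall_thickness_um Membrane wall thickness \eqn{\Delta x}, micrometres.
#' @param water_content Volumetric water content \eqn{H} (void fraction of the
#'   wetted wall), dimensionless in (0, 1].
#' @param tortuosity Tortuosity \eqn{\tau \ge 1}: ratio of the true permeation
#'   path length to the wall thickness. Default 1.6, the empirical value used
#'   for polyethersulfone hemoconcentration membranes.
#' @param membrane_area_m2 Total membrane area of the device, m^2 (optional,
#'   used by the STOP-method permeability arithmetic).
#' @param inner_diameter_um Fibre inner diameter, micrometres (informational).
#' @return An object of class `membrane_spec`.
#' @examples
#' m <- membrane_spec("PUREMA A", wall_thickness_um = 30, water_content = 0.79)
#' m$surface_porosity   # H / tau = 0.49375
#' @export
membrane_spec <- function(name, wall_thickness_um, water_content,
                          tortuosity = 1.6, membrane_area_m2 = NA_real_,
                          inner_diameter_um = NA_real_) {
  if (!is.character(name) || length(name) != 1L)
    stop_domain("'name' must be a single string")
  check_scalar(wall_thickness_um, "wall_thickness_um")
  check_scalar(water_content, "water_content")
  check_scalar(tortuosity, "tortuosity")
  if (wall_thickness_um <= 0)
    stop_domain("'wall_thickness_um' must be > 0 (got %g)", wall_thickness_um)
  if (water_content <= 0 || water_content > 1)
    stop_domain("'water_content' must lie in (0, 1] (got %g)", water_content)
  if (tortuosity < 1)
    stop_domain("'tortuosity' must be >= 1 (got %g)", tortuosity)
  if (!is.na(membrane_area_m2) && membrane_area_m2 <= 0)
    stop_domain("'membrane_area_m2' must be > 0 (got %g)", membrane_area_m2)
  ak <- water_content / tortuosity
  if (ak <= 0 || ak > 1)
    stop_domain("derived surface porosity H/tau = %g outside (0, 1]", ak)
  structure(list(name = name,
                 wall_thickness_um = wall_thickness_um,
                 water_content = water_content,
                 tortuosity = tortuosity,
                 membrane_area_m2 = membrane_area_m2,
                 inner_diameter_um = inner_diameter_um,
                 surface_porosity = ak),
            class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat("Membrane:", x$name, "\n")
  cat(sprintf("  wall thickness  %g um\n", x$wall_thickness_um))
  cat(sprintf("  water content H %g\n", x$water_content))
  cat(sprintf("  tortuosity tau  %g\n", x$tortuosity))
  cat(sprintf("  surface porosity A_K = H/tau = %g\n", x$surface_porosity))
  if (!is.na(x$membrane_area_m2))
    cat(sprintf("  membrane area   %g m^2\n", x$membrane_area_m2))
  invisible(x)
}

#' Bundled reference parameters of two commercial hemoconcentration membranes
#'
#' Published characterisation values for the PUREMA A and PUREMA B
#' polyethersulfone hollow-fibre hemoconcentrator membranes: 30 um wall
#' thickness, 200 um inner diameter, 1.1 m^2 device area, water contents of
#' 0.79 and 0.77 v/v and an assumed tortuosity of 1.6.
#'
#' @return Named list of two [membrane_spec()] objects (`"PUREMA A"`,
#'   `"PUREMA B"`).
#' @seealso [purema_study()] for the matching permeability observations.
#' @export
purema_membranes <- function() {
  list(
    "PUREMA A" = membrane_spec("PUREMA A", wall_thickness_um = 30,
                               water_content = 0.79, tortuosity = 1.6,
                               membrane_area_m2 = 1.1, inner_diameter_um = 200),
    "PUREMA B" = membrane_spec("PUREMA B", wall_thickness_um = 30,
                               water_content = 0.77, tortuosity = 1.6,
                               membrane_area_m2 = 1.1, inner_diameter_um = 200))
}

#' Bundled permeability and sieving observations for the PUREMA membranes
#'
#' Mean pure water permeabilities (mL/(hr mmHg m^2), dead-end filtration,
#' n = 10) before and after bovine blood contact under high and low
#' filtration load, together with mean albumin sieving coefficients (n = 3),
#' for the membranes of [purema_membranes()]. These are summary values: raw
#' replicates were not published, so paired tests cannot be recomputed from
#' them (see [fouling_report()]).
#'
#' @return Named list (one entry per membrane) with elements `lp` (named
#'   numeric: `before`, `after_high_load`, `after_low_load`) and `sc_albumin`.
#' @export
purema_study <- function() {
  list(
    "PUREMA A" = list(
      lp = c(before = 207, after_high_load = 180, after_low_load = 194),
      sc_albumin = 0.01),
    "PUREMA B" = list(
      lp = c(before = 115, after_high_load = 114, after_low_load = 116),
      sc_albumin = 0.02))
}
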