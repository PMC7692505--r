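#' Surface porosity from water content and tortuosity
#'
#' In the tortuous pore diffusion model the tortuosity ties the volumetric
#' water content \eqn{H} to the areal surface porosity:
#' \eqn{\tau = H / A_K}, so \eqn{A_K = H / \tau}.
#'
#' @param h Water content \eqn{H}, volume fraction in (0, 1].
#' @param tau Tortuosity \eqn{\tau \ge 1}.
#' @return Surface porosity \eqn{A_K}, dimensionless in (0, 1].
#' @examples
#' surface_porosity(0.79, 1.6)   # 0.49375
#' @export
surface_porosity <- function(h, tau) {
  check_scalar(h, "h"); check_scalar(tau, "tau")
  if (h <= 0 || h > 1) stop_domain("'h' must lie in (0, 1] (got %g)", h)
  if (tau < 1) stop_domain("'tau' must be >= 1 (got %g)", tau)
  h / tau
}

#' TPD-model pore diameter from pure water permeability
#'
#' The tortuous pore diffusion (TPD) model treats a homogeneous membrane as a
#' bundle of tortuous cylindrical pores in Hagen-Poiseuille flow, giving
#' \deqn{L_P = \frac{r_P^2 H}{8 \mu \tau^2 \Delta x} \quad\Longleftrightarrow\quad
#'       r_P = \sqrt{\frac{8 \mu \tau^2 \Delta x}{H} L_P}.}
#' Inputs are taken in the clinical units in which they are reported
#' (permeability in mL/(hr mmHg m^2), viscosity in cP, thickness in um) and
#' converted to one canonical SI system (m, s, Pa; 1 mmHg = 133.322 Pa,
#' 1 cP = 1e-3 Pa s) before evaluation; the pore radius and diameter are
#' returned in nm.
#'
#' @param lp Pure water permeability \eqn{L_P}, mL/(hr mmHg m^2); must be
#'   >= 0. The diameter scales as \eqn{\sqrt{L_P}}.
#' @param spec A [membrane_spec()].
#' @param viscosity_cp Pure water viscosity \eqn{\mu}, cP. Default 0.695
#'   (pure water at 310 K, the temperature of the permeability measurement).
#' @return Object of class `tpd_result`: list with `pore_radius_nm`,
#'   `pore_diameter_nm`, `surface_porosity` and `inputs` (echo of all inputs
#'   used).
#' @examples
#' pm <- purema_membranes()
#' pore_diameter_from_lp(207, pm[["PUREMA A"]])$pore_diameter_nm  # 30.5 nm
#' pore_diameter_from_lp(115, pm[["PUREMA B"]])$pore_diameter_nm  # 23.1 nm
#' @seealso [lp_from_pore_radius()] for the algebraic inverse.
#' @export
pore_diameter_from_lp <- function(lp, spec, viscosity_cp = 0.695) {
  check_scalar(lp, "lp"); check_scalar(viscosity_cp, "viscosity_cp")
  if (!inherits(spec, "membrane_spec"))
    stop_domain("'spec' must be a membrane_spec object")
  if (lp < 0) stop_domain("'lp' must be >= 0 (got %g)", lp)
  if (viscosity_cp <= 0)
    stop_domain("'viscosity_cp' must be > 0 (got %g)", viscosity_cp)
  lp_si <- lp_clinical_to_si(lp)                    # m/(s Pa)
  mu <- viscosity_cp * CP_PAS                       # Pa s
  dx <- spec$wall_thickness_um * 1e-6               # m
  rp_m <- sqrt(8 * mu * spec$tortuosity^2 * dx * lp_si / spec$water_content)
  rp_nm <- rp_m * 1e9
  structure(list(pore_radius_nm = rp_nm,
                 pore_diameter_nm = 2 * rp_nm,
                 surface_porosity = spec$surface_porosity,
                 inputs = list(lp = lp, viscosity_cp = viscosity_cp,
                               spec = spec)),
            class = "tpd_result")
}

#' @export
print.tpd_result <- function(x, ...) {
  s <- x$inputs$spec
  cat("Tortuous pore diffusion model\n")
  cat(sprintf("  %s: Lp = %g mL/(hr mmHg m^2), H = %g, tau = %g, dx = %g um, mu = %g cP\n",
              s$name, x$inputs$lp, s$water_content, s$tortuosity,
              s$wall_thickness_um, x$inputs$viscosity_cp))
  cat(sprintf("  pore radius   %.2f nm\n", x$pore_radius_nm))
  cat(sprintf("  pore diameter %.1f nm\n", round(x$pore_diameter_nm, 1)))
  cat(sprintf("  surface porosity A_K = %g\n", x$surface_porosity))
  invisible(x)
}

#' Pure water permeability from TPD pore radius
#'
#' Exact algebraic inverse of [pore_diameter_from_lp()]:
#' \eqn{L_P = r_P^2 H / (8 \mu \tau^2 \Delta x)}, reported back in clinical
#' units mL/(hr mmHg m^2). The round trip `lp -> rp -> lp` reproduces the
#' input to machine precision.
#'
#' @param rp_nm Pore radius, nm; must be >= 0. Permeability scales as
#'   \eqn{r_P^2}.
#' @inheritParams pore_diameter_from_lp
#' @return Pure water permeability, mL/(hr mmHg m^2).
#' @export
lp_from_pore_radius <- function(rp_nm, spec, viscosity_cp = 0.695) {
  check_scalar(rp_nm, "rp_nm"); check_scalar(viscosity_cp, "viscosity_cp")
  if (!inherits(spec, "membrane_spec"))
    stop_domain("'spec' must be a membrane_spec object")
  if (rp_nm < 0) stop_domain("'rp_nm' must be >= 0 (got %g)", rp_nm)
  if (viscosity_cp <= 0)
    stop_domain("'viscosity_cp' must be > 0 (got %g)", viscosity_cp)
  mu <- viscosity_cp * CP_PAS
  dx <- spec$wall_thickness_um * 1e-6
  rp_m <- rp_nm * 1e-9
  lp_si <- rp_m^2 * spec$water_content / (8 * mu * spec$tortuosity^2 * dx)
  lp_si_to_clinical(lp_si)
}

#' Hindered-transport factors for a solute in a cylindrical pore
#'
#' Steric and hydrodynamic corrections for a spherical solute of radius
#' ratio \eqn{q = r_s / r_P} diffusing inside a cylindrical pore, in the
#' Verniory pore-model convention: the steric hindrance factor at the pore
#' inlet \eqn{S_D = (1 - q)^2} and the wall-friction factor
#' \deqn{f(q) = \frac{1 - 2.105 q + 2.0865 q^3 - 1.7068 q^5 + 0.72603 q^6}
#'                   {1 - 0.75857 q^5},}
#' the Haberman-Sayre centerline drag expression. Both equal 1 for a point
#' solute and decrease towards 0 as the solute fills the pore.
#'
#' @param q Solute-to-pore radius ratio, in [0, 1).
#' @param friction Function of `q` returning the wall-friction factor;
#'   defaults to the polynomial above. Supplying a different published form
#'   (e.g. a centreline Bungay-Brenner fit) changes only this factor.
#' @return Named list with `f_q` (friction factor) and `s_d` (steric factor).
#' @examples
#' hindrance_factors(0)      # both 1: point solute
#' hindrance_factors(0.5)$f_q   # about 0.171
#' @export
hindrance_factors <- function(q, friction = verniory_friction) {
  check_scalar(q, "q")
  if (q < 0 || q >= 1) stop_domain("'q' must lie in [0, 1) (got %g)", q)
  list(f_q = friction(q), s_d = (1 - q)^2)
}

#' @rdname hindrance_factors
#' @export
verniory_friction <- function(q) {
  (1 - 2.105 * q + 2.0865 * q^3 - 1.7068 * q^5 + 0.72603 * q^6) /
    (1 - 0.75857 * q^5)
}

#' Solute membrane permeability under the TPD model
#'
#' Diffusive permeability of a solute through the tortuous pore bundle:
#' \deqn{P_m = \frac{D_O\, f(q)\, S_D\, A_K}{\tau\, \Delta x},}
#' where \eqn{D_O} is the free diffusivity of the solute in water and
#' \eqn{A_K = H/\tau}. At \eqn{q = 0} this reduces to
#' \eqn{D_O A_K / (\tau \Delta x)}.
#'
#' @param do_m2s Free solution diffusivity \eqn{D_O}, m^2/s; must be > 0.
#' @param q Solute-to-pore radius ratio, in [0, 1).
#' @param spec A [membrane_spec()].
#' @param friction Optional wall-friction function, see [hindrance_factors()].
#' @return Solute permeability \eqn{P_m}, m/s.
#' @export
solute_permeability <- function(do_m2s, q, spec, friction = verniory_friction) {
  check_scalar(do_m2s, "do_m2s")
  if (!inherits(spec, "membrane_spec"))
    stop_domain("'spec' must be a membrane_spec object")
  if (do_m2s <= 0) stop_domain("'do_m2s' must be > 0 (got %g)", do_m2s)
  hf <- hindrance_factors(q, friction)
  dx <- spec$wall_thickness_um * 1e-6
  do_m2s * hf$f_q * hf$s_d * spec$surface_porosity / (spec$tortuosity * dx)
}

#' Pure water permeability from a dead-end filtration (STOP method) run
#'
#' The STOP method drives RO water through the membrane dead-end at a set
#' transmembrane pressure and records the filtrate flow. Permeability in the
#' clinical convention is filtrate flux per pressure per area:
#' \deqn{L_P = \frac{Q_F \times 60}{A \cdot TMP}}
#' with \eqn{Q_F} in mL/min, TMP in mmHg and \eqn{A} in m^2, yielding
#' mL/(hr mmHg m^2). If a collected volume is recorded instead of a flow
#' rate, divide by `duration_min` first; `duration_min` is otherwise
#' metadata only.
#'
#' @param qf_ml_min Filtrate flow \eqn{Q_F}, mL/min; >= 0.
#' @param tmp_mmhg Transmembrane pressure, mmHg; > 0.
#' @param area_m2 Membrane area, m^2; > 0.
#' @param duration_min Run duration, min (metadata; default 1).
#' @return Pure water permeability, mL/(hr mmHg m^2).
#' @examples
#' lp_from_stop_method(330, 100, 1.1)   # 180
#' @export
lp_from_stop_method <- function(qf_ml_min, tmp_mmhg, area_m2,
                                duration_min = 1) {
  check_scalar(qf_ml_min, "qf_ml_min"); check_scalar(tmp_mmhg, "tmp_mmhg")
  check_scalar(area_m2, "area_m2")
  if (qf_ml_min < 0) stop_domain("'qf_ml_min' must be >= 0 (got %g)", qf_ml_min)
  if (tmp_mmhg <= 0)
    stop_domain("'tmp_mmhg' must be > 0 (got %g): zero pressure", tmp_mmhg)
  if (area_m2 <= 0) stop_domain("'area_m2' must be > 0 (got %g)", area_m2)
  (qf_ml_min * 60) / (area_m2 * tmp_mmhg)
}
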