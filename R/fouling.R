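#' Paired t-test on before/after replicate vectors
#'
#' Standard two-sided paired t-test on the elementwise differences, pairing
#' by index. A thin wrapper around [stats::t.test()] that enforces the
#' pairing preconditions and rejects the degenerate zero-variance case
#' (where the t statistic is undefined) with an explicit error.
#'
#' @param before,after Numeric replicate vectors of equal length `n >= 2`.
#' @param alpha Significance level; default 0.05.
#' @return List with `t`, `df`, `p` (two-sided) and `significant`
#'   (`p < alpha`).
#' @examples
#' paired_t_test(c(10, 12, 14), c(9, 11, 12))   # t = 4, df = 2, p ~ 0.057
#' @export
paired_t_test <- function(before, after, alpha = 0.05) {
  if (!is.numeric(before) || !is.numeric(after))
    stop_domain("'before' and 'after' must be numeric vectors")
  if (length(before) != length(after))
    stop_domain("paired vectors differ in length (%d vs %d)",
                length(before), length(after))
  if (length(before) < 2L)
    stop_domain("need at least 2 pairs (got %d)", length(before))
  d <- before - after
  if (sd(d) == 0)
    stop_domain("zero-variance differences: paired t statistic is undefined")
  tt <- t.test(before, after, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha)
}

#' Solute sieving coefficient
#'
#' Ratio of the filtrate concentration to the mean blood-side concentration,
#' the standard hemoconcentrator convention:
#' \deqn{SC = \frac{2\, C_{filtrate}}{C_{blood,in} + C_{blood,out}}.}
#' SC near 0 means the solute (e.g. albumin) is retained; SC = 1 means free
#' passage. A value above 1 is physically suspect and triggers a warning.
#'
#' @param c_blood_in,c_blood_out Blood-side inlet and outlet concentrations
#'   (any consistent unit); both >= 0, not both 0.
#' @param c_filtrate Filtrate-side concentration, same unit; >= 0.
#' @return Sieving coefficient, dimensionless.
#' @examples
#' sieving_coefficient(40, 44, 0.42)   # 0.01
#' @export
sieving_coefficient <- function(c_blood_in, c_blood_out, c_filtrate) {
  check_scalar(c_blood_in, "c_blood_in")
  check_scalar(c_blood_out, "c_blood_out")
  check_scalar(c_filtrate, "c_filtrate")
  if (c_blood_in < 0 || c_blood_out < 0 || c_filtrate < 0)
    stop_domain("concentrations must be >= 0")
  if (c_blood_in + c_blood_out == 0)
    stop_domain("blood-side concentrations are both zero")
  sc <- 2 * c_filtrate / (c_blood_in + c_blood_out)
  if (sc > 1)
    warning(sprintf("sieving coefficient %.3g > 1 is physically suspect", sc))
  sc
}

#' Before/after fouling comparison report
#'
#' The study-level comparison for one membrane: pure water permeability
#' before and after blood contact, permeability retention ratios, the TPD
#' pore diameter for every condition, paired t-tests (when replicate vectors
#' rather than summary means are supplied) and the albumin sieving
#' coefficient. Because the TPD diameter scales as \eqn{\sqrt{L_P}}, the
#' report satisfies `diameter_after / diameter_before =
#' sqrt(lp_after / lp_before)` exactly.
#'
#' @param membrane A [membrane_spec()].
#' @param lp Named list or vector of permeabilities in mL/(hr mmHg m^2).
#'   Must contain `before`; optional `after_high_load`, `after_low_load`.
#'   Each element is either a single mean or a replicate vector; t-tests are
#'   computed only where both `before` and the after-condition are replicate
#'   vectors of equal length.
#' @param sc Optional albumin sieving coefficient: either a single number or
#'   a list with `c_blood_in`, `c_blood_out`, `c_filtrate` passed to
#'   [sieving_coefficient()].
#' @param alpha Significance level for the paired tests.
#' @param viscosity_cp Water viscosity for the TPD diameters, cP.
#' @return Object of class `fouling_comparison`: list with `membrane`,
#'   `conditions` (data frame: condition, n, lp_mean, lp_sd, retention,
#'   tpd_diameter_nm), `t_tests` (data frame or NULL with a `t_test_note`),
#'   `sc_albumin`.
#' @examples
#' rep <- fouling_report(purema_membranes()[["PUREMA A"]],
#'                       purema_study()[["PUREMA A"]]$lp, sc = 0.01)
#' rep$conditions$tpd_diameter_nm    # 30.5, 28.5, 29.5 nm
#' @export
fouling_report <- function(membrane, lp, sc = NULL, alpha = 0.05,
                           viscosity_cp = 0.695) {
  if (!inherits(membrane, "membrane_spec"))
    stop_domain("'membrane' must be a membrane_spec object")
  lp <- as.list(lp)
  if (is.null(lp$before))
    stop_domain("'lp' must contain a 'before' condition")
  known <- c("before", "after_high_load", "after_low_load")
  extra <- setdiff(names(lp), known)
  if (length(extra) > 0L)
    stop_domain("unknown condition(s): %s", paste(extra, collapse = ", "))
  conds <- intersect(known, names(lp))
  rows <- lapply(conds, function(cn) {
    v <- lp[[cn]]
    if (!is.numeric(v) || length(v) < 1L || any(v < 0))
      stop_domain("permeabilities for '%s' must be non-negative numbers", cn)
    data.frame(condition = cn, n = length(v), lp_mean = mean(v),
               lp_sd = if (length(v) > 1L) sd(v) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  tab$retention <- tab$lp_mean / tab$lp_mean[tab$condition == "before"]
  if (any(tab$retention > 1.5) || any(tab$retention < 0))
    warning("permeability retention outside [0, 1.5]: check condition labels")
  else if (any(tab$retention > 1))
    message("note: a post-contact permeability exceeds the pre-contact value")
  tab$tpd_diameter_nm <- vapply(tab$lp_mean, function(v)
    pore_diameter_from_lp(v, membrane, viscosity_cp)$pore_diameter_nm,
    numeric(1))
  after <- setdiff(conds, "before")
  have_reps <- function(cn) length(lp[[cn]]) >= 2L
  tests <- NULL; note <- NULL
  testable <- after[vapply(after, function(cn)
    have_reps(cn) && have_reps("before") &&
      length(lp[[cn]]) == length(lp$before), logical(1))]
  if (length(testable) > 0L) {
    tests <- do.call(rbind, lapply(testable, function(cn) {
      tt <- paired_t_test(lp$before, lp[[cn]], alpha)
      data.frame(comparison = paste("before vs", cn), t = tt$t, df = tt$df,
                 p = tt$p, significant = tt$significant)
    }))
  }
  if (length(setdiff(after, testable)) > 0L)
    note <- paste("t-test skipped for:",
                  paste(setdiff(after, testable), collapse = ", "),
                  "(summary means only; replicate vectors required)")
  sc_val <- NULL
  if (!is.null(sc)) {
    sc_val <- if (is.list(sc))
      sieving_coefficient(sc$c_blood_in, sc$c_blood_out, sc$c_filtrate)
    else sc
    if (sc_val < 0) stop_domain("sieving coefficient must be >= 0")
    if (sc_val > 1)
      warning(sprintf("sieving coefficient %.3g > 1 is physically suspect",
                      sc_val))
  }
  structure(list(membrane = membrane, conditions = tab, t_tests = tests,
                 t_test_note = note, sc_albumin = sc_val, alpha = alpha,
                 viscosity_cp = viscosity_cp),
            class = "fouling_comparison")
}

#' @export
print.fouling_comparison <- function(x, ...) {
  cat("Fouling comparison:", x$membrane$name, "\n")
  tab <- x$conditions
  tab$lp_mean <- sprintf("%.4g", tab$lp_mean)
  tab$retention <- sprintf("%.3f", tab$retention)
  tab$tpd_diameter_nm <- sprintf("%.1f", tab$tpd_diameter_nm)
  print(tab, row.names = FALSE)
  if (!is.null(x$t_tests)) {
    cat(sprintf("Paired t-tests (alpha = %g):\n", x$alpha))
    print(x$t_tests, row.names = FALSE)
  }
  if (!is.null(x$t_test_note)) cat(x$t_test_note, "\n")
  if (!is.null(x$sc_albumin))
    cat(sprintf("Albumin sieving coefficient: %.3g\n", x$sc_albumin))
  invisible(x)
}
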