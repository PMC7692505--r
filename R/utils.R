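# Unit conversion constants. All transport algebra is done in SI
# (m, s, Pa); clinical units only at the interface.
MMHG_PA <- 133.322      # 1 mmHg in Pa
CP_PAS  <- 1e-3         # 1 cP in Pa s

# Clinical permeability mL/(hr mmHg m^2) -> SI m/(s Pa)
lp_clinical_to_si <- function(lp) lp * 1e-6 / (3600 * MMHG_PA)
lp_si_to_clinical <- function(lp) lp * 3600 * MMHG_PA / 1e-6

stop_domain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("hemopore_domain_error", "hemopore_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("hemopore_format_error", "hemopore_error")))
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("'%s' must be a single finite number", name)
  invisible(x)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()),
      add = TRUE)
    set.seed(seed)
  }
  force(code)
}
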