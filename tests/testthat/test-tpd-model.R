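test_that("surface porosity is water content over tortuosity", {
  expect_equal(surface_porosity(0.79, 1.6), 0.49375)
  expect_equal(surface_porosity(0.77, 1.6), 0.48125)
  expect_equal(surface_porosity(1, 1), 1)
  expect_error(surface_porosity(0, 1.6), "'h'", class = "hemopore_domain_error")
  expect_error(surface_porosity(1.2, 1.6), "'h'")
  expect_error(surface_porosity(0.5, 0.9), "'tau'")
})

test_that("membrane_spec validates its invariants", {
  expect_error(membrane_spec("x", -1, 0.8), "wall_thickness")
  expect_error(membrane_spec("x", 30, 0), "water_content")
  expect_error(membrane_spec("x", 30, 0.8, tortuosity = 0.5), "tortuosity")
  expect_error(membrane_spec("x", 30, 0.8, membrane_area_m2 = 0),
               "membrane_area")
  m <- membrane_spec("x", 30, 0.8, tortuosity = 2)
  expect_equal(m$surface_porosity, 0.4)
})

test_that("TPD diameter follows square-root scaling and rejects bad input", {
  spec <- default_spec()
  expect_equal(pore_diameter_from_lp(0, spec)$pore_diameter_nm, 0)
  d1 <- pore_diameter_from_lp(50, spec)$pore_diameter_nm
  d4 <- pore_diameter_from_lp(200, spec)$pore_diameter_nm
  expect_equal(d4, 2 * d1, tolerance = 1e-12)
  res <- pore_diameter_from_lp(207, spec)
  expect_equal(res$pore_diameter_nm, 2 * res$pore_radius_nm)
  expect_equal(res$surface_porosity, 0.49375)
  expect_error(pore_diameter_from_lp(-1, spec), "'lp'")
  expect_error(pore_diameter_from_lp(100, spec, viscosity_cp = 0),
               "viscosity")
  expect_error(pore_diameter_from_lp(100, list(a = 1)), "membrane_spec")
})

test_that("permeability <-> pore radius round trip is the identity", {
  set.seed(42)
  for (i in 1:200) {
    lp <- runif(1, 1, 1000)
    spec <- membrane_spec("sweep", wall_thickness_um = runif(1, 5, 100),
                          water_content = runif(1, 0.1, 1),
                          tortuosity = runif(1, 1, 3))
    mu <- runif(1, 0.3, 1.5)
    rp <- pore_diameter_from_lp(lp, spec, mu)$pore_radius_nm
    expect_equal(lp_from_pore_radius(rp, spec, mu), lp, tolerance = 1e-12)
  }
  # quadratic scaling of Lp in the radius
  spec <- default_spec()
  expect_equal(lp_from_pore_radius(20, spec),
               4 * lp_from_pore_radius(10, spec), tolerance = 1e-12)
  expect_equal(lp_from_pore_radius(0, spec), 0)
})

test_that("TPD diameter is monotone in each physical parameter", {
  set.seed(7)
  for (i in 1:50) {
    lp <- runif(1, 5, 500); h <- runif(1, 0.2, 0.9)
    tau <- runif(1, 1, 2.5); dx <- runif(1, 10, 60)
    mu <- runif(1, 0.4, 1.2)
    base <- pore_diameter_from_lp(
      lp, membrane_spec("m", dx, h, tau), mu)$pore_diameter_nm
    up <- function(lp2 = lp, h2 = h, tau2 = tau, dx2 = dx, mu2 = mu)
      pore_diameter_from_lp(lp2, membrane_spec("m", dx2, h2, tau2),
                            mu2)$pore_diameter_nm
    expect_gt(up(lp2 = lp * 1.1), base)    # increasing in Lp
    expect_gt(up(mu2 = mu * 1.1), base)    # increasing in viscosity
    expect_gt(up(tau2 = tau * 1.1), base)  # increasing in tortuosity
    expect_gt(up(dx2 = dx * 1.1), base)    # increasing in thickness
    expect_lt(up(h2 = min(h * 1.1, 1)), base)  # decreasing in water content
  }
})

test_that("hindrance factors obey point-solute and pore-filling limits", {
  hf0 <- hindrance_factors(0)
  expect_equal(hf0$f_q, 1)
  expect_equal(hf0$s_d, 1)
  hf1 <- hindrance_factors(1 - 1e-9)
  expect_lt(hf1$s_d, 1e-12)
  # value frozen from an independent hand evaluation of the published
  # friction polynomial at q = 0.5
  expect_equal(hindrance_factors(0.5)$f_q, 0.1703576, tolerance = 1e-6)
  # monotone non-increasing over a grid
  q <- seq(0, 0.99, by = 0.01)
  f <- vapply(q, function(x) hindrance_factors(x)$f_q, numeric(1))
  s <- vapply(q, function(x) hindrance_factors(x)$s_d, numeric(1))
  expect_true(all(diff(f) <= 0))
  expect_true(all(diff(s) <= 0))
  expect_true(all(f > 0 & f <= 1))
  expect_error(hindrance_factors(1), "'q'")
  expect_error(hindrance_factors(-0.1), "'q'")
})

test_that("solute permeability reduces to the diffusive closed form at q = 0", {
  spec <- default_spec()
  # D_O * A_K / (tau * dx) with D_O = 1e-9 m^2/s
  expect_equal(solute_permeability(1e-9, 0, spec),
               1e-9 * 0.49375 / (1.6 * 30e-6), tolerance = 1e-12)
  base <- solute_permeability(1e-9, 0, spec)
  for (q in c(0.1, 0.3, 0.6, 0.9))
    expect_lt(solute_permeability(1e-9, q, spec), base)
  expect_equal(solute_permeability(2e-9, 0.3, spec),
               2 * solute_permeability(1e-9, 0.3, spec), tolerance = 1e-12)
  expect_error(solute_permeability(0, 0.1, spec), "do_m2s")
})

test_that("STOP-method permeability arithmetic", {
  expect_equal(lp_from_stop_method(330, 100, 1.1), 180)
  expect_equal(lp_from_stop_method(150, 50, 1.1), 163.6364,
               tolerance = 1e-6)
  expect_equal(lp_from_stop_method(0, 50, 1.1), 0)
  expect_error(lp_from_stop_method(330, 0, 1.1), "zero pressure")
  expect_error(lp_from_stop_method(-1, 50, 1.1), "qf")
})
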