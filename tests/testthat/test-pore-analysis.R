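test_that("flattening removes planes exactly and preserves pit depth", {
  flat <- topography(matrix(5, 16, 16), 160)
  expect_equal(flatten_topography(flat)$heights, matrix(0, 16, 16))

  n <- 32
  tilt <- outer(seq_len(n), seq_len(n), function(y, x) 0.1 * x + 0.2 * y)
  tt <- flatten_topography(topography(tilt, n * 10))
  expect_equal(max(abs(tt$heights)), 0, tolerance = 1e-9)

  # tilted plane + pit: depth relative to a symmetric ring around the pit
  # is invariant under plane subtraction
  pit <- make_pit_grid(n, 10, list(list(cx = 160, cy = 160, a = 30)),
                       depth = 5)
  h <- tilt + pit$heights
  # pit floor and annulus are both symmetric about the pit centre, so any
  # plane's mean over each equals its value at the centre and cancels
  dist <- outer(seq_len(n), seq_len(n),
                function(y, x) sqrt((x * 10 - 5 - 160)^2 +
                                    (y * 10 - 5 - 160)^2))
  ring <- !pit$mask & dist < 60
  depth_of <- function(hh) mean(hh[ring]) - mean(hh[pit$mask])
  before <- depth_of(h)
  after <- depth_of(flatten_topography(topography(h, n * 10))$heights)
  expect_equal(before, 5, tolerance = 1e-9)  # analytic construction
  expect_equal(after, before, tolerance = 1e-9)

  expect_error(flatten_topography(topography(matrix(0, 1, 8), 80)),
               "single-row")

  # per-line median alignment removes row offsets a plane fit cannot
  rowoff <- matrix(rep(c(0, 4), each = 1, length.out = n), n, n)
  tl <- flatten_topography(topography(rowoff, n * 10), "plane+lines")
  expect_equal(max(abs(tl$heights)), 0, tolerance = 1e-9)
})

test_that("segmentation finds exactly the constructed pits", {
  # pure noise: no pore survives threshold + min-area at defaults
  set.seed(11)
  noise <- topography(matrix(rnorm(128 * 128), 128, 128), 512)
  seg0 <- segment_pores(flatten_topography(noise))
  expect_equal(seg0$n_pores, 0L)

  # one circular pit much deeper than the noise scale: exactly one pore
  pit <- make_pit_grid(128, 4, list(list(cx = 256, cy = 256, a = 40)),
                       depth = 20)
  t1 <- topography(pit$heights + matrix(rnorm(128 * 128, sd = 1), 128, 128),
                   512)
  seg1 <- segment_pores(flatten_topography(t1))
  m1 <- measure_pores(seg1)
  expect_equal(nrow(m1), 1L)
  expect_false(m1$edge_flag)
  expect_equal(m1$depth_nm, 20, tolerance = 5)

  # pit centred on the border is detected but flagged
  edge <- pit_topography(64, 4, list(list(cx = 0, cy = 128, a = 24)))
  me <- measure_pores(segment_pores(flatten_topography(edge)))
  expect_equal(nrow(me), 1L)
  expect_true(me$edge_flag)

  # determinism
  seg1b <- segment_pores(flatten_topography(t1))
  expect_identical(seg1$labels, seg1b$labels)
})

test_that("Feret axes match brute-force oracles and true geometry", {
  px <- 2
  # circle of true diameter 40 nm (radius 10 px)
  circ <- make_pit_grid(64, px, list(list(cx = 64, cy = 64, a = 20)))
  t <- topography(circ$heights, 128)
  m <- measure_pore(segment_pores(t), 1L)
  expect_equal(m$major_nm, 40, tolerance = 2)     # within 1 px
  expect_equal(m$minor_nm, 40, tolerance = 2)
  expect_equal(m$area_nm2, sum(circ$mask) * px^2)
  pts <- mask_corners(circ$mask, px)
  expect_equal(m$major_nm, feret_max_oracle(pts), tolerance = 1e-9)
  expect_equal(m$minor_nm, feret_min_oracle(pts), tolerance = 1e-3)

  # axis-aligned 40 x 20 px ellipse, then rotated by 30 degrees
  for (th in c(0, pi / 6)) {
    ell <- make_pit_grid(96, px, list(list(cx = 96, cy = 96, a = 20 * px,
                                           b = 10 * px, theta = th)))
    me <- measure_pore(segment_pores(topography(ell$heights, 192)), 1L)
    tol <- if (th == 0) 1 * px else 1.5 * px
    expect_equal(me$major_nm, 40 * px, tolerance = tol)
    expect_equal(me$minor_nm, 20 * px, tolerance = tol)
    pts <- mask_corners(ell$mask, px)
    expect_equal(me$major_nm, feret_max_oracle(pts), tolerance = 1e-9)
    expect_equal(me$minor_nm, feret_min_oracle(pts), tolerance = 1e-2)
  }
})

test_that("Feret axes are stable under rotation of the same ellipse", {
  px <- 2
  angles <- seq(0, 170, by = 20) * pi / 180
  majors <- minors <- numeric(length(angles))
  for (i in seq_along(angles)) {
    ell <- make_pit_grid(96, px, list(list(cx = 96, cy = 96, a = 30,
                                           b = 14, theta = angles[i])))
    m <- measure_pore(segment_pores(topography(ell$heights, 192)), 1L)
    majors[i] <- m$major_nm; minors[i] <- m$minor_nm
  }
  expect_lt(diff(range(majors)), 1.5 * px)
  expect_lt(diff(range(minors)), 1.5 * px)
})

test_that("measurements scale exactly with pixel size", {
  pit <- make_pit_grid(64, 2, list(list(cx = 64, cy = 64, a = 20, b = 12)))
  m1 <- measure_pore(segment_pores(topography(pit$heights, 128)), 1L)
  m2 <- measure_pore(segment_pores(topography(pit$heights, 256)), 1L)
  expect_equal(m2$major_nm, 2 * m1$major_nm)
  expect_equal(m2$minor_nm, 2 * m1$minor_nm)
  expect_equal(m2$equiv_diameter_nm, 2 * m1$equiv_diameter_nm)
  expect_equal(m2$area_nm2, 4 * m1$area_nm2)
})

test_that("equivalent diameter is the ellipse-area-equivalent", {
  expect_equal(equivalent_diameter(27.1, 14.9), 20.09, tolerance = 1e-3)
  expect_equal(equivalent_diameter(21.8, 14.0), 17.47, tolerance = 1e-3)
  expect_equal(equivalent_diameter(12, 12), 12)
  expect_error(equivalent_diameter(10, 0), "major >= minor > 0")
  expect_error(equivalent_diameter(10, 12), "major >= minor > 0")
})

test_that("distributions bin from zero and summarise with sample sd", {
  m <- data.frame(pore_id = 1:3, centroid_x_nm = 0, centroid_y_nm = 0,
                  major_nm = c(10, 10, 20), minor_nm = c(8, 8, 16),
                  equiv_diameter_nm = sqrt(c(80, 80, 320)),
                  area_nm2 = c(60, 60, 250), depth_nm = 1,
                  edge_flag = FALSE)
  d <- build_distribution(m, "major", bin_width = 5)
  expect_equal(sum(d$counts), d$n)
  expect_equal(d$counts[[3]], 2)              # [10, 15)
  expect_equal(d$counts[[5]], 1)              # [20, 25)
  expect_true(all(diff(d$bin_edges) > 0))
  summ <- d$summary[d$summary$metric == "major", ]
  expect_equal(summ$mean, 13.33333, tolerance = 1e-5)
  expect_equal(summ$sd, 5.773503, tolerance = 1e-6)

  one <- build_distribution(m[1, ], "major")
  expect_true(one$single_pore)
  expect_equal(one$summary$sd, rep(0, 4))

  same <- build_distribution(m[c(1, 1, 1), ], "area")
  expect_equal(same$summary$sd[same$summary$metric == "area"], 0)

  # all pores on the edge: default exclusion leaves nothing and says so
  medge <- m; medge$edge_flag <- TRUE
  expect_error(build_distribution(medge, "major"), "edge")
  expect_equal(build_distribution(medge, "major", include_edge = TRUE)$n, 3)
})
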