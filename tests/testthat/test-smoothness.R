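make_border <- function(px, spacing = c(1, 1)) {
  b <- binary_mask(px, spacing = spacing)
  class(b) <- c("border_mask", class(b))
  b
}

test_that("snap_landmark finds the nearest border pixel", {
  px <- matrix(FALSE, 30, 30)
  px[, 15] <- TRUE  # vertical line at col 14 (0-based)
  b <- make_border(px)
  expect_identical(snap_landmark(c(7, 14), b), c(7L, 14L))   # already on border
  expect_identical(snap_landmark(c(7, 11), b), c(7L, 14L))   # 3 px to the left
  expect_error(snap_landmark(c(7, 0), b, radius = 5), "landmark error")

  # random points against the brute-force scan, including tie-breaks
  set.seed(41)
  for (i in 1:25) {
    m <- matrix(runif(400) > 0.9, 20, 20)
    if (!any(m)) next
    pt <- runif(2, 0, 19)
    bm <- make_border(m)
    expect_identical(snap_landmark(pt, bm, radius = 40),
                     as.integer(oracle_nearest_border(pt, m)))
  }
})

test_that("euclidean_length respects spacing and symmetry", {
  expect_equal(euclidean_length(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_length(c(0, 0), c(0, 10), spacing = c(1, 0.5)), 5)
  set.seed(42)
  for (i in 1:10) {
    p <- runif(2, 0, 50); q <- runif(2, 0, 50); s <- runif(2, 0.1, 2)
    expect_equal(euclidean_length(p, q, s), euclidean_length(q, p, s))
  }
  expect_error(euclidean_length(c(1, 1), c(1, 1)), "degenerate")
})

test_that("geodesic_length handles straight and diagonal chains", {
  px <- matrix(FALSE, 5, 15)
  px[3, 3:13] <- TRUE  # 11 collinear pixels
  b <- make_border(px)
  expect_equal(geodesic_length(b, c(2, 2), c(2, 12)), 10)

  dg <- matrix(FALSE, 10, 10)
  for (i in 0:4) dg[2 + i, 2 + i] <- TRUE
  bd <- make_border(dg)
  expect_equal(geodesic_length(bd, c(1, 1), c(5, 5)), 4 * sqrt(2))

  # anisotropic spacing weights
  b2 <- make_border(px, spacing = c(2, 0.5))
  expect_equal(geodesic_length(b2, c(2, 2), c(2, 12)), 5)
})

test_that("geodesic_length equals the independent Dijkstra oracle and is symmetric", {
  skip_if_not_installed("igraph")
  set.seed(43)
  for (i in 1:30) {
    cv <- random_pixel_curve(60, 40, 40)
    b <- make_border(cv$mask)
    g <- geodesic_length(b, cv$start, cv$end)
    o <- oracle_geodesic_igraph(cv$mask, cv$start, cv$end)
    expect_equal(g, o, tolerance = 1e-12)
    expect_equal(geodesic_length(b, cv$end, cv$start), g)
    # metric property: never below the chord
    expect_gte(g, euclidean_length(cv$start, cv$end) - 1e-9)
  }
})

test_that("disconnected endpoints raise a connectivity error naming the point", {
  px <- matrix(FALSE, 10, 10)
  px[2, 2:4] <- TRUE
  px[8, 6:8] <- TRUE
  b <- make_border(px)
  expect_error(geodesic_length(b, c(1, 1), c(7, 7)), "connectivity error.*\\(7, 7\\)")
  expect_error(geodesic_length(b, c(1, 1), c(5, 5)), "not on the border")
})

test_that("side_measurement: flat border gives SI 1, half circle approaches 2/pi", {
  px <- matrix(FALSE, 10, 60)
  px[5, 6:55] <- TRUE
  b <- make_border(px)
  sm <- side_measurement(b, c(4, 5), c(4, 54), side = "nasal")
  expect_equal(sm$si, 1.0)
  expect_equal(sm$basal_length, sm$actual_length)

  # rasterized half circle, endpoints on the diameter
  r <- 30
  theta <- seq(0, pi, length.out = 400)
  rows <- round(40 - r * sin(theta)); cols <- round(35 + r * cos(theta))
  hc <- matrix(FALSE, 50, 70)
  hc[cbind(rows + 1, cols + 1)] <- TRUE
  bhc <- make_border(hc)
  smh <- side_measurement(bhc, c(40, 65), c(40, 5), side = "temporal")
  expect_lt(abs(smh$si - 2 / pi), 0.03)
  # and the raw estimator stays within the oracle path cost
  smr <- side_measurement(bhc, c(40, 65), c(40, 5), estimator = "raw")
  expect_gte(smr$actual_length, smr$basal_length)
  expect_lte(smr$si, 1)
})

test_that("coinciding snapped endpoints are a degenerate-measurement error", {
  px <- matrix(FALSE, 12, 12)
  px[6, 4:8] <- TRUE
  b <- make_border(px)
  expect_error(side_measurement(b, c(5, 5.1), c(5, 4.9), snap_radius = 3),
               "degenerate")
})

test_that("overall SI is the mediant of the side ratios", {
  mk <- function(side, bl, al) structure(
    list(side = side, basal_length = bl, actual_length = al, si = bl / al,
         peripheral = c(0, 0), central = c(0, 1)),
    class = "side_measurement")
  res <- compute_overall_si(mk("nasal", 100, 125), mk("temporal", 100, 125))
  expect_equal(res$overall_si, 0.8)

  res2 <- compute_overall_si(mk("nasal", 90, 100), mk("temporal", 110, 130))
  expect_equal(res2$overall_si, 200 / 230)
  expect_gt(res2$overall_si, min(res2$nasal$si, res2$temporal$si))
  expect_lt(res2$overall_si, max(res2$nasal$si, res2$temporal$si))

  # equal side SIs collapse to that SI
  res3 <- compute_overall_si(mk("nasal", 80, 100), mk("temporal", 120, 150))
  expect_equal(res3$overall_si, 0.8)
})

test_that("measure_si runs the full pipeline and names failing stages", {
  r <- render_iris(quick_flat_spec(seed = 44))
  res <- measure_si(r$image, r$landmarks, preprocess_cfg = quick_pre_cfg())
  expect_gte(res$overall_si, 0.99)
  expect_lte(res$overall_si, 1)
  expect_gte(res$nasal$actual_length, res$nasal$basal_length)

  # landmarks far off any border: stage-named error
  bad <- landmark_set(c(5, 5), c(5, 30), c(5, 60), c(5, 90))
  expect_error(measure_si(r$image, bad, preprocess_cfg = quick_pre_cfg()),
               "\\[measure-nasal\\]")
})

test_that("measured SI is invariant under isotropic scaling of the scene", {
  g1 <- list(width = 600L, height = 320L, side_span = 220L,
             baseline_row = 130L, iris_thickness = 40L, pupil_gap = 100L)
  g2 <- list(width = 1200L, height = 640L, side_span = 440L,
             baseline_row = 260L, iris_thickness = 80L, pupil_gap = 200L)
  base <- do.call(synthetic_iris_spec,
                  c(g1, list(crypt_amplitude = 8, crypt_frequency = 4,
                             speckle_sigma = 0.05, blur_sigma = 1, seed = 45)))
  doubled <- do.call(synthetic_iris_spec,
                     c(g2, list(crypt_amplitude = 16, crypt_frequency = 4,
                                speckle_sigma = 0.05, blur_sigma = 1, seed = 45)))
  r1 <- render_iris(base); r2 <- render_iris(doubled)
  s1 <- measure_si(r1$image, r1$landmarks, preprocess_cfg = pre_cfg_for(g1))
  s2 <- measure_si(r2$image, r2$landmarks, preprocess_cfg = pre_cfg_for(g2))
  expect_lt(abs(s1$overall_si - s2$overall_si), 0.01)
})
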