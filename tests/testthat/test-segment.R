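test_that("two-valued images are separated exactly, with polarity symmetry", {
  px <- matrix(10, 20, 20)
  px[6:15, 6:15] <- 200
  img <- gray_image(px)
  m_dark <- adaptive_kmeans_binarize(img, segmentation_config(polarity = "dark"))
  m_bright <- adaptive_kmeans_binarize(img, segmentation_config(polarity = "bright"))
  thr <- attr(m_dark, "threshold")
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_identical(m_dark$pixels, px == 10)
  expect_identical(m_bright$pixels, !m_dark$pixels)
})

test_that("histogram 2-means agrees with the exhaustive cut-point oracle", {
  set.seed(31)
  vals <- round(c(rnorm(1e4, 60, 10), rnorm(1e4, 180, 10)))
  vals <- pmin(pmax(vals, 0), 255)
  n <- 142  # 142*142 = 20164 >= 2e4
  px <- matrix(c(vals, rep(60, n * n - length(vals))), n, n)
  img <- gray_image(px)
  # tiny tol: compare the fully converged solution against the oracle
  m <- adaptive_kmeans_binarize(img, segmentation_config(tol = 1e-8,
                                                         max_iter = 1000))
  thr <- attr(m, "threshold")
  h <- image_histogram(img)
  cut <- oracle_best_cut(h)
  # identical induced partition of the occupied gray levels (inside the empty
  # inter-mode gap the within-class SS is flat, so the numeric cut is not
  # unique there)
  occ <- which(h > 0) - 1
  expect_identical(occ <= thr, occ <= cut)
  expect_identical(m$pixels, px <= cut)
})

test_that("binarization rejects constant images", {
  expect_error(adaptive_kmeans_binarize(gray_image(matrix(7, 5, 5))),
               "single gray level")
})

test_that("morphological_clean removes specks, fills holes, bridges gaps", {
  # speck removal with closing off
  px <- matrix(FALSE, 60, 60)
  px[10:34, 10:29] <- TRUE            # 500 px blob
  px[50, 40:42] <- TRUE               # 3 px speck
  cfg <- segmentation_config(min_area = 50, closing_radius = 0)
  out <- morphological_clean(binary_mask(px), cfg)
  expect_false(any(out$pixels[50, ]))
  expect_identical(out$pixels[10:34, 10:29], px[10:34, 10:29])

  # interior hole filling
  sq <- matrix(FALSE, 30, 30)
  sq[5:24, 5:24] <- TRUE
  sq[15, 15] <- FALSE
  out2 <- morphological_clean(binary_mask(sq), cfg)
  expect_true(out2$pixels[15, 15])

  # closing bridges a 1-px gap: two strips become one component
  strips <- matrix(FALSE, 20, 40)
  strips[10, 2:18] <- TRUE
  strips[10, 20:38] <- TRUE
  n_before <- max(oracle_label_components(strips))
  cleaned <- morphological_clean(binary_mask(strips),
                                 segmentation_config(min_area = 10,
                                                     closing_radius = 2))
  n_after <- max(oracle_label_components(cleaned$pixels))
  expect_identical(c(n_before, n_after), c(2L, 1L))
})

test_that("morphological_clean is idempotent and area-monotone", {
  set.seed(32)
  px <- matrix(runif(80 * 80) > 0.6, 80, 80)
  cfg <- segmentation_config(min_area = 30, closing_radius = 2)
  once <- morphological_clean(binary_mask(px), cfg)
  twice <- morphological_clean(once, cfg)
  expect_identical(twice$pixels, once$pixels)
  # every surviving component has area >= min_area
  lab <- oracle_label_components(once$pixels)
  if (max(lab) > 0) expect_true(all(tabulate(lab[lab > 0]) >= 30))
})

test_that("cleaning that leaves nothing is an error", {
  px <- matrix(FALSE, 20, 20)
  px[5, 5] <- TRUE
  expect_error(morphological_clean(binary_mask(px),
                                   segmentation_config(min_area = 50,
                                                       closing_radius = 0)),
               "no iris component")
})

test_that("extract_border traces outer boundaries", {
  # filled rectangle: perimeter pixel count 2*(h + w) - 4
  px <- matrix(FALSE, 30, 40)
  px[11:20, 11:30] <- TRUE
  b <- extract_border(binary_mask(px))
  expect_identical(sum(b$pixels), 2L * (10L + 20L) - 4L)

  # single-pixel-thick curve is its own boundary
  curve <- matrix(FALSE, 20, 20)
  for (i in 1:15) curve[3 + i %/% 3, 2 + i] <- TRUE
  b2 <- extract_border(binary_mask(curve))
  expect_identical(b2$pixels, curve)

  # filled disk: border is one 8-connected component close to the circle
  disk <- matrix(FALSE, 80, 80)
  ctr <- 40.5
  for (r in 1:80) for (c in 1:80)
    if ((r - ctr)^2 + (c - ctr)^2 <= 30^2) disk[r, c] <- TRUE
  b3 <- extract_border(binary_mask(disk))
  expect_identical(max(oracle_label_components(b3$pixels)), 1L)
  idx <- which(b3$pixels, arr.ind = TRUE)
  radii <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2)
  expect_true(all(abs(radii - 30) <= 1.2))
})

test_that("a boundary is its own boundary, and largest-component selection works", {
  px <- matrix(FALSE, 40, 40)
  px[5:20, 5:20] <- TRUE    # area 256
  px[30:33, 30:33] <- TRUE  # area 16
  b <- extract_border(binary_mask(px), keep = 1L)
  expect_false(any(b$pixels[30:33, 30:33]))
  bb <- extract_border(b, keep = 1L)
  expect_identical(bb$pixels, b$pixels)
  b2 <- extract_border(binary_mask(px), keep = 2L)
  expect_true(any(b2$pixels[30:33, 30:33]))
})
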