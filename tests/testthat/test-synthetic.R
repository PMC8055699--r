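test_that("analytic_si: flat curve, trapezoid cross-check, amplitude monotonicity", {
  expect_equal(analytic_si(function(x) rep(50, length(x)), 0, 100,
                           fprime = function(x) rep(0, length(x))), 1.0)

  # one full sine period: quadrature vs dense trapezoid summation (1e6 points)
  L <- 200; k <- 1; A <- L / (2 * pi * k)
  f <- function(x) A * sin(2 * pi * k * x / L)
  fp <- function(x) A * 2 * pi * k / L * cos(2 * pi * k * x / L)
  si <- analytic_si(f, 0, L, fprime = fp)
  xs <- seq(0, L, length.out = 1e6)
  arc_trap <- sum(sqrt(diff(xs)^2 + diff(f(xs))^2))
  expect_equal(si, L / arc_trap, tolerance = 1e-6)

  # SI strictly decreasing in amplitude
  sis <- vapply(seq(0, 20, by = 2), function(A2) {
    analytic_si(function(x) A2 * sin(2 * pi * x / L), 0, L,
                fprime = function(x) A2 * 2 * pi / L * cos(2 * pi * x / L))
  }, numeric(1))
  expect_true(all(diff(sis) < 0))
  expect_error(analytic_si(function(x) rep(NaN, length(x)), 0, 1), "finite")
})

test_that("synthetic truth: SI in (0,1], equal to 1 iff amplitude 0", {
  for (A in c(0, 3, 9)) {
    sp <- synthetic_iris_spec(crypt_amplitude = A, seed = 50 + A)
    tr <- render_iris(sp)$truth
    sis <- c(tr$true_si_nasal, tr$true_si_temporal, tr$true_si_overall)
    expect_true(all(sis > 0 & sis <= 1))
    if (A == 0) expect_equal(unname(sis), c(1, 1, 1))
    else expect_true(all(sis < 1))
  }
})

test_that("rendering is deterministic and respects spec invariants", {
  sp <- quick_flat_spec(seed = 51)
  r1 <- render_iris(sp); r2 <- render_iris(sp)
  expect_identical(r1$image$pixels, r2$image$pixels)
  expect_identical(r1$truth$true_si_overall, r2$truth$true_si_overall)

  sp2 <- quick_flat_spec(seed = 52)
  expect_false(identical(render_iris(sp2)$image$pixels, r1$image$pixels))

  expect_error(synthetic_iris_spec(baseline_row = 600, iris_thickness = 60),
               "out of frame")
  expect_error(synthetic_iris_spec(crypt_amplitude = -1), "crypt_amplitude")
  expect_error(synthetic_iris_spec(side_span = 600, pupil_gap = 200), "width")
})

test_that("amplitude_for_si inverts the analytic SI", {
  sp <- synthetic_iris_spec(seed = 53)
  for (target in c(0.98, 0.90, 0.84)) {
    a <- amplitude_for_si(target, sp)
    sp2 <- sp; sp2$crypt_amplitude <- a
    expect_equal(render_iris(sp2)$truth$true_si_overall, target,
                 tolerance = 1e-3)
  }
  expect_equal(amplitude_for_si(1, sp), 0)
  expect_error(amplitude_for_si(0.2, sp), "not reachable")
})

test_that("generate_cohort hits the requested inter-eye effect in analytic truth", {
  # null case: no systematic inter-eye difference
  co0 <- generate_cohort(n_subjects = 40, fu_effect = 0, seed = 54)
  t0 <- co0$truth
  w0 <- reshape(t0[, c("subject", "group", "eye", "true_si_overall")],
                idvar = c("subject", "group"), timevar = "eye",
                direction = "wide")
  d0 <- w0$true_si_overall.OD - w0$true_si_overall.OS
  expect_lt(abs(mean(d0)), 0.01)

  # fu_effect 0.03, n=11: mean |inter-eye| truth difference in [0.02, 0.04]
  co <- generate_cohort(n_subjects = 11, fu_effect = 0.03, seed = 55)
  tr <- co$truth
  w <- reshape(tr[, c("subject", "group", "eye", "true_si_overall")],
               idvar = c("subject", "group"), timevar = "eye",
               direction = "wide")
  dfu <- abs(w$true_si_overall.OD - w$true_si_overall.OS)[w$group == "FU"]
  expect_gte(mean(dfu), 0.02)
  expect_lte(mean(dfu), 0.04)

  # determinism: identical tables on re-run
  co_again <- generate_cohort(n_subjects = 11, fu_effect = 0.03, seed = 55)
  expect_identical(co$truth, co_again$truth)
})

test_that("cohort effect size converges to fu_effect at large n", {
  co <- generate_cohort(n_subjects = 200, fu_effect = 0.03, seed = 56)
  tr <- co$truth
  w <- reshape(tr[, c("subject", "group", "eye", "true_si_overall")],
               idvar = c("subject", "group"), timevar = "eye",
               direction = "wide")
  d <- abs(w$true_si_overall.OD - w$true_si_overall.OS)
  expect_lt(abs(mean(d[w$group == "FU"]) - 0.03), 0.005)
})
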