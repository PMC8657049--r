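test_that("clearance scaling matches a stepwise hand unit conversion", {
  ind <- fixture_individual(fub = 0.05, clint = 10)
  ind$q_gut <- 64; ind$q_hepatic_artery <- 26  # hepatic blood flow 90 L/h
  chem <- fixture_chemical()
  p <- scale_clearances(ind, chem)
  # by hand: 10 uL/min/10^6 cells * 110 x10^6 cells/g * 1800 g = 1.98e6 uL/min
  # -> * 60 min/h * 1e-6 L/uL = 118.8 L/h whole-liver intrinsic clearance
  clint_whole_hand <- 10 * 110 * 1800 * 60 / 1e6
  expect_equal(p$clint_whole, clint_whole_hand, tolerance = 1e-12)
  cl_h_hand <- 90 * (0.05 * clint_whole_hand) / (90 + 0.05 * clint_whole_hand)
  expect_equal(p$cl_hepatic, cl_h_hand, tolerance = 1e-12)
  expect_equal(p$cl_renal, ind$gfr * 0.05, tolerance = 1e-12)
  # well-stirred bounds
  expect_lt(p$cl_hepatic, 0.05 * clint_whole_hand)
  expect_lt(p$cl_hepatic, 90)
})

test_that("well-stirred limits: fully bound chemical and infinite intrinsic clearance", {
  chem <- fixture_chemical()
  nearly_bound <- scale_clearances(fixture_individual(fub = 1e-12), chem)
  expect_lt(nearly_bound$cl_hepatic, 1e-9)
  expect_lt(nearly_bound$cl_renal, 1e-9)
  huge <- scale_clearances(fixture_individual(clint = 1e9), chem)
  q_h <- huge$flows[["gut"]] + huge$flows[["hepatic_artery"]]
  expect_equal(huge$cl_hepatic, q_h, tolerance = 1e-4)  # flow-limited asymptote
})

test_that("steady state is zero at zero dose and exactly linear in dose", {
  chem <- fixture_chemical()
  ind <- fixture_individual()
  expect_equal(steady_state_css(scale_clearances(ind, chem, dose = 0))$css_liver, 0)
  css1 <- steady_state_css(scale_clearances(ind, chem, dose = 1))$css_liver
  css2 <- steady_state_css(scale_clearances(ind, chem, dose = 2))$css_liver
  expect_equal(css2, 2 * css1, tolerance = 1e-12)
  css_half <- steady_state_css(scale_clearances(ind, chem, dose = 0.5))$css_liver
  expect_equal(css_half, 0.5 * css1, tolerance = 1e-12)
  expect_gt(css1, 0)
})

test_that("mass is conserved by construction: column sums equal elimination", {
  p <- scale_clearances(fixture_individual(), fixture_chemical())
  sys <- pbtk_matrix(p)
  resid <- colSums(sys$A) + sys$elim
  expect_lt(max(abs(resid)) / max(abs(sys$A)), 1e-12)
  # only liver and kidney eliminate
  expect_true(all(sys$elim[setdiff(names(sys$elim), c("liver", "kidney"))] == 0))
  expect_gt(sys$elim[["liver"]], 0)
})

test_that("analytic steady state agrees with the ODE oracle", {
  p <- scale_clearances(fixture_individual(), fixture_chemical())
  a <- steady_state_css(p)
  o <- integrate_to_steady_state(p, max_days = 2e5)
  expect_equal(o$method, "ode")
  expect_lt(abs(a$css_liver - o$css_liver) / a$css_liver, 1e-3)
  expect_lt(abs(a$css_plasma - o$css_plasma) / a$css_plasma, 1e-3)
  # zero-dose trajectory stays identically zero
  z <- integrate_to_steady_state(scale_clearances(fixture_individual(), fixture_chemical(), dose = 0))
  expect_identical(unname(z$amounts), rep(0, 7))
})

test_that("Css decreases with intrinsic clearance and with unbound fraction", {
  chem <- fixture_chemical()
  css_at <- function(clint, fub) {
    steady_state_css(scale_clearances(fixture_individual(fub = fub, clint = clint), chem))$css_liver
  }
  clints <- c(0.5, 2, 8, 32)
  expect_true(all(diff(vapply(clints, css_at, numeric(1), fub = 0.05)) < 0))
  fubs <- c(0.01, 0.05, 0.2, 0.8)
  expect_true(all(diff(vapply(fubs, function(f) css_at(10, f), numeric(1))) < 0))
})

test_that("uM and mg/L liver concentrations round-trip through molecular weight", {
  p <- scale_clearances(fixture_individual(), fixture_chemical(mw = 326.3))
  res <- steady_state_css(p)
  css_mg_per_l <- res$amounts[["liver"]] / p$volumes[["liver"]]
  expect_equal(res$css_liver * 326.3 / 1000, css_mg_per_l, tolerance = 1e-12)
})

test_that("population Css: degenerate population and percentile monotonicity", {
  chem <- fixture_chemical()
  pop <- sample_population(fixed_population_spec(n = 6))
  d <- population_css(pop, chem)
  expect_s3_class(d, "css_distribution")
  expect_equal(length(unique(round(d$samples, 12))), 1L)
  expect_true(all(abs(d$percentiles - d$samples[1]) / d$samples[1] < 1e-12))

  spec <- default_population_spec("adults", n = 200, seed = 4L)
  d2 <- population_css(sample_population(spec), chem)
  expect_true(all(diff(d2$percentiles) >= 0))
  expect_equal(unname(d2$percentiles["P50"]), median(d2$samples))
})

test_that("per-individual solver failures are reported with the individual index", {
  chem <- fixture_chemical()
  pop <- sample_population(fixed_population_spec(n = 3))
  pop$liver_mass[2] <- -1
  expect_error(population_css(pop, chem), "individual 2")
  expect_error(population_css(pop[0, ], chem), "empty")
})

test_that("css_distribution rejects invalid samples and recomputes percentiles", {
  expect_error(css_distribution("X", "adults", c(1, -2)), "positive")
  expect_error(css_distribution("X", "adults", numeric(0)), "at least one")
  d <- css_distribution("X", "adults", c(3, 1, 2), ranks = c(25, 50, 75))
  expect_equal(unname(d$percentiles), unname(quantile(c(1, 2, 3), c(0.25, 0.5, 0.75), type = 7)))
})

test_that("analytic and ODE solutions agree over random physiological draws", {
  set.seed(42)
  for (i in 1:10) {
    draw <- random_pbtk_draw()
    p <- scale_clearances(draw$individual, draw$chemical)
    a <- steady_state_css(p)
    o <- integrate_to_steady_state(p, max_days = 2e5)
    expect_lt(abs(a$css_liver - o$css_liver) / a$css_liver, 1e-3)
  }
})
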