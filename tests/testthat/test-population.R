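test_that("all-fixed spec yields n identical individuals at the location values", {
  pop <- sample_population(fixed_population_spec(n = 7))
  expect_equal(nrow(pop), 7L)
  expect_true(all(pop$body_weight == 70))
  expect_true(all(pop$liver_mass == 0.0257 * 70))
  expect_true(all(pop$q_cardiac == 13.6 * 70^0.75))
  expect_equal(length(unique(pop$fub)), 1L)
  expect_equal(length(unique(pop$clint)), 1L)
})

test_that("sampling is a pure function of (spec, seed) and preserves caller RNG", {
  spec <- default_population_spec("adults", n = 50, seed = 7L)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  pop1 <- sample_population(spec)
  pop2 <- sample_population(spec)
  expect_identical(pop1, pop2)
  after <- runif(1)
  expect_identical(before, after)  # caller RNG untouched by sampling

  spec2 <- spec
  spec2$seed <- 8L
  expect_false(identical(sample_population(spec2)$body_weight, pop1$body_weight))
})

test_that("lognormal body weight reproduces its geometric mean at large n", {
  spec <- default_population_spec("adults", n = 10000, seed = 3L)
  pop <- sample_population(spec)
  gm <- exp(mean(log(pop$body_weight)))
  expect_lt(abs(gm - 70) / 70, 0.02)
})

test_that("sampled parameter percentiles are monotone in rank", {
  spec <- default_population_spec("children", n = 500, seed = 11L)
  pop <- sample_population(spec)
  for (col in c("body_weight", "liver_mass", "q_cardiac", "gfr", "fub", "clint")) {
    q <- unname(quantile(pop[[col]], c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7))
    expect_true(all(diff(q) >= 0), info = col)
  }
})

test_that("individuals converge to the location vector as variance shrinks", {
  spec <- default_population_spec("adults", n = 20, seed = 5L)
  for (p in names(spec$distributions)) spec$distributions[[p]]$scale <-
    spec$distributions[[p]]$scale * 1e-6
  pop <- sample_population(spec)
  expect_lt(max(abs(pop$body_weight - 70) / 70), 1e-4)
  expect_lt(max(abs(pop$fub - 0.05) / 0.05), 1e-4)
})

test_that("default specs encode the child/adult physiological contrast", {
  kids <- default_population_spec("children")
  grow <- default_population_spec("adults")
  expect_gt(grow$distributions$body_weight$location,
            kids$distributions$body_weight$location)
  # per-kg intrinsic metabolic capacity (clint x liver fraction) higher in children
  kid_cap <- kids$distributions$clint$location * kids$distributions$liver_fraction$location
  adu_cap <- grow$distributions$clint$location * grow$distributions$liver_fraction$location
  expect_gt(kid_cap, adu_cap)
  expect_error(default_population_spec("infants"))
})

test_that("blood-flow balance holds by construction", {
  pop <- sample_population(default_population_spec("adults", n = 200, seed = 2L))
  expect_true(check_flow_balance(pop, tol = 1e-9))
})

test_that("degenerate descriptors are rejected; impossible redraws error out", {
  expect_error(dist_descriptor("fixed", 1, 0.1), "scale = 0")
  expect_error(dist_descriptor("lognormal", 1, -1), "scale")
  expect_error(dist_descriptor("logitnormal", 1.5, 0.1), "location")
  spec <- fixed_population_spec(n = 10)
  spec$distributions$clint <- dist_descriptor("normal-truncated-positive", -50, 0.01)
  expect_error(sample_population(spec), "positive value within")
  bad <- fixed_population_spec(n = 3)
  bad$distributions$fub <- NULL
  expect_error(
    population_spec("adults", 3, 1L, bad$distributions),
    "fub"
  )
})

test_that("population specs round-trip through YAML", {
  spec <- default_population_spec("children", n = 42, seed = 9L)
  path <- tempfile(fileext = ".yaml")
  write_population_spec(spec, path)
  back <- read_population_spec(path)
  expect_equal(back$age_group, "children")
  expect_equal(back$n, 42L)
  expect_identical(sample_population(back), sample_population(spec))
})
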