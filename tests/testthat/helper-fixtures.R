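# Shared fixtures built in code: a reference adult individual, a TPHP-like
# chemical, and random-but-physiological parameter draws for property tests.

fixture_individual <- function(fub = 0.05, clint = 10, bw = 70) {
  q_cardiac <- 330 * (bw / 70)^0.75
  list(
    body_weight = bw,
    liver_mass = 1.8 * bw / 70,
    hepatocellularity = 110,
    q_cardiac = q_cardiac,
    q_gut = 0.160 * q_cardiac,
    q_hepatic_artery = 0.065 * q_cardiac,
    q_kidney = 0.190 * q_cardiac,
    q_rest = 0.585 * q_cardiac,
    gfr = 6.8 * (bw / 70)^0.75,
    fub = fub,
    clint = clint
  )
}

fixture_chemical <- function(mw = 326.3, k = c(gut = 8, liver = 12, lung = 4,
                                               kidney = 6, rest = 5),
                             clint_default = 6, fub_default = 0.05, fabs = 1) {
  chemical("TPHP", "triphenyl phosphate", molecular_weight = mw,
           clint_default = clint_default, fub_default = fub_default,
           partition_coefficients = k, fabs = fabs)
}

# One random physiologically plausible (individual, chemical) pair.
random_pbtk_draw <- function() {
  bw <- runif(1, 10, 100)
  q_cardiac <- 13.6 * bw^0.75 * runif(1, 0.7, 1.4)
  ind <- list(
    body_weight = bw,
    liver_mass = runif(1, 0.02, 0.04) * bw,
    hepatocellularity = runif(1, 80, 150),
    q_cardiac = q_cardiac,
    q_gut = 0.160 * q_cardiac,
    q_hepatic_artery = 0.065 * q_cardiac,
    q_kidney = 0.190 * q_cardiac,
    q_rest = 0.585 * q_cardiac,
    gfr = 0.28 * bw^0.75 * runif(1, 0.6, 1.5),
    fub = 10^runif(1, -3, -0.3),
    clint = 10^runif(1, -1, 1.5)
  )
  chem <- chemical("X", "random test chemical",
                   molecular_weight = runif(1, 200, 500),
                   clint_default = ind$clint,
                   fub_default = min(ind$fub, 0.99),
                   partition_coefficients = c(gut = runif(1, 1, 15), liver = runif(1, 1, 15),
                                              lung = runif(1, 1, 15), kidney = runif(1, 1, 15),
                                              rest = runif(1, 1, 15)),
                   fabs = runif(1, 0.5, 1))
  list(individual = ind, chemical = chem)
}

# A tiny all-fixed population spec: every individual identical.
fixed_population_spec <- function(n = 5, age_group = "adults", seed = 1L) {
  fixed <- function(loc) dist_descriptor("fixed", loc, 0)
  population_spec(
    age_group = age_group, n = n, seed = seed,
    distributions = list(
      body_weight = fixed(70), liver_fraction = fixed(0.0257),
      hepatocellularity = fixed(110), cardiac_allometric = fixed(13.6),
      gfr_allometric = fixed(0.28), fub = fixed(0.05), clint = fixed(8)
    )
  )
}

write_csv_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
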