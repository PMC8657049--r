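make_css <- function(samples, chemical_id = "TPHP", age_group = "adults",
                     ranks = c(2.5, 25, 50, 75, 97.5)) {
  css_distribution(chemical_id, age_group, samples, dose_ref = 1, ranks = ranks)
}

test_that("reverse dosimetry identity: AC50 equal to Css gives HED = dose_ref", {
  css <- make_css(rep(5, 11))
  assay <- list(assay_name = "a", chemical_id = "TPHP", ac50 = 5)
  hed <- hed_from_assay(assay, css, ranks = c(2.5, 50, 97.5))
  expect_true(all(hed$samples == 1))
  expect_true(all(hed$percentiles == 1))
})

test_that("HED median equals ac50 / median(Css) for odd sample counts", {
  set.seed(1)
  css <- make_css(rlnorm(101, log(20), 0.5))
  assay <- list(assay_name = "a", chemical_id = "TPHP", ac50 = 5.43)
  hed <- hed_from_assay(assay, css, ranks = c(25, 50, 75))
  expect_equal(unname(hed$percentiles["P50"]), 5.43 / median(css$samples), tolerance = 1e-12)
})

test_that("HED percentiles are scale-equivariant in the Css samples", {
  set.seed(2)
  x <- rlnorm(200, log(10), 0.6)
  assay <- list(assay_name = "a", chemical_id = "TPHP", ac50 = 1.26)
  h1 <- hed_from_assay(assay, make_css(x), ranks = c(2.5, 50, 97.5))
  h3 <- hed_from_assay(assay, make_css(3 * x), ranks = c(2.5, 50, 97.5))
  expect_equal(unname(h3$percentiles), unname(h1$percentiles) / 3, tolerance = 1e-12)
})

test_that("chemical mismatch between assay and Css distribution errors", {
  css <- make_css(rep(5, 3), chemical_id = "TDCPP")
  expect_error(hed_from_assay(list(assay_name = "a", chemical_id = "TPHP", ac50 = 1), css),
               "mismatch")
})

test_that("printed-summary pathway flips percentile ranks through the reciprocal", {
  css_pct <- c(P2.5 = 14.6, P50 = 58.66, P97.5 = 481.66)
  hed <- hed_from_css_percentiles(5.01, css_pct)
  expect_named(hed, c("P2.5", "P50", "P97.5"))
  expect_equal(unname(hed["P50"]), 5.01 / 58.66)   # median maps to median
  expect_equal(unname(hed["P2.5"]), 5.01 / 481.66) # low HED from high Css
  expect_equal(unname(hed["P97.5"]), 5.01 / 14.6)
  expect_true(all(diff(hed) > 0))
})

test_that("pooled merge behaves like order statistics over combined samples", {
  ranks <- c(2.5, 50, 97.5)
  one <- hed_distribution("TPHP", "adults", "a1", rlnorm(1000, 0, 0.3), ranks = ranks)
  self_merge <- merge_assays(list(one, one), ranks = ranks)
  # duplicating every sample leaves the median exactly invariant; other
  # interpolated percentiles shift by at most one order-statistic gap
  expect_equal(unname(self_merge$percentiles["P50"]), unname(one$percentiles["P50"]),
               tolerance = 1e-12)
  expect_equal(self_merge$percentiles, one$percentiles, tolerance = 0.02)
  expect_equal(self_merge$assay_name, "overall")

  lo <- hed_distribution("TPHP", "adults", "a1", rep(0.01, 50), ranks = ranks)
  hi <- hed_distribution("TPHP", "adults", "a2", rep(1.0, 50), ranks = ranks)
  both <- merge_assays(list(lo, hi), ranks = ranks)
  med <- unname(both$percentiles["P50"])
  expect_gte(med, 0.01)
  expect_lte(med, 1.0)
})

test_that("merging four assay distributions lands the overall median inside the per-assay band", {
  set.seed(3)
  css <- make_css(rlnorm(500, log(25.34), 0.5), chemical_id = "TDCPP", age_group = "children")
  ac50s <- c(5.01, 4.62, 0.39, 0.36)
  ranks <- c(2.5, 50, 97.5)
  heds <- lapply(seq_along(ac50s), function(i) {
    hed_from_assay(list(assay_name = paste0("a", i), chemical_id = "TDCPP", ac50 = ac50s[i]),
                   css, ranks = ranks)
  })
  overall <- merge_assays(heds, ranks = ranks)
  per_medians <- vapply(heds, function(h) unname(h$percentiles["P50"]), numeric(1))
  ov <- unname(overall$percentiles["P50"])
  expect_gt(ov, min(per_medians))
  expect_lt(ov, max(per_medians))
})

test_that("merge rejects mixed chemicals, mixed age groups and unequal pools", {
  r <- c(50)
  a <- hed_distribution("TPHP", "adults", "a1", rep(1, 10), ranks = r)
  b <- hed_distribution("TDCPP", "adults", "a2", rep(1, 10), ranks = r)
  c_ <- hed_distribution("TPHP", "children", "a3", rep(1, 10), ranks = r)
  d <- hed_distribution("TPHP", "adults", "a4", rep(1, 7), ranks = r)
  expect_error(merge_assays(list(a, b), ranks = r), "chemicals")
  expect_error(merge_assays(list(a, c_), ranks = r), "age group")
  expect_error(merge_assays(list(a, d), ranks = r), "equal sample counts")
})

test_that("median-of-medians merge is available as a non-default alternative", {
  r <- c(25, 50, 75)
  a <- hed_distribution("TPHP", "adults", "a1", rep(0.1, 9), ranks = r)
  b <- hed_distribution("TPHP", "adults", "a2", rep(0.2, 9), ranks = r)
  c_ <- hed_distribution("TPHP", "adults", "a3", rep(0.4, 9), ranks = r)
  m <- merge_assays(list(a, b, c_), method = "median_of_medians", ranks = r)
  expect_equal(unname(m$percentiles["P50"]), 0.2)
})

test_that("animal HED is POD times DAF", {
  expect_equal(animal_hed(list(pod_value = 105, daf = 0.24)), 25.2)
  expect_equal(animal_hed(list(pod_value = 5, daf = 0.26)), 1.3)
  expect_equal(animal_hed(list(pod_value = 7, daf = 1)), 7)  # identity factor
  expect_error(animal_hed(list(pod_value = 5, daf = 1.5)), "daf")
})

test_that("extreme percentile ranks at modest n trigger an estimator warning", {
  expect_warning(
    hed_distribution("TPHP", "adults", "a1", rlnorm(100), ranks = c(0.1, 50, 99.9)),
    "n = 5000"
  )
  expect_silent(hed_distribution("TPHP", "adults", "a1", rlnorm(100), ranks = c(2.5, 50, 97.5)))
})
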