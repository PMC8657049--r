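test_that("EDI CSV reading: published Latvia row, missing cells, duplicates", {
  path <- write_csv_fixture(c(
    "region,age_group,chemical_id,edi_ng_kg_day,reference",
    "Latvia,adults,TPHP,24,B11",
    "Latvia,children,TPHP,560,B11",
    "Latvia,adults,TDCPP,67.4,B11",
    "Latvia,children,TDCPP,1570,B11",
    "North China,adults,TPHP,0.42,B34",
    "North China,children,TPHP,-,B34",
    "North China,adults,TDCPP,0.33,B34",
    "North China,children,TDCPP,-,B34"
  ))
  expect_message(tab <- read_edi_table(path), "skipping 2")
  expect_equal(nrow(tab), 6L)
  latvia <- tab[tab$region == "Latvia", ]
  expect_setequal(latvia$edi_median, c(24, 560, 67.4, 1570))
  expect_equal(tab$edi_median[tab$region == "Latvia" & tab$age_group == "children" &
                                tab$chemical_id == "TDCPP"], 1570)
  # only adult records exist for North China
  expect_equal(sort(unique(tab$age_group[tab$region == "North China"])), "adults")

  empty <- write_csv_fixture("region,age_group,chemical_id,edi_ng_kg_day,reference")
  expect_equal(nrow(read_edi_table(empty)), 0L)

  expect_error(
    edi_table(c("A", "A"), c("adults", "adults"), c("TPHP", "TPHP"), c(1, 2)),
    "duplicate"
  )
})

test_that("point MOE applies the mg -> ng conversion and matches hand arithmetic", {
  # published overall child TDCPP HED vs Latvian children EDI
  moe <- moe_point(0.042, 1570)
  expect_equal(moe, 0.042 * 1e6 / 1570, tolerance = 1e-12)
  expect_equal(moe, 26.75, tolerance = 0.01)
  expect_equal(classify_moe(moe), "moderate")
  # animal TPHP HED vs Latvia adults: deep inside the low tier
  moe2 <- moe_point(25.2, 24)
  expect_equal(moe2, 1.05e6)
  expect_equal(classify_moe(moe2), "low")
  # numerically equal doses after conversion sit on the high/moderate boundary
  expect_equal(moe_point(1570 / 1e6, 1570), 1)
  expect_error(moe_point(-1, 10), "positive")
  expect_error(moe_point(1, 0), "positive")
})

test_that("tier thresholds are honoured exactly and partition the positive axis", {
  expect_equal(classify_moe(1), "high")
  expect_equal(classify_moe(100), "low")
  expect_equal(classify_moe(99.999), "moderate")
  expect_equal(classify_moe(1 + 1e-12), "moderate")
  set.seed(10)
  moes <- 10^runif(200, -3, 8)
  tiers <- classify_moe(moes)
  expect_true(all(tiers %in% c("high", "moderate", "low")))
  expect_identical(tiers == "high", moes <= 1)
  expect_identical(tiers == "low", moes >= 100)
})

test_that("probabilistic assessment pairs HED rank p with MOE rank p", {
  ranks <- c(0.1, 1, 2.5, 50, 97.5, 99, 99.9)
  set.seed(4)
  hed <- suppressWarnings(
    hed_distribution("TPHP", "adults", "overall", rlnorm(1000, log(0.1), 0.7), ranks = ranks)
  )
  edi <- list(region = "Germany", age_group = "adults", chemical_id = "TPHP", edi_median = 0.21)
  a <- probabilistic_assessment(hed, edi)
  expect_equal(unname(a$moe_percentiles),
               unname(hed$percentiles * 1e6 / 0.21), tolerance = 1e-12)
  expect_true(all(diff(a$moe_percentiles) >= 0))
  expect_named(a$intervals, c("central", "broad", "extreme"))
  expect_equal(names(a$intervals$extreme), c("P0.1", "P99.9"))
  # tiers consistent with thresholds at every rank
  expect_identical(unname(a$tier_per_percentile),
                   classify_moe(as.numeric(a$moe_percentiles)))
})

test_that("degenerate HED collapses all intervals; EDI scaling divides MOE", {
  ranks <- c(0.1, 1, 2.5, 50, 97.5, 99, 99.9)
  hed <- suppressWarnings(
    hed_distribution("TDCPP", "children", "overall", rep(0.042, 100), ranks = ranks)
  )
  edi <- list(region = "Latvia", age_group = "children", chemical_id = "TDCPP",
              edi_median = 1570)
  a <- probabilistic_assessment(hed, edi)
  expect_equal(length(unique(round(unlist(a$intervals), 9))), 1L)

  edi10 <- edi; edi10$edi_median <- 15700
  a10 <- probabilistic_assessment(hed, edi10)
  expect_equal(unname(a10$moe_percentiles), unname(a$moe_percentiles) / 10, tolerance = 1e-12)
})

test_that("larger EDI never increases any MOE percentile", {
  ranks <- c(2.5, 50, 97.5)
  set.seed(5)
  hed <- hed_distribution("TPHP", "children", "overall", rlnorm(300, log(0.3), 0.5),
                          ranks = ranks)
  edis <- c(0.5, 5, 50, 500)
  moes <- vapply(edis, function(e) {
    a <- probabilistic_assessment(hed, list(region = "r", age_group = "children",
                                            chemical_id = "TPHP", edi_median = e))
    as.numeric(a$moe_percentiles)
  }, numeric(length(ranks)))
  for (r in seq_along(ranks)) expect_true(all(diff(moes[r, ]) < 0))
})

test_that("assessment rejects mismatched chemical or age group", {
  hed <- hed_distribution("TPHP", "adults", "overall", rep(1, 10), ranks = 50)
  expect_error(probabilistic_assessment(
    hed, list(region = "r", age_group = "adults", chemical_id = "TDCPP", edi_median = 1)
  ), "chemical mismatch")
  expect_error(probabilistic_assessment(
    hed, list(region = "r", age_group = "children", chemical_id = "TPHP", edi_median = 1)
  ), "age-group mismatch")
})
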