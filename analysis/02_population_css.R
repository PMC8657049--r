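#!/usr/bin/env Rscript
# Step 2: Monte Carlo population liver Css at 1 mg/kg/day.
#
# Samples the children and adult virtual populations for each chemical and
# solves the analytic PBTK steady state per individual. Writes the per-
# individual samples (results/css_samples.csv) and a percentile summary
# next to the published values (results/css_summary.csv).

library(operisk)

bundle <- read_bundle("results/fixtures")
ref <- bundle$reference_css
ranks <- c(2.5, 25, 50, 75, 97.5)

samples <- list()
summary_rows <- list()
for (id in names(bundle$chemicals)) {
  for (ag in names(bundle$population_specs)) {
    spec <- population_spec_for_chemical(bundle$population_specs[[ag]], bundle$chemicals[[id]])
    pop <- sample_population(spec)
    d <- population_css(pop, bundle$chemicals[[id]], dose = 1, ranks = ranks)
    samples[[paste(id, ag, sep = ".")]] <-
      data.frame(chemical_id = id, age_group = ag, css_uM = d$samples)
    pub <- ref[ref$chemical_id == id & ref$age_group == ag, ]
    summary_rows[[paste(id, ag, sep = ".")]] <- data.frame(
      chemical_id = id, age_group = ag, n = length(d$samples),
      t(round(d$percentiles, 3)),
      published_P50 = pub$P50,
      median_rel_err = round((d$percentiles[["P50"]] - pub$P50) / pub$P50, 3),
      check.names = FALSE
    )
    message(sprintf("%s / %-8s median Css %6.2f uM (published %6.2f; %+.0f%%)",
                    id, ag, d$percentiles[["P50"]], pub$P50,
                    100 * (d$percentiles[["P50"]] - pub$P50) / pub$P50))
  }
}

css_summary <- do.call(rbind, summary_rows)
write.csv(do.call(rbind, samples), "results/css_samples.csv", row.names = FALSE)
write.csv(css_summary, "results/css_summary.csv", row.names = FALSE)

stopifnot(all(abs(css_summary$median_rel_err) < 0.25))
message("all four medians within the 25% calibration diagnostic; ",
        "percentile spreads are narrower than the published survey-based ones by design")
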