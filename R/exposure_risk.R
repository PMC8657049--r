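# Exposure and risk: estimated daily intake (EDI) tables, margin of
# exposure (MOE = HED / EDI, with HED converted mg -> ng so both published
# units can be used verbatim), the three-tier concern classification and
# probabilistic MOE assessments per population.

EDI_COLUMNS <- c("region", "age_group", "chemical_id", "edi_ng_kg_day", "reference")

#' Construct and validate an EDI table
#'
#' @param region Character vector of region labels.
#' @param age_group `"children"` or `"adults"` per record.
#' @param chemical_id Chemical identifiers.
#' @param edi_median Median estimated daily intakes in ng/kg-bw/day (> 0),
#'   computed with high dust-ingestion rates.
#' @param reference Citation tags.
#' @return A `data.frame` of class `edi_table`; `(region, age_group,
#'   chemical_id)` must be unique.
#' @export
edi_table <- function(region, age_group, chemical_id, edi_median,
                      reference = rep("", length(region))) {
  df <- data.frame(
    region = as.character(region),
    age_group = as.character(age_group),
    chemical_id = as.character(chemical_id),
    edi_median = as.numeric(edi_median),
    reference = as.character(reference),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(!df$age_group %in% c("children", "adults"))) {
      stopf("age_group must be 'children' or 'adults'")
    }
    if (any(!is.finite(df$edi_median) | df$edi_median <= 0)) stopf("edi_median must be positive")
    key <- paste(df$region, df$age_group, df$chemical_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[which(duplicated(key))[1], ]
      stopf("duplicate EDI record for (%s, %s, %s)", d$region, d$age_group, d$chemical_id)
    }
  }
  class(df) <- c("edi_table", "data.frame")
  df
}

#' Read an EDI table from CSV
#'
#' Expects columns `region`, `age_group`, `chemical_id`, `edi_ng_kg_day`,
#' `reference`. Cells whose EDI is `"-"` (not surveyed) are skipped with a
#' message; duplicated `(region, age_group, chemical)` keys are an error.
#'
#' @param path Path to the CSV file.
#' @return An [edi_table()] with one record per non-missing cell.
#' @export
read_edi_table <- function(path) {
  if (!file.exists(path)) stopf("EDI table not found: '%s'", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(EDI_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stopf("EDI table '%s' is missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(edi_table(character(), character(), character(), numeric(), character()))
  }
  missing_cell <- trimws(raw$edi_ng_kg_day) %in% c("-", "", "NA") | is.na(raw$edi_ng_kg_day)
  if (any(missing_cell)) {
    message(sprintf("read_edi_table: skipping %d record(s) without a surveyed EDI (marked '-')",
                    sum(missing_cell)))
    raw <- raw[!missing_cell, , drop = FALSE]
  }
  val <- suppressWarnings(as.numeric(raw$edi_ng_kg_day))
  bad <- which(is.na(val))
  if (length(bad)) {
    stopf("'%s' row %d: EDI value '%s' is not numeric", path, bad[1], raw$edi_ng_kg_day[bad[1]])
  }
  edi_table(raw$region, raw$age_group, raw$chemical_id, val, raw$reference)
}

#' Point margin of exposure
#'
#' `MOE = HED / EDI`, dimensionless, with the HED converted from mg/kg/day
#' to ng/kg/day (factor 10^6) so published HED and EDI tables can be used
#' in their native units.
#'
#' @param hed HED in mg/kg/day (> 0); vectorised.
#' @param edi EDI in ng/kg-bw/day (> 0).
#' @return Dimensionless MOE.
#' @export
moe_point <- function(hed, edi) {
  if (any(!is.finite(hed) | hed <= 0)) stopf("hed must be positive")
  if (any(!is.finite(edi) | edi <= 0)) stopf("edi must be positive")
  (hed * 1e6) / edi
}

#' Three-tier MOE concern classification
#'
#' `"high"` concern iff MOE <= 1, `"moderate"` iff 1 < MOE < 100, `"low"`
#' iff MOE >= 100; the boundaries are honoured exactly.
#'
#' @param moe Positive MOE values; vectorised.
#' @return Character vector of tiers.
#' @export
classify_moe <- function(moe) {
  if (any(!is.finite(moe) | moe <= 0)) stopf("moe must be positive")
  ifelse(moe <= 1, "high", ifelse(moe < 100, "moderate", "low"))
}

#' Probabilistic MOE assessment for one population and region
#'
#' Pairs the HED percentile at rank p with the population's median EDI to
#' give the MOE percentile at rank p, assigns a concern tier to every rank,
#' and assembles the three reporting bands P2.5--P97.5, P1--P99 and
#' P0.1--P99.9. EDI enters as a point value; all variability comes from the
#' HED distribution.
#'
#' @param hed A [hed_distribution()].
#' @param edi One row of an [edi_table()] for the same chemical and age
#'   group.
#' @return A list of class `moe_assessment` with `moe_percentiles`,
#'   `tier_per_percentile` and `intervals` (`central`, `broad`, `extreme`).
#' @export
probabilistic_assessment <- function(hed, edi) {
  stopifnot(inherits(hed, "hed_distribution"))
  e <- as.list(edi)
  if (!identical(as.character(e$chemical_id), as.character(hed$chemical_id))) {
    stopf("chemical mismatch: HED is for '%s' but EDI is for '%s'",
          hed$chemical_id, e$chemical_id)
  }
  if (!identical(as.character(e$age_group), as.character(hed$age_group))) {
    stopf("age-group mismatch: HED is for '%s' but EDI is for '%s'",
          hed$age_group, e$age_group)
  }
  moe <- moe_point(hed$percentiles, e$edi_median)
  band <- function(lo, hi) {
    nm <- rank_names(c(lo, hi))
    if (!all(nm %in% names(moe))) return(NULL)
    stats::setNames(as.numeric(moe[nm]), nm)
  }
  structure(
    list(
      region = e$region, age_group = hed$age_group, chemical_id = hed$chemical_id,
      edi_median = e$edi_median,
      moe_percentiles = moe,
      tier_per_percentile = stats::setNames(classify_moe(as.numeric(moe)), names(moe)),
      intervals = Filter(Negate(is.null), list(
        central = band(2.5, 97.5),
        broad = band(1, 99),
        extreme = band(0.1, 99.9)
      ))
    ),
    class = "moe_assessment"
  )
}

#' @export
print.moe_assessment <- function(x, ...) {
  cat(sprintf("<moe_assessment> %s / %s / %s (EDI %.4g ng/kg/day)\n",
              x$region, x$age_group, x$chemical_id, x$edi_median))
  df <- data.frame(moe = signif(as.numeric(x$moe_percentiles), 3),
                   tier = x$tier_per_percentile)
  print(df)
  invisible(x)
}
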