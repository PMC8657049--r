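# Reverse dosimetry: converting in vitro AC50 bioactivity concentrations to
# human equivalent dose (HED) distributions through the population liver
# Css, merging assays into an overall liver-effect HED, and the parallel
# animal-POD x DAF pathway.
#
# The central relation is HED [mg/kg/day] = AC50 [uM] * dose_ref / Css [uM],
# applied sample-wise to the Monte Carlo Css draws. Because the transform is
# monotone decreasing, the HED percentile at rank p comes from the Css
# percentile at rank (100 - p).

#' Construct a HED distribution object
#'
#' @param chemical_id Chemical identifier.
#' @param age_group Population label.
#' @param assay_name Source assay, or `"overall"` for merged assays.
#' @param samples Positive HED samples in mg/kg/day.
#' @param ranks Percentile ranks to summarise at; must include at least
#'   0.1, 1, 2.5, 25, 50, 75, 97.5, 99 and 99.9 for the probabilistic MOE
#'   bands.
#' @return A list of class `hed_distribution`.
#' @export
hed_distribution <- function(chemical_id, age_group, assay_name, samples,
                             ranks = default_percentile_ranks()) {
  if (!length(samples)) stopf("hed_distribution needs at least one sample")
  if (any(!is.finite(samples) | samples <= 0)) stopf("all HED samples must be positive")
  warn_extreme_ranks(ranks, length(samples))
  structure(
    list(chemical_id = chemical_id, age_group = age_group,
         assay_name = assay_name, samples = as.numeric(samples),
         ranks = ranks, percentiles = pctile(samples, ranks)),
    class = "hed_distribution"
  )
}

#' HED distribution for one assay from the population Css
#'
#' Applies the reverse-dosimetry relation sample-wise:
#' `HED_i = ac50 / Css_i * dose_ref`, where `dose_ref` is the unit dose the
#' Css samples were simulated at (1 mg/kg/day).
#'
#' @param assay One row of an [assay_table()] (or a list with `assay_name`,
#'   `chemical_id`, `ac50`).
#' @param css A [css_distribution()] for the same chemical.
#' @param ranks Percentile ranks; default [default_percentile_ranks()].
#' @return A [hed_distribution()].
#' @export
hed_from_assay <- function(assay, css, ranks = default_percentile_ranks()) {
  stopifnot(inherits(css, "css_distribution"))
  a <- as.list(assay)
  if (!identical(as.character(a$chemical_id), as.character(css$chemical_id))) {
    stopf("chemical mismatch: assay is for '%s' but Css distribution is for '%s'",
          a$chemical_id, css$chemical_id)
  }
  if (!is_number(a$ac50) || a$ac50 <= 0) stopf("ac50 must be positive")
  hed_distribution(css$chemical_id, css$age_group, a$assay_name,
                   a$ac50 * css$dose_ref / css$samples, ranks = ranks)
}

#' HED percentiles from a printed Css percentile summary
#'
#' Convenience pathway for working directly from a published Css summary
#' rather than Monte Carlo samples: the HED percentile at rank p is
#' `ac50 * dose_ref / Css` at rank (100 - p) (the reciprocal transform
#' reverses rank order; the median maps to the median).
#'
#' @param ac50 AC50 in uM.
#' @param css_percentiles Named numeric vector of Css percentiles in uM,
#'   names `"P<rank>"` (e.g. `P2.5`, `P50`, `P97.5`).
#' @param dose_ref Reference dose in mg/kg/day; default 1.
#' @return Named numeric vector of HED percentiles (mg/kg/day) at the
#'   complementary ranks, sorted by rank.
#' @export
hed_from_css_percentiles <- function(ac50, css_percentiles, dose_ref = 1) {
  if (!is_number(ac50) || ac50 <= 0) stopf("ac50 must be positive")
  ranks <- as.numeric(sub("^P", "", names(css_percentiles)))
  if (any(is.na(ranks))) stopf("css_percentiles must be named 'P<rank>'")
  hed <- ac50 * dose_ref / as.numeric(css_percentiles)
  out_ranks <- 100 - ranks
  ord <- order(out_ranks)
  stats::setNames(hed[ord], rank_names(out_ranks[ord]))
}

#' Merge per-assay HED distributions into an overall liver-effect HED
#'
#' The default merge pools the Monte Carlo samples of all assays with equal
#' weight (equal sample counts are enforced) and recomputes percentiles on
#' the pooled set, so the overall median can fall between per-assay medians.
#' `method = "median_of_medians"` instead summarises the per-assay
#' percentile curves by their rank-wise median (non-default; retained for
#' sensitivity analysis, with pooled samples set to the rank-wise medians).
#'
#' @param heds List of [hed_distribution()]s sharing chemical and age group.
#' @param method `"pool"` (default) or `"median_of_medians"`.
#' @param ranks Percentile ranks for the merged summary.
#' @return A [hed_distribution()] with `assay_name = "overall"`.
#' @export
merge_assays <- function(heds, method = c("pool", "median_of_medians"),
                         ranks = default_percentile_ranks()) {
  method <- match.arg(method)
  if (!length(heds)) stopf("merge_assays needs at least one HED distribution")
  stopifnot(all(vapply(heds, inherits, logical(1), "hed_distribution")))
  chem <- unique(vapply(heds, `[[`, character(1), "chemical_id"))
  age <- unique(vapply(heds, `[[`, character(1), "age_group"))
  if (length(chem) != 1L) stopf("cannot merge HEDs across chemicals: %s", paste(chem, collapse = ", "))
  if (length(age) != 1L) stopf("cannot merge HEDs across age groups: %s", paste(age, collapse = ", "))
  ns <- vapply(heds, function(h) length(h$samples), integer(1))
  if (method == "pool") {
    if (length(unique(ns)) != 1L) {
      stopf("pooled merge requires equal sample counts per assay (got %s)", paste(ns, collapse = ", "))
    }
    samples <- unlist(lapply(heds, `[[`, "samples"), use.names = FALSE)
    hed_distribution(chem, age, "overall", samples, ranks = ranks)
  } else {
    per_assay <- vapply(heds, function(h) pctile(h$samples, ranks), numeric(length(ranks)))
    med <- apply(matrix(per_assay, nrow = length(ranks)), 1, stats::median)
    out <- hed_distribution(chem, age, "overall", med, ranks = ranks)
    out$percentiles <- stats::setNames(med, rank_names(ranks))
    out
  }
}

#' Animal-based human equivalent dose
#'
#' Converts an animal point of departure (NOAEL or LOAEL) to a human
#' equivalent dose with the dosimetric adjustment factor:
#' `HED = POD * DAF`.
#'
#' @param pod One row of a [pod_table()] (or a list with `pod_value` and
#'   `daf`).
#' @return HED in mg/kg/day.
#' @export
animal_hed <- function(pod) {
  p <- as.list(pod)
  if (!is_number(p$pod_value) || p$pod_value <= 0) stopf("pod_value must be positive")
  if (!is_number(p$daf) || p$daf <= 0 || p$daf > 1) stopf("daf must lie in (0, 1]")
  p$pod_value * p$daf
}

#' @export
print.hed_distribution <- function(x, ...) {
  cat(sprintf("<hed_distribution> %s / %s / %s: n = %d\n",
              x$chemical_id, x$age_group, x$assay_name, length(x$samples)))
  print(signif(x$percentiles, 3))
  invisible(x)
}
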