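# End-to-end orchestration: cytotoxicity filter -> population sampling ->
# liver Css -> per-assay, overall and animal HEDs -> MOE assessment for
# every (chemical, age group, region) combination, with a run log.
#
# The population Css is computed once per (chemical, age group) and reused
# for every assay and region: all HED percentiles for a chemical/age group
# derive from the same Monte Carlo draw.

#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory for the report files.
#' @param input_dir Optional directory written by [write_bundle()]; when
#'   `NULL` the shipped fixture bundle is generated in memory.
#' @param n Population size per age group.
#' @param seed Master seed; every random draw derives from it.
#' @param dose_ref Reference dose for the Css simulation (mg/kg/day).
#' @param ranks Percentile ranks (sorted, strictly inside (0, 100)).
#' @param regions Optional character vector restricting the MOE assessment
#'   to these regions.
#' @param calibrate Calibrate fixture chemicals against the published adult
#'   median Css (ignored when `input_dir` is given).
#' @param merge_method Assay merge: `"pool"` (default) or
#'   `"median_of_medians"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, input_dir = NULL, n = 1000L, seed = 101L,
                       dose_ref = 1, ranks = default_percentile_ranks(),
                       regions = NULL, calibrate = TRUE,
                       merge_method = c("pool", "median_of_medians")) {
  if (!is_number(dose_ref) || dose_ref <= 0) stopf("dose_ref must be > 0")
  if (is.unsorted(ranks, strictly = TRUE)) stopf("ranks must be sorted strictly increasing")
  if (any(ranks <= 0 | ranks >= 100)) stopf("ranks must lie strictly inside (0, 100)")
  if (!is.null(input_dir) && !dir.exists(input_dir)) stopf("input_dir not found: '%s'", input_dir)
  structure(
    list(out_dir = out_dir, input_dir = input_dir, n = as.integer(n),
         seed = as.integer(seed), dose_ref = dose_ref, ranks = ranks,
         regions = regions, calibrate = isTRUE(calibrate),
         merge_method = match.arg(merge_method)),
    class = "run_config"
  )
}

#' Run the full risk-assessment pipeline
#'
#' Executes filter -> sample -> Css -> HED (per-assay, overall, animal) ->
#' MOE for every chemical, age group and region in the inputs, and writes
#' `hed_table.csv` (per-assay rows plus an overall row per chemical and age
#' group), `moe_assessments.csv`, `summary.json` and `run.log` under
#' `config$out_dir`. Reruns with the same config are numerically identical.
#'
#' @param config A [run_config()] (or a YAML path holding its fields).
#' @return Invisibly, a list with elements `css`, `hed_table`, `heds`,
#'   `moe_table`, `animal_hed` and `bundle`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    config <- do.call(run_config, cfg)
  }
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  logf <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                       sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, log_path)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  logf("pipeline start: seed=%d n=%d dose_ref=%g merge=%s", config$seed, config$n,
       config$dose_ref, config$merge_method)
  bundle <- stage("inputs", {
    if (is.null(config$input_dir)) {
      make_fixture_bundle(seed = config$seed, n = config$n, calibrate = config$calibrate)
    } else {
      b <- read_bundle(config$input_dir, n = config$n)
      for (ag in names(b$population_specs)) b$population_specs[[ag]]$n <- config$n
      b
    }
  })
  fx <- bundle$provenance[grepl("fixture", bundle$provenance$source), ]
  logf("fixture-provenance constants in use: %s", paste(fx$item, collapse = ", "))
  for (id in names(bundle$chemicals)) {
    ch <- bundle$chemicals[[id]]
    logf("chemical %s: MW=%.1f Clint=%.4g fub=%.3g fabs=%.2f", id,
         ch$molecular_weight, ch$clint_default, ch$fub_default, ch$fabs)
  }

  assays <- stage("cytotoxicity_filter", filter_by_cytotoxicity(bundle$assay_table))
  logf("cytotoxicity filter: %d of %d assays retained", nrow(assays), nrow(bundle$assay_table))

  age_groups <- names(bundle$population_specs)
  chem_ids <- names(bundle$chemicals)
  css <- list()
  heds <- list()
  hed_rows <- list()
  extreme_notes <- character()
  note_warns <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      extreme_notes <<- c(extreme_notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  for (id in chem_ids) {
    chem <- bundle$chemicals[[id]]
    for (ag in age_groups) {
      key <- paste(id, ag, sep = ".")
      spec <- population_spec_for_chemical(bundle$population_specs[[ag]], chem)
      pop <- stage(paste0("sample_population/", key), sample_population(spec))
      css[[key]] <- stage(paste0("population_css/", key),
                          population_css(pop, chem, dose = config$dose_ref,
                                         ranks = config$ranks))
      logf("Css %s: median %.4g uM (P2.5 %.4g, P97.5 %.4g), n=%d", key,
           unname(css[[key]]$percentiles["P50"]),
           unname(css[[key]]$percentiles["P2.5"]),
           unname(css[[key]]$percentiles["P97.5"]), length(css[[key]]$samples))
      chem_assays <- assays[assays$chemical_id == id, , drop = FALSE]
      per_assay <- lapply(seq_len(nrow(chem_assays)), function(i) {
        stage(paste0("hed_from_assay/", key),
              note_warns(hed_from_assay(chem_assays[i, ], css[[key]], ranks = config$ranks)))
      })
      overall <- stage(paste0("merge_assays/", key),
                       note_warns(merge_assays(per_assay, method = config$merge_method,
                                               ranks = config$ranks)))
      heds[[key]] <- c(per_assay, list(overall))
      for (h in heds[[key]]) {
        ac50 <- if (h$assay_name == "overall") NA_real_ else
          chem_assays$ac50[chem_assays$assay_name == h$assay_name]
        row <- data.frame(chemical_id = id, age_group = ag, assay_name = h$assay_name,
                          ac50_uM = ac50, stringsAsFactors = FALSE)
        pc <- as.data.frame(as.list(h$percentiles), check.names = FALSE)
        names(pc) <- paste0("hed_", names(h$percentiles))
        row <- cbind(row, pc)
        row$display <- sprintf("%.3g(%.3g~%.3g)", h$percentiles[["P50"]],
                               h$percentiles[["P2.5"]], h$percentiles[["P97.5"]])
        hed_rows[[length(hed_rows) + 1L]] <- row
      }
    }
  }
  hed_table <- do.call(rbind, hed_rows)
  if (length(extreme_notes)) {
    logf("percentile-estimator notes: %s", paste(unique(extreme_notes), collapse = " | "))
  }

  animal <- stats::setNames(
    vapply(seq_len(nrow(bundle$pod_table)), function(i) animal_hed(bundle$pod_table[i, ]),
           numeric(1)),
    bundle$pod_table$chemical_id
  )
  logf("animal-based HEDs: %s", paste(sprintf("%s=%.4g", names(animal), animal), collapse = ", "))

  edi <- bundle$edi_table
  if (!is.null(config$regions)) edi <- edi[edi$region %in% config$regions, , drop = FALSE]
  moe_rows <- list()
  assessments <- list()
  for (i in seq_len(nrow(edi))) {
    rec <- edi[i, ]
    key <- paste(rec$chemical_id, rec$age_group, sep = ".")
    if (is.null(heds[[key]])) next
    overall <- heds[[key]][[length(heds[[key]])]]
    a <- stage(sprintf("moe/%s/%s", rec$region, key),
               probabilistic_assessment(overall, rec))
    assessments[[length(assessments) + 1L]] <- a
    row <- data.frame(region = rec$region, age_group = rec$age_group,
                      chemical_id = rec$chemical_id, edi_ng_kg_day = rec$edi_median,
                      stringsAsFactors = FALSE)
    mc <- as.data.frame(as.list(a$moe_percentiles), check.names = FALSE)
    names(mc) <- paste0("moe_", names(a$moe_percentiles))
    tc <- as.data.frame(as.list(a$tier_per_percentile), check.names = FALSE,
                        stringsAsFactors = FALSE)
    names(tc) <- paste0("tier_", names(a$tier_per_percentile))
    moe_rows[[length(moe_rows) + 1L]] <- cbind(row, mc, tc)
  }
  moe_table <- do.call(rbind, moe_rows)
  logf("MOE assessments: %d (regions x age groups x chemicals)", nrow(moe_table))

  utils::write.csv(hed_table, file.path(config$out_dir, "hed_table.csv"), row.names = FALSE)
  utils::write.csv(moe_table, file.path(config$out_dir, "moe_assessments.csv"), row.names = FALSE)
  summary <- list(
    seed = config$seed, n = config$n, dose_ref = config$dose_ref,
    merge_method = config$merge_method,
    chemicals = lapply(bundle$chemicals, function(ch) {
      list(molecular_weight = ch$molecular_weight, clint = ch$clint_default,
           fub = ch$fub_default, fabs = ch$fabs)
    }),
    css_medians = lapply(css, function(d) unname(d$percentiles[["P50"]])),
    overall_hed_medians = lapply(heds, function(hh) {
      unname(hh[[length(hh)]]$percentiles[["P50"]])
    }),
    animal_hed = as.list(animal),
    n_assessments = nrow(moe_table)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline done; outputs in '%s'", config$out_dir)
  writeLines(log_lines, log_path)
  invisible(list(css = css, hed_table = hed_table, heds = heds,
                 moe_table = moe_table, animal_hed = animal, bundle = bundle))
}
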