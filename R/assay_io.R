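# In vitro assay and animal point-of-departure tables: reading, validation
# and cytotoxicity filtering.
#
# AC50 is the activity concentration causing 50% of the maximum hepatocyte
# response; units are fixed at uM throughout (no unit autodetection). Assays
# whose AC50 is not strictly below the cytotoxicity limit are confounded by
# cell death and are dropped.

ASSAY_COLUMNS <- c("assay_name", "chemical_id", "ac50_uM", "cytotox_limit_uM", "biological_target")
POD_COLUMNS <- c("chemical_id", "pod_mg_per_kg_day", "pod_type", "daf", "effect_label")

#' Construct and validate a table of in vitro assay records
#'
#' @param assay_name Character vector of assay identifiers, unique per chemical.
#' @param chemical_id Character vector of chemical identifiers.
#' @param ac50 AC50 values in uM; strictly positive.
#' @param cytotox_limit Cytotoxicity limits in uM; strictly positive.
#' @param biological_target Free-text description of the assay target.
#'
#' @return A `data.frame` of class `assay_table` with one row per assay.
#' @export
assay_table <- function(assay_name, chemical_id, ac50, cytotox_limit,
                        biological_target = rep("", length(assay_name))) {
  df <- data.frame(
    assay_name = as.character(assay_name),
    chemical_id = as.character(chemical_id),
    ac50 = as.numeric(ac50),
    cytotox_limit = as.numeric(cytotox_limit),
    biological_target = as.character(biological_target),
    stringsAsFactors = FALSE
  )
  validate_assay_table(df)
  class(df) <- c("assay_table", "data.frame")
  df
}

validate_assay_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$assay_name))) stopf("assay_name must be nonempty for every record")
  bad <- which(!is.finite(df$ac50) | df$ac50 <= 0)
  if (length(bad)) stopf("row %d: ac50 must be a positive number (got '%s')", bad[1], df$ac50[bad[1]])
  bad <- which(!is.finite(df$cytotox_limit) | df$cytotox_limit <= 0)
  if (length(bad)) stopf("row %d: cytotox_limit must be a positive number", bad[1])
  dup <- duplicated(df[, c("chemical_id", "assay_name")])
  if (any(dup)) {
    stopf("duplicate assay_name '%s' for chemical '%s'",
          df$assay_name[which(dup)[1]], df$chemical_id[which(dup)[1]])
  }
  invisible(df)
}

#' Read an in vitro assay table from CSV
#'
#' Expects columns `assay_name`, `chemical_id`, `ac50_uM`, `cytotox_limit_uM`,
#' `biological_target` (UTF-8, decimal point). Malformed numeric cells are
#' reported with their row number.
#'
#' @param path Path to the CSV file.
#' @return An [assay_table()] with one record per data row.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stopf("assay table not found: '%s'", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(ASSAY_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stopf("assay table '%s' is missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(assay_table(character(), character(), numeric(), numeric(), character()))
  }
  parse_num <- function(col) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val))
    if (length(bad)) {
      stopf("'%s' row %d, column '%s': value '%s' is not numeric",
            path, bad[1], col, raw[[col]][bad[1]])
    }
    val
  }
  assay_table(
    assay_name = raw$assay_name,
    chemical_id = raw$chemical_id,
    ac50 = parse_num("ac50_uM"),
    cytotox_limit = parse_num("cytotox_limit_uM"),
    biological_target = raw$biological_target
  )
}

#' Drop assays confounded by cytotoxicity
#'
#' Retains exactly the assays whose AC50 lies strictly below the cytotoxicity
#' limit (ties are dropped: an AC50 at the limit is not "below" it). Order is
#' preserved and records are not modified; an empty result is legal.
#'
#' @param records An [assay_table()].
#' @return The retained subset, same class.
#' @export
filter_by_cytotoxicity <- function(records) {
  validate_assay_table(records)
  out <- records[records$ac50 < records$cytotox_limit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct and validate animal point-of-departure records
#'
#' A POD (NOAEL or LOAEL, mg/kg/day) from an animal study is converted to a
#' human equivalent dose by multiplication with a dosimetric adjustment
#' factor (DAF) in [animal_hed()].
#'
#' @param chemical_id Character vector of chemical identifiers.
#' @param pod_value POD doses in mg/kg/day; strictly positive.
#' @param pod_type One of `"NOAEL"` or `"LOAEL"` per record.
#' @param daf Dimensionless dosimetric adjustment factors in (0, 1].
#' @param effect_label Free-text effect description.
#' @return A `data.frame` of class `pod_table`.
#' @export
pod_table <- function(chemical_id, pod_value, pod_type, daf,
                      effect_label = rep("", length(chemical_id))) {
  df <- data.frame(
    chemical_id = as.character(chemical_id),
    pod_value = as.numeric(pod_value),
    pod_type = as.character(pod_type),
    daf = as.numeric(daf),
    effect_label = as.character(effect_label),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(!is.finite(df$pod_value) | df$pod_value <= 0)) stopf("pod_value must be positive")
    if (any(!df$pod_type %in% c("NOAEL", "LOAEL"))) stopf("pod_type must be 'NOAEL' or 'LOAEL'")
    if (any(!is.finite(df$daf) | df$daf <= 0 | df$daf > 1)) stopf("daf must lie in (0, 1]")
  }
  class(df) <- c("pod_table", "data.frame")
  df
}

#' Read an animal point-of-departure table from CSV
#'
#' Expects columns `chemical_id`, `pod_mg_per_kg_day`, `pod_type`, `daf`,
#' `effect_label`.
#'
#' @param path Path to the CSV file.
#' @return A [pod_table()].
#' @export
read_pod_table <- function(path) {
  if (!file.exists(path)) stopf("POD table not found: '%s'", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(POD_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stopf("POD table '%s' is missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) return(pod_table(character(), numeric(), character(), numeric()))
  num <- function(col) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val))
    if (length(bad)) stopf("'%s' row %d, column '%s': value '%s' is not numeric",
                           path, bad[1], col, raw[[col]][bad[1]])
    val
  }
  pod_table(raw$chemical_id, num("pod_mg_per_kg_day"), raw$pod_type, num("daf"), raw$effect_label)
}
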