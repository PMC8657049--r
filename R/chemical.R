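# Chemical-specific PBTK inputs: molecular weight (for uM <-> mg/L),
# intrinsic hepatic clearance, plasma protein binding, tissue:plasma
# partition coefficients and oral absorbed fraction.

PARTITION_COMPARTMENTS <- c("gut", "liver", "lung", "kidney", "rest")

#' Construct a chemical parameter set for the PBTK model
#'
#' @param chemical_id Short identifier, e.g. `"TPHP"`.
#' @param name Full chemical name.
#' @param molecular_weight Molar mass in g/mol (needed to express liver
#'   concentrations in uM).
#' @param clint_default Intrinsic hepatic clearance in uL/min per 10^6
#'   hepatocytes (population geometric-mean location).
#' @param fub_default Fraction unbound in plasma, in (0, 1].
#' @param partition_coefficients Named numeric vector of tissue:plasma
#'   partition coefficients for `gut`, `liver`, `lung`, `kidney`, `rest`
#'   (all > 0). Blood compartments have coefficient 1 by definition.
#' @param fabs Oral fraction absorbed, in (0, 1]. Default 1 (complete
#'   absorption).
#'
#' @return A list of class `ope_chemical`.
#' @export
chemical <- function(chemical_id, name = chemical_id, molecular_weight,
                     clint_default, fub_default, partition_coefficients,
                     fabs = 1) {
  if (!is_number(molecular_weight) || molecular_weight <= 0) stopf("molecular_weight must be > 0")
  if (!is_number(clint_default) || clint_default < 0) stopf("clint_default must be >= 0")
  if (!is_number(fub_default) || fub_default <= 0 || fub_default > 1) stopf("fub_default must lie in (0, 1]")
  if (!is_number(fabs) || fabs <= 0 || fabs > 1) stopf("fabs must lie in (0, 1]")
  missing_k <- setdiff(PARTITION_COMPARTMENTS, names(partition_coefficients))
  if (length(missing_k)) {
    stopf("partition_coefficients missing compartment(s): %s", paste(missing_k, collapse = ", "))
  }
  pc <- partition_coefficients[PARTITION_COMPARTMENTS]
  if (any(!is.finite(pc) | pc <= 0)) stopf("all partition coefficients must be > 0")
  structure(
    list(
      chemical_id = as.character(chemical_id),
      name = as.character(name),
      molecular_weight = molecular_weight,
      clint_default = clint_default,
      fub_default = fub_default,
      partition_coefficients = pc,
      fabs = fabs
    ),
    class = "ope_chemical"
  )
}

#' @export
print.ope_chemical <- function(x, ...) {
  cat(sprintf("<ope_chemical> %s (%s)\n", x$chemical_id, x$name))
  cat(sprintf("  MW %.1f g/mol | Clint %.3g uL/min/10^6 cells | fub %.3g | fabs %.2f\n",
              x$molecular_weight, x$clint_default, x$fub_default, x$fabs))
  cat("  partition coefficients:",
      paste(sprintf("%s=%.3g", names(x$partition_coefficients), x$partition_coefficients),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a chemical parameter set to a YAML config file
#'
#' @param chem An [chemical()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chemical_config <- function(chem, path) {
  stopifnot(inherits(chem, "ope_chemical"))
  yaml::write_yaml(
    list(
      chemical_id = chem$chemical_id,
      name = chem$name,
      molecular_weight = chem$molecular_weight,
      clint_default = chem$clint_default,
      fub_default = chem$fub_default,
      partition_coefficients = as.list(chem$partition_coefficients),
      fabs = chem$fabs
    ),
    path
  )
  invisible(path)
}

#' Read a chemical parameter set from a YAML config file
#'
#' @param path Path to a config written by [write_chemical_config()].
#' @return An [chemical()] object.
#' @export
read_chemical_config <- function(path) {
  if (!file.exists(path)) stopf("chemical config not found: '%s'", path)
  cfg <- yaml::read_yaml(path)
  chemical(
    chemical_id = cfg$chemical_id,
    name = cfg$name,
    molecular_weight = cfg$molecular_weight,
    clint_default = cfg$clint_default,
    fub_default = cfg$fub_default,
    partition_coefficients = unlist(cfg$partition_coefficients),
    fabs = cfg$fabs
  )
}
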