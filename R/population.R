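# Seeded Monte Carlo virtual populations of children and adults.
#
# A population spec maps each physiological parameter to a distribution
# descriptor (lognormal, truncated-positive normal, logit-normal or fixed).
# Body-weight-driven allometry keeps the model self-consistent: liver mass
# scales with BW^1, blood flows and GFR with BW^0.75, and the rest-of-body
# flow is computed as the residual of cardiac output so the flow balance
# holds by construction.

DIST_FAMILIES <- c("lognormal", "normal-truncated-positive", "logitnormal", "fixed")

# Parameters every spec must describe. body_weight in kg; liver_fraction is
# liver mass / BW; hepatocellularity in 10^6 cells per g liver;
# cardiac_allometric in L/h per kg^0.75; gfr_allometric in L/h per kg^0.75;
# fub dimensionless in (0,1); clint in uL/min per 10^6 hepatocytes.
POPULATION_PARAMS <- c("body_weight", "liver_fraction", "hepatocellularity",
                       "cardiac_allometric", "gfr_allometric", "fub", "clint")

# Fixed fractions of cardiac output routed to each perfused compartment;
# rest-of-body receives the residual (0.585). Standard reference values.
FLOW_FRACTIONS <- c(gut = 0.160, hepatic_artery = 0.065, kidney = 0.190)

#' Describe one sampled parameter's distribution
#'
#' @param family One of `"lognormal"` (location = geometric mean, scale =
#'   log-sd), `"normal-truncated-positive"` (location = mean, scale = sd,
#'   non-positive draws redrawn), `"logitnormal"` (location = median in
#'   (0,1), scale = sd on the logit scale) or `"fixed"` (scale must be 0).
#' @param location Central value in the parameter's units.
#' @param scale Spread parameter, `>= 0`.
#' @return A list descriptor.
#' @export
dist_descriptor <- function(family, location, scale) {
  family <- match.arg(family, DIST_FAMILIES)
  if (!is_number(location)) stopf("location must be a finite number")
  if (!is_number(scale) || scale < 0) stopf("scale must be >= 0")
  if (family == "fixed" && scale != 0) stopf("fixed distributions must have scale = 0")
  if (family == "logitnormal" && (location <= 0 || location >= 1)) {
    stopf("logitnormal location must lie in (0, 1)")
  }
  list(family = family, location = location, scale = scale)
}

#' Construct a virtual-population specification
#'
#' @param age_group `"children"` or `"adults"`.
#' @param n Number of individuals to sample (>= 1).
#' @param seed Integer RNG seed; sampling is a pure function of (spec, seed).
#' @param distributions Named list of [dist_descriptor()]s covering every
#'   parameter in `operisk:::POPULATION_PARAMS`.
#' @param clint_multiplier Age-group multiplier applied to a chemical's
#'   default intrinsic clearance by [population_spec_for_chemical()]
#'   (children metabolise these chemicals faster per unit liver).
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(age_group, n, seed, distributions, clint_multiplier = 1) {
  age_group <- match.arg(age_group, c("children", "adults"))
  if (!is_number(n) || n < 1 || n != round(n)) stopf("n must be a positive integer")
  if (!is_number(seed)) stopf("seed must be an integer")
  missing_p <- setdiff(POPULATION_PARAMS, names(distributions))
  if (length(missing_p)) {
    stopf("population spec missing distribution(s) for: %s", paste(missing_p, collapse = ", "))
  }
  for (p in POPULATION_PARAMS) {
    d <- distributions[[p]]
    if (!is.list(d) || !all(c("family", "location", "scale") %in% names(d))) {
      stopf("distribution for '%s' must be a dist_descriptor()", p)
    }
    distributions[[p]] <- dist_descriptor(d$family, d$location, d$scale)
  }
  if (!is_number(clint_multiplier) || clint_multiplier <= 0) stopf("clint_multiplier must be > 0")
  structure(
    list(age_group = age_group, n = as.integer(n), seed = as.integer(seed),
         distributions = distributions[POPULATION_PARAMS],
         clint_multiplier = clint_multiplier),
    class = "population_spec"
  )
}

#' Shipped default population specifications
#'
#' Fixture stand-ins for a survey-derived population: children (0--18) are
#' lighter, have a larger liver-mass fraction and a higher per-liver-mass
#' metabolic capacity than adults (18--79). Locations are geometric means.
#'
#' @param age_group `"children"` or `"adults"`.
#' @param chemical Optional [chemical()]; when supplied, the `clint` and
#'   `fub` locations are set from the chemical's defaults (clint scaled by
#'   the age-group multiplier) via [population_spec_for_chemical()].
#' @param n Population size; default 1000.
#' @param seed RNG seed; default 1.
#' @return A [population_spec()].
#' @export
default_population_spec <- function(age_group = c("children", "adults"),
                                    chemical = NULL, n = 1000L, seed = 1L) {
  age_group <- match.arg(age_group)
  base <- switch(age_group,
    adults = list(
      body_weight = dist_descriptor("lognormal", 70, 0.20),
      liver_fraction = dist_descriptor("lognormal", 0.0257, 0.12),
      clint_multiplier = 1.0
    ),
    children = list(
      body_weight = dist_descriptor("lognormal", 26, 0.45),
      liver_fraction = dist_descriptor("lognormal", 0.033, 0.12),
      clint_multiplier = 2.0
    )
  )
  spec <- population_spec(
    age_group = age_group, n = n, seed = seed,
    distributions = list(
      body_weight = base$body_weight,
      liver_fraction = base$liver_fraction,
      hepatocellularity = dist_descriptor("lognormal", 110, 0.15),
      cardiac_allometric = dist_descriptor("lognormal", 13.6, 0.12),
      gfr_allometric = dist_descriptor("lognormal", 0.28, 0.18),
      fub = dist_descriptor("logitnormal", 0.05, 0.30),
      clint = dist_descriptor("lognormal", 8 * base$clint_multiplier, 0.45)
    ),
    clint_multiplier = base$clint_multiplier
  )
  if (!is.null(chemical)) spec <- population_spec_for_chemical(spec, chemical)
  spec
}

#' Specialise a population spec to one chemical
#'
#' Sets the intrinsic-clearance location to `clint_default * clint_multiplier`
#' and the unbound-fraction location to `fub_default`, keeping the spread
#' parameters of the spec.
#'
#' @param spec A [population_spec()].
#' @param chem An [chemical()].
#' @return A modified [population_spec()].
#' @export
population_spec_for_chemical <- function(spec, chem) {
  stopifnot(inherits(spec, "population_spec"), inherits(chem, "ope_chemical"))
  spec$distributions$clint$location <- chem$clint_default * spec$clint_multiplier
  spec$distributions$fub$location <- chem$fub_default
  spec
}

draw_param <- function(d, n, name, max_retries = 100L) {
  x <- switch(d$family,
    fixed = rep(d$location, n),
    lognormal = stats::rlnorm(n, meanlog = log(d$location), sdlog = d$scale),
    logitnormal = stats::plogis(stats::qlogis(d$location) + stats::rnorm(n, 0, d$scale)),
    `normal-truncated-positive` = {
      x <- stats::rnorm(n, d$location, d$scale)
      tries <- 0L
      while (any(x <= 0)) {
        tries <- tries + 1L
        if (tries > max_retries) {
          stopf("parameter '%s': could not draw a positive value within %d redraws", name, max_retries)
        }
        bad <- x <= 0
        x[bad] <- stats::rnorm(sum(bad), d$location, d$scale)
      }
      x
    }
  )
  if (any(x <= 0)) stopf("parameter '%s': non-positive draw", name)
  x
}

#' Sample a virtual population
#'
#' Draws `spec$n` individuals, deterministically in (spec, seed); the
#' caller's RNG state is untouched. Derived quantities: liver mass =
#' liver_fraction * BW; cardiac output = cardiac_allometric * BW^0.75; the
#' perfused flows are fixed fractions of cardiac output with the
#' rest-of-body flow as residual, so the flow balance is exact.
#'
#' @param spec A [population_spec()].
#' @return A `data.frame` of class `ope_population`, one row per individual,
#'   with columns `body_weight` (kg), `liver_mass` (kg), `hepatocellularity`
#'   (10^6 cells/g), `q_cardiac`, `q_gut`, `q_hepatic_artery`, `q_kidney`,
#'   `q_rest`, `gfr` (all L/h), `fub`, `clint` (uL/min/10^6 cells).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  draws <- with_preserved_seed(spec$seed, {
    out <- list()
    for (p in POPULATION_PARAMS) out[[p]] <- draw_param(spec$distributions[[p]], n, p)
    out
  })
  bw <- draws$body_weight
  q_cardiac <- draws$cardiac_allometric * bw^0.75
  pop <- data.frame(
    body_weight = bw,
    liver_mass = draws$liver_fraction * bw,
    hepatocellularity = draws$hepatocellularity,
    q_cardiac = q_cardiac,
    q_gut = FLOW_FRACTIONS[["gut"]] * q_cardiac,
    q_hepatic_artery = FLOW_FRACTIONS[["hepatic_artery"]] * q_cardiac,
    q_kidney = FLOW_FRACTIONS[["kidney"]] * q_cardiac,
    q_rest = (1 - sum(FLOW_FRACTIONS)) * q_cardiac,
    gfr = draws$gfr_allometric * bw^0.75,
    fub = draws$fub,
    clint = draws$clint
  )
  if (any(pop$fub >= 1)) stopf("sampled fub >= 1")
  class(pop) <- c("ope_population", "data.frame")
  attr(pop, "age_group") <- spec$age_group
  attr(pop, "seed") <- spec$seed
  pop
}

#' Check the blood-flow balance of a sampled population
#'
#' Verifies that compartment outflows sum to cardiac output within relative
#' tolerance `tol` for every individual.
#'
#' @param pop An [sample_population()] result.
#' @param tol Relative tolerance; default `1e-9`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_flow_balance <- function(pop, tol = 1e-9) {
  resid <- abs(pop$q_gut + pop$q_hepatic_artery + pop$q_kidney + pop$q_rest - pop$q_cardiac) /
    pop$q_cardiac
  if (any(resid > tol)) stopf("flow balance violated for individual %d", which.max(resid))
  invisible(TRUE)
}

#' Serialise a population spec to YAML
#' @param spec A [population_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_spec <- function(spec, path) {
  stopifnot(inherits(spec, "population_spec"))
  yaml::write_yaml(
    list(age_group = spec$age_group, n = spec$n, seed = spec$seed,
         clint_multiplier = spec$clint_multiplier,
         distributions = spec$distributions),
    path
  )
  invisible(path)
}

#' Read a population spec from YAML
#' @param path Path written by [write_population_spec()].
#' @return A [population_spec()].
#' @export
read_population_spec <- function(path) {
  if (!file.exists(path)) stopf("population spec not found: '%s'", path)
  cfg <- yaml::read_yaml(path)
  population_spec(cfg$age_group, cfg$n, cfg$seed, cfg$distributions, cfg$clint_multiplier)
}
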