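# Seven-compartment, flow-limited, linear PBTK model for chronic oral
# dosing: gut, liver, lung, arterial blood, venous blood, kidney and a
# lumped "rest of body".
#
# Oral input enters the gut at a constant rate (the daily dose averaged over
# 24 h, times the absorbed fraction); the gut drains into the liver via the
# portal flow; elimination is hepatic (unbound intrinsic clearance acting on
# liver venous plasma, which yields the well-stirred clearance when
# referenced to inflowing blood) plus renal glomerular filtration of unbound
# chemical. Tissue partitioning is flow-limited via tissue:plasma partition
# coefficients; blood compartments have coefficient 1.
#
# State is the amount (mg) in each compartment; the system is linear,
# dx/dt = A x + b, so the steady state is the solution of A x = -b and Css
# scales linearly with dose.

COMPARTMENTS <- c("gut", "liver", "lung", "arterial", "venous", "kidney", "rest")

# Compartment volumes as fractions of body weight (L/kg at unit density);
# rest-of-body takes the remainder of total body volume. Standard reference
# values; liver volume comes from sampled liver mass at density 1.05 kg/L.
VOLUME_FRACTIONS <- c(gut = 0.0171, lung = 0.0076, arterial = 0.0257,
                      venous = 0.0514, kidney = 0.0044)
LIVER_DENSITY_KG_PER_L <- 1.05

#' Scale chemical clearances to one individual
#'
#' Builds the fully parameterised per-individual, per-chemical model
#' coefficients. Whole-liver intrinsic clearance is
#' `clint * hepatocellularity * liver mass` with unit conversion
#' uL/min -> L/h; hepatic clearance follows the well-stirred model
#' `CL_h = Q_h * fub * CLint / (Q_h + fub * CLint)` (bounded above by both
#' the hepatic blood flow and the unbound intrinsic clearance); renal
#' clearance is `GFR * fub`.
#'
#' @param individual One row of an [sample_population()] data frame (or a
#'   list with the same fields).
#' @param chem An [chemical()].
#' @param dose Chronic oral dose in mg/kg/day; default the unit dose 1.
#' @return A list of class `pbtk_parameters` with compartment volumes (L),
#'   flows (L/h), clearances (L/h) and the gut input rate (mg/h).
#' @export
scale_clearances <- function(individual, chem, dose = 1) {
  stopifnot(inherits(chem, "ope_chemical"))
  ind <- as.list(individual)
  req <- c("body_weight", "liver_mass", "hepatocellularity", "q_cardiac", "q_gut",
           "q_hepatic_artery", "q_kidney", "q_rest", "gfr", "fub", "clint")
  missing_f <- req[!vapply(req, function(f) is_number(ind[[f]]), logical(1))]
  if (length(missing_f)) stopf("individual is missing field(s): %s", paste(missing_f, collapse = ", "))
  if (ind$liver_mass <= 0) stopf("liver mass must be > 0")
  if (ind$q_cardiac <= 0 || ind$q_gut <= 0 || ind$q_hepatic_artery <= 0) stopf("blood flows must be > 0")
  if (ind$fub <= 0 || ind$fub > 1) stopf("fub must lie in (0, 1]")
  if (!is_number(dose) || dose < 0) stopf("dose must be >= 0")

  bw <- ind$body_weight
  v_liver <- ind$liver_mass / LIVER_DENSITY_KG_PER_L
  volumes <- c(
    gut = VOLUME_FRACTIONS[["gut"]] * bw,
    liver = v_liver,
    lung = VOLUME_FRACTIONS[["lung"]] * bw,
    arterial = VOLUME_FRACTIONS[["arterial"]] * bw,
    venous = VOLUME_FRACTIONS[["venous"]] * bw,
    kidney = VOLUME_FRACTIONS[["kidney"]] * bw,
    rest = NA_real_
  )
  volumes[["rest"]] <- bw - sum(volumes[setdiff(COMPARTMENTS, "rest")])
  if (volumes[["rest"]] <= 0) stopf("rest-of-body volume non-positive (liver mass too large for body weight)")

  # uL/min/10^6 cells * 10^6 cells/g * g -> uL/min; * 60 / 1e6 -> L/h
  clint_whole <- ind$clint * ind$hepatocellularity * (ind$liver_mass * 1000) * 60 / 1e6
  q_h <- ind$q_gut + ind$q_hepatic_artery
  fu_cl <- ind$fub * clint_whole
  cl_hepatic <- if (fu_cl == 0) 0 else q_h * fu_cl / (q_h + fu_cl)
  cl_renal <- ind$gfr * ind$fub

  structure(
    list(
      individual = ind,
      chemical = chem,
      volumes = volumes,
      flows = c(cardiac = ind$q_cardiac, gut = ind$q_gut,
                hepatic_artery = ind$q_hepatic_artery, kidney = ind$q_kidney,
                rest = ind$q_rest),
      fub = ind$fub,
      gfr = ind$gfr,
      clint_whole = clint_whole,
      cl_hepatic = cl_hepatic,
      cl_renal = cl_renal,
      dose = dose,
      dose_rate = dose * bw / 24  # mg/h into gut (before fabs)
    ),
    class = "pbtk_parameters"
  )
}

#' System matrix and input vector of the linear PBTK model
#'
#' Returns `A` (1/h, acting on compartment amounts in mg) and `b` (mg/h)
#' such that the model is `dx/dt = A x + b`. Column sums of `A` are zero for
#' non-eliminating compartments and equal minus the elimination rate
#' coefficients for liver and kidney, so total mass is conserved up to
#' input and elimination by construction.
#'
#' @param params A [scale_clearances()] result.
#' @return List with matrix `A`, vector `b`, and the elimination rate
#'   coefficients `elim` (per-amount, 1/h, named by compartment).
#' @export
pbtk_matrix <- function(params) {
  stopifnot(inherits(params, "pbtk_parameters"))
  V <- params$volumes
  Q <- params$flows
  K <- params$chemical$partition_coefficients
  q_h <- Q[["gut"]] + Q[["hepatic_artery"]]

  # per-amount outflow coefficients (venous plasma leaving tissue i has
  # concentration x_i / (V_i * K_i))
  k_gut <- Q[["gut"]] / (V[["gut"]] * K[["gut"]])
  k_liver_flow <- q_h / (V[["liver"]] * K[["liver"]])
  k_liver_met <- params$fub * params$clint_whole / (V[["liver"]] * K[["liver"]])
  k_lung <- Q[["cardiac"]] / (V[["lung"]] * K[["lung"]])
  k_art <- Q[["cardiac"]] / V[["arterial"]]
  k_ven <- Q[["cardiac"]] / V[["venous"]]
  k_kid_flow <- Q[["kidney"]] / (V[["kidney"]] * K[["kidney"]])
  k_kid_ren <- params$cl_renal / (V[["kidney"]] * K[["kidney"]])
  k_rest <- Q[["rest"]] / (V[["rest"]] * K[["rest"]])

  A <- matrix(0, 7, 7, dimnames = list(COMPARTMENTS, COMPARTMENTS))
  A["gut", "gut"] <- -k_gut
  A["gut", "arterial"] <- Q[["gut"]] / V[["arterial"]]
  A["liver", "gut"] <- k_gut
  A["liver", "arterial"] <- Q[["hepatic_artery"]] / V[["arterial"]]
  A["liver", "liver"] <- -(k_liver_flow + k_liver_met)
  A["venous", "liver"] <- k_liver_flow
  A["lung", "venous"] <- k_ven
  A["lung", "lung"] <- -k_lung
  A["arterial", "lung"] <- k_lung
  A["arterial", "arterial"] <- -k_art
  A["kidney", "arterial"] <- Q[["kidney"]] / V[["arterial"]]
  A["kidney", "kidney"] <- -(k_kid_flow + k_kid_ren)
  A["venous", "kidney"] <- k_kid_flow
  A["rest", "arterial"] <- Q[["rest"]] / V[["arterial"]]
  A["rest", "rest"] <- -k_rest
  A["venous", "rest"] <- k_rest
  A["venous", "venous"] <- -k_ven

  b <- stats::setNames(numeric(7), COMPARTMENTS)
  b["gut"] <- params$dose_rate * params$chemical$fabs

  elim <- stats::setNames(numeric(7), COMPARTMENTS)
  elim["liver"] <- k_liver_met
  elim["kidney"] <- k_kid_ren

  list(A = A, b = b, elim = elim)
}

mg_per_l_to_um <- function(conc_mg_per_l, molecular_weight) {
  conc_mg_per_l / molecular_weight * 1000
}

#' Analytic steady-state liver concentration
#'
#' Solves `A x + b = 0` for the steady-state amounts under constant oral
#' input and reports the total liver tissue concentration and the venous
#' plasma concentration, both in uM. The steady state exists and is stable
#' because all eigenvalues of `A` have negative real parts (checked).
#'
#' @param params A [scale_clearances()] result.
#' @return A list of class `css_result` with `css_liver` (uM), `css_plasma`
#'   (uM), `amounts` (mg) and `method = "analytic"`.
#' @export
steady_state_css <- function(params) {
  sys <- pbtk_matrix(params)
  ev <- eigen(sys$A, only.values = TRUE)$values
  worst <- which.max(Re(ev))
  if (Re(ev[worst]) >= 0) {
    stopf("PBTK system matrix is not stable: eigenvalue %d has real part %.3g >= 0",
          worst, Re(ev[worst]))
  }
  x <- solve(sys$A, -sys$b)
  mw <- params$chemical$molecular_weight
  structure(
    list(
      css_liver = mg_per_l_to_um(x[["liver"]] / params$volumes[["liver"]], mw),
      css_plasma = mg_per_l_to_um(x[["venous"]] / params$volumes[["venous"]], mw),
      amounts = x,
      method = "analytic"
    ),
    class = "css_result"
  )
}

#' ODE-integration oracle for the steady state
#'
#' Integrates the model from zero initial amounts under constant infusion
#' (via [deSolve::lsoda()]) until the liver concentration changes by less
#' than `rel_tol` over one simulated day, and returns the terminal
#' concentrations. This is the numerical cross-check for
#' [steady_state_css()].
#'
#' @param params A [scale_clearances()] result.
#' @param rel_tol Relative convergence tolerance per day; default `1e-5`.
#' @param max_days Horizon in days before giving up; default 10000.
#' @return A `css_result` with `method = "ode"`.
#' @export
integrate_to_steady_state <- function(params, rel_tol = 1e-5, max_days = 10000) {
  if (!is_number(rel_tol) || rel_tol <= 0) stopf("rel_tol must be > 0")
  sys <- pbtk_matrix(params)
  deriv <- function(t, x, p) list(as.vector(sys$A %*% x + sys$b))
  x0 <- stats::setNames(numeric(7), COMPARTMENTS)
  if (sys$b[["gut"]] == 0) {
    x_final <- x0  # homogeneous system from zero: trajectory stays zero
  } else {
    chunk_days <- 50
    days_done <- 0
    prev_day_liver <- 0
    x_final <- NULL
    while (is.null(x_final)) {
      times <- seq(0, chunk_days * 24, by = 24)
      sol <- deSolve::lsoda(x0, times, deriv, parms = NULL,
                            rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
      liver_daily <- c(prev_day_liver, sol[-1, "liver"])
      # converged when the one-day change AND the estimated remaining
      # distance to the asymptote (geometric-tail extrapolation of the
      # slowest mode) are both below rel_tol relative to the current level
      d <- diff(liver_daily)
      hit <- integer(0)
      for (t in seq_along(d)[-1]) {
        lvl <- liver_daily[t + 1]
        if (lvl <= 0) next
        if (abs(d[t]) >= rel_tol * lvl) next
        r <- if (d[t - 1] != 0) d[t] / d[t - 1] else 0
        gap <- if (r > 0 && r < 1) abs(d[t]) * r / (1 - r) else abs(d[t])
        if (gap < rel_tol * lvl) { hit <- t; break }
      }
      if (length(hit)) {
        x_final <- stats::setNames(sol[hit + 1, COMPARTMENTS], COMPARTMENTS)
      } else {
        x0 <- stats::setNames(sol[nrow(sol), COMPARTMENTS], COMPARTMENTS)
        prev_day_liver <- liver_daily[length(liver_daily)]
        days_done <- days_done + chunk_days
        if (days_done >= max_days) {
          stopf("ODE integration did not reach steady state within %d days", max_days)
        }
        # slowly clearing parameter sets take many multiples of the initial
        # chunk; grow it geometrically to keep the solver call count low
        chunk_days <- min(chunk_days * 2, 2000)
      }
    }
  }
  mw <- params$chemical$molecular_weight
  structure(
    list(
      css_liver = mg_per_l_to_um(x_final[["liver"]] / params$volumes[["liver"]], mw),
      css_plasma = mg_per_l_to_um(x_final[["venous"]] / params$volumes[["venous"]], mw),
      amounts = x_final,
      method = "ode"
    ),
    class = "css_result"
  )
}

#' Construct (and validate) a population Css distribution
#'
#' @param chemical_id Chemical identifier.
#' @param age_group Population label.
#' @param samples Positive Css samples in uM.
#' @param dose_ref Reference dose the samples were computed at (mg/kg/day).
#' @param ranks Percentile ranks to summarise at.
#' @return A list of class `css_distribution` with `samples` and a
#'   `percentiles` vector recomputable from the samples.
#' @export
css_distribution <- function(chemical_id, age_group, samples, dose_ref = 1,
                             ranks = default_percentile_ranks()) {
  if (!length(samples)) stopf("css_distribution needs at least one sample")
  if (any(!is.finite(samples) | samples <= 0)) stopf("all Css samples must be positive")
  structure(
    list(chemical_id = chemical_id, age_group = age_group,
         dose_ref = dose_ref, samples = as.numeric(samples),
         ranks = ranks, percentiles = pctile(samples, ranks)),
    class = "css_distribution"
  )
}

#' Population liver steady-state concentrations
#'
#' Computes the analytic liver Css for every individual of a sampled
#' population at the given chronic dose and summarises the distribution at
#' the requested percentile ranks.
#'
#' @param population An [sample_population()] result.
#' @param chem An [chemical()].
#' @param dose Chronic oral dose in mg/kg/day; default the unit dose 1.
#' @param ranks Percentile ranks; default [default_percentile_ranks()].
#' @return A [css_distribution()].
#' @export
population_css <- function(population, chem, dose = 1,
                           ranks = default_percentile_ranks()) {
  if (!nrow(population)) stopf("population is empty")
  n <- nrow(population)
  samples <- numeric(n)
  for (i in seq_len(n)) {
    samples[i] <- tryCatch(
      steady_state_css(scale_clearances(population[i, ], chem, dose))$css_liver,
      error = function(e) stopf("individual %d: %s", i, conditionMessage(e))
    )
  }
  css_distribution(chem$chemical_id, attr(population, "age_group") %||% "unknown",
                   samples, dose_ref = dose, ranks = ranks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.css_distribution <- function(x, ...) {
  cat(sprintf("<css_distribution> %s / %s: n = %d at %.3g mg/kg/day\n",
              x$chemical_id, x$age_group, length(x$samples), x$dose_ref))
  print(round(x$percentiles, 3))
  invisible(x)
}
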