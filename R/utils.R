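# Internal helpers shared across modules.

DEFAULT_RANKS <- c(0.1, 1, 2.5, 25, 50, 75, 97.5, 99, 99.9)

#' Default percentile ranks reported throughout the pipeline
#'
#' The ranks cover the median, the central interval (P2.5--P97.5) and the two
#' broader intervals (P1--P99, P0.1--P99.9) used in the probabilistic MOE
#' assessment.
#'
#' @return Numeric vector of percentile ranks in (0, 100).
#' @export
default_percentile_ranks <- function() DEFAULT_RANKS

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Empirical percentiles with linear interpolation between order statistics
# (quantile type 7, the R default). Fixed here so every module reports the
# same estimator; P0.1/P99.9 are sensitive to this choice at n ~ 1000.
pctile <- function(x, ranks = DEFAULT_RANKS) {
  if (any(ranks <= 0 | ranks >= 100)) stopf("percentile ranks must lie strictly inside (0, 100)")
  stats::setNames(
    stats::quantile(x, probs = ranks / 100, type = 7, names = FALSE),
    rank_names(ranks)
  )
}

rank_names <- function(ranks) {
  paste0("P", vapply(ranks, function(r) format(r, trim = TRUE, scientific = FALSE),
                     character(1)))
}

# Run expr with a fixed RNG seed, then restore the caller's RNG state, so
# sampling functions are pure in (spec, seed) and leave no global footprint.
with_preserved_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

warn_extreme_ranks <- function(ranks, n) {
  extreme <- ranks[ranks < 0.5 | ranks > 99.5]
  if (length(extreme) && n < 5000) {
    warnf(
      "extreme percentile ranks (%s) estimated from only n = %d samples; estimates are estimator-sensitive below n = 5000",
      paste(rank_names(extreme), collapse = ", "), n
    )
  }
  invisible(NULL)
}
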