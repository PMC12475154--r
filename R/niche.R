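#' Parameters of the thermal-niche generator
#'
#' Five parameters control the random pool of rectangular thermal niches:
#' `alpha`/`beta` are the lower and upper organismal temperature limits
#' (defaults -2 degC, where sea water is always frozen, and 44 degC, the
#' ceiling for metazoan reproduction); `gamma`/`delta` are the minimum and
#' maximum degrees of eurythermy, i.e. the admissible breadth of the
#' tolerance range (defaults 4 and 20 degC); `n` is the pool size (default
#' 100,000 independent niches).
#'
#' `breadth_formula` selects how the tolerance breadth X is drawn from the
#' uniform deviate d1. `"corrected"` (default) uses
#' `X = d1 * (delta - gamma) + gamma`, so X spans `[gamma, delta]` as the
#' eurythermy parameters require. `"verbatim"` keeps the variant
#' `X = d1 * (delta - gamma) + delta` (X in `[delta, 2*delta - gamma]`),
#' retained for comparison only; it contradicts the definition of
#' gamma/delta as the minimum/maximum tolerance range.
#'
#' @param alpha,beta Lower/upper temperature limits, degC (`alpha < beta`).
#' @param gamma,delta Min/max tolerance-range breadth, degC
#'   (`0 < gamma <= delta <= beta - alpha`).
#' @param n Number of niches (>= 1).
#' @param seed Integer seed for the pool's RNG stream.
#' @param breadth_formula `"corrected"` or `"verbatim"` (see Details).
#' @return A list of class `niche_params`.
#' @export
niche_params <- function(alpha = -2, beta = 44, gamma = 4, delta = 20,
                         n = 100000L, seed = 1L,
                         breadth_formula = c("corrected", "verbatim")) {
  breadth_formula <- match.arg(breadth_formula)
  if (!(alpha < beta)) stop("alpha must be < beta")
  if (!(gamma > 0 && gamma <= delta)) stop("need 0 < gamma <= delta")
  if (!(delta <= beta - alpha)) stop("delta must be <= beta - alpha")
  if (n < 1) stop("n must be >= 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 n = as.integer(n), seed = as.integer(seed),
                 breadth_formula = breadth_formula),
            class = "niche_params")
}

#' Build niches from explicit uniform deviates
#'
#' Maps pairs of uniform deviates (d1, d2) to niche intervals: breadth
#' `X = d1 * (delta - gamma) + gamma` (corrected; see [niche_params()] for
#' the verbatim variant) and centre
#' `Y = d2 * (beta - X/2 - (alpha + X/2)) + (alpha + X/2)`, giving the
#' interval `[Y - X/2, Y + X/2]`, always contained in `[alpha, beta]`.
#' Useful for injecting known draws in tests and sensitivity work.
#'
#' @param d1,d2 Numeric vectors in \[0, 1\] (breadth and centre deviates).
#' @param params A [niche_params()] (its `n` is ignored here).
#' @return A `niche_pool` with `length(d1)` niches.
#' @export
niches_from_draws <- function(d1, d2, params = niche_params()) {
  stopifnot(inherits(params, "niche_params"), length(d1) == length(d2),
            all(d1 >= 0 & d1 <= 1), all(d2 >= 0 & d2 <= 1))
  X <- if (params$breadth_formula == "corrected") {
    d1 * (params$delta - params$gamma) + params$gamma
  } else {
    d1 * (params$delta - params$gamma) + params$delta
  }
  lo_c <- params$alpha + X / 2                 # admissible centre range
  hi_c <- params$beta - X / 2
  Y <- d2 * (hi_c - lo_c) + lo_c
  structure(list(params = params, lower = Y - X / 2, upper = Y + X / 2),
            class = "niche_pool")
}

#' Generate the random pool of rectangular thermal niches
#'
#' Draws `n` niches with a single seeded generator, niche by niche (d1 then
#' d2), so that with the same seed a smaller pool is a prefix of a larger
#' one. Each niche is the temperature interval `[Y - X/2, Y + X/2]` with
#' breadth X and centre Y as described in [niches_from_draws()].
#'
#' @param params A [niche_params()].
#' @return An object of class `niche_pool` with numeric vectors `lower` and
#'   `upper` (degC) and the generating `params`.
#' @examples
#' pool <- generate_niche_pool(niche_params(n = 1000, seed = 42))
#' range(pool$upper - pool$lower)   # within [gamma, delta]
#' @export
generate_niche_pool <- function(params = niche_params()) {
  stopifnot(inherits(params, "niche_params"))
  u <- with_local_seed(params$seed, stats::runif(2L * params$n))
  d1 <- u[seq(1L, 2L * params$n, by = 2L)]
  d2 <- u[seq(2L, 2L * params$n, by = 2L)]
  niches_from_draws(d1, d2, params)
}

#' @export
print.niche_pool <- function(x, ...) {
  cat(sprintf(
    "<niche_pool> %d thermal niches in [%.1f, %.1f] degC, breadth %.2f-%.2f\n",
    length(x$lower), x$params$alpha, x$params$beta,
    min(x$upper - x$lower), max(x$upper - x$lower)))
  invisible(x)
}

#' Thermal suitability of a temperature for every niche
#'
#' A niche is suitable iff `lower <= temperature <= upper` (closed on both
#' ends: the niche is the set of conditions enabling growth, so boundary
#' temperatures are included; the choice has measure-zero effect).
#'
#' @param pool A `niche_pool`.
#' @param temperature A single finite temperature, degC.
#' @return Logical vector, one element per niche.
#' @export
suitability <- function(pool, temperature) {
  stopifnot(inherits(pool, "niche_pool"), length(temperature) == 1,
            is.finite(temperature))
  pool$lower <= temperature & temperature <= pool$upper
}

#' Empirical coverage of the niche pool along temperature
#'
#' Fraction of niches suitable at each temperature -- the Monte-Carlo
#' estimate of the coverage probability P(lower <= t <= upper). Under the
#' corrected breadth formula the exact curve is symmetric about the
#' mid-domain `(alpha + beta)/2` (21 degC at defaults) and maximal on the
#' plateau `[alpha + delta, beta - delta]`: a mid-domain effect in niche
#' space rather than in geographical space.
#'
#' @param pool A `niche_pool`.
#' @param temperatures Numeric vector of temperatures, degC.
#' @return Numeric vector of suitable fractions, same length.
#' @export
niche_coverage <- function(pool, temperatures) {
  stopifnot(inherits(pool, "niche_pool"), all(is.finite(temperatures)))
  vapply(temperatures,
         function(t) mean(pool$lower <= t & t <= pool$upper),
         numeric(1))
}

#' Write / read a niche pool as CSV
#'
#' Plain CSV with columns `niche_id, lower, upper`, so pools generated
#' elsewhere can be injected into the projection stages.
#'
#' @param pool A `niche_pool`.
#' @param path File path.
#' @return `write_niche_pool` returns `path` invisibly; `read_niche_pool`
#'   returns a `niche_pool` (with the default generator parameters attached
#'   but no generative claim about the intervals).
#' @export
write_niche_pool <- function(pool, path) {
  stopifnot(inherits(pool, "niche_pool"))
  utils::write.csv(
    data.frame(niche_id = seq_along(pool$lower),
               lower = pool$lower, upper = pool$upper),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_niche_pool
#' @export
read_niche_pool <- function(path) {
  df <- utils::read.csv(path)
  need <- c("niche_id", "lower", "upper")
  if (!all(need %in% names(df)))
    stop("niche pool CSV must have columns niche_id, lower, upper")
  if (any(df$lower >= df$upper)) stop("every niche needs lower < upper")
  structure(list(params = niche_params(n = nrow(df)),
                 lower = as.numeric(df$lower),
                 upper = as.numeric(df$upper)),
            class = "niche_pool")
}
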