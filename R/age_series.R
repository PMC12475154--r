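#' A time series indexed by geological age
#'
#' The common currency of all temporal analyses: values indexed by age in
#' Ma. The conventional ordering is old to young (strictly decreasing
#' ages, e.g. 541 -> 0 Ma); strictly increasing input is accepted and
#' reordered.
#'
#' @param ages Numeric ages in Ma, strictly monotone.
#' @param values Numeric values, finite, same length as `ages`.
#' @param label Optional short name carried through analyses.
#' @return An object of class `age_series` with fields `ages`, `values`,
#'   `label`.
#' @export
age_series <- function(ages, values, label = "") {
  stopifnot(is.numeric(ages), is.numeric(values),
            length(ages) == length(values), length(ages) >= 1)
  if (!all(is.finite(values))) stop("values must be finite")
  if (!all(is.finite(ages))) stop("ages must be finite")
  if (length(ages) > 1) {
    d <- diff(ages)
    if (all(d > 0)) {          # young -> old supplied; flip to old -> young
      ages <- rev(ages)
      values <- rev(values)
    } else if (!all(d < 0)) {
      stop("ages must be strictly monotone")
    }
  }
  structure(list(ages = as.numeric(ages), values = as.numeric(values),
                 label = as.character(label)),
            class = "age_series")
}

#' @export
print.age_series <- function(x, ...) {
  cat(sprintf("<age_series>%s %d points, %.1f -> %.1f Ma\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$ages), x$ages[1], x$ages[length(x$ages)]))
  invisible(x)
}

#' @export
as.data.frame.age_series <- function(x, ...) {
  data.frame(age_ma = x$ages, value = x$values)
}

#' Write / read an age series as CSV
#'
#' Two-column CSV (`age_ma`, `value`) -- the exchange format for fossil
#' diversity curves, fragmentation indices and simulation ledger series.
#'
#' @param series An [age_series()].
#' @param path File path.
#' @param label Label to attach on read.
#' @export
write_age_series <- function(series, path) {
  stopifnot(inherits(series, "age_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_age_series
#' @export
read_age_series <- function(path, label = "") {
  df <- utils::read.csv(path)
  if (!all(c("age_ma", "value") %in% names(df)))
    stop("age series CSV must have columns age_ma, value")
  age_series(df$age_ma, df$value, label)
}

#' Shape-preserving interpolation of an age series
#'
#' Interpolates onto new ages with a piecewise cubic Hermite interpolating
#' polynomial (PCHIP): values at the source knots are reproduced exactly
#' and the interpolant never overshoots local extrema on monotone
#' segments. No extrapolation: target ages must lie within the source
#' span.
#'
#' @param series An [age_series()].
#' @param target_ages Numeric ages within the source span, strictly
#'   monotone.
#' @return An [age_series()] at `target_ages` (old -> young).
#' @export
interpolate_to_ages <- function(series, target_ages) {
  stopifnot(inherits(series, "age_series"), is.numeric(target_ages),
            length(target_ages) >= 1)
  lo <- min(series$ages); hi <- max(series$ages)
  if (min(target_ages) < lo - 1e-9 || max(target_ages) > hi + 1e-9)
    stop("target ages outside the source age span (no extrapolation)")
  # pchip wants increasing abscissae; age_series stores old -> young
  xi <- rev(series$ages)
  yi <- rev(series$values)
  tgt <- sort(unique(as.numeric(target_ages)), decreasing = TRUE)
  vals <- if (length(xi) <= 2) {
    stats::approx(xi, yi, xout = rev(tgt))$y
  } else {
    pracma::pchip(xi, yi, rev(tgt))
  }
  age_series(tgt, rev(vals), series$label)
}
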