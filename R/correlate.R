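two_tailed_p <- function(r, df) {
  if (df < 1) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- abs(r) * sqrt(df / (1 - r^2))
  2 * stats::pt(-t, df)
}

#' Pearson correlation between two age series
#'
#' Pearson r with the classical two-tailed probability from
#' `t = r * sqrt(df / (1 - r^2))`, df = n - 2. The two series must already
#' share the same ages (align them beforehand with
#' [interpolate_to_ages()]; correlation never resamples).
#'
#' @param x,y [age_series()] objects on identical ages, n >= 3.
#' @return An object of class `cor_result` with fields `r`, `n`, `df`,
#'   `p`, and (after [adjusted_p()]) `df_adj`, `p_acf`.
#' @export
correlate <- function(x, y) {
  stopifnot(inherits(x, "age_series"), inherits(y, "age_series"))
  if (length(x$ages) != length(y$ages) ||
      max(abs(x$ages - y$ages)) > 1e-9)
    stop("series must share the same ages (interpolate first)")
  n <- length(x$values)
  if (n < 3) stop("need at least 3 paired samples")
  if (stats::sd(x$values) == 0 || stats::sd(y$values) == 0)
    stop("zero variance in one of the series")
  r <- stats::cor(x$values, y$values)
  df <- n - 2L
  structure(list(r = r, n = n, df = df, p = two_tailed_p(r, df),
                 df_adj = NA_integer_, p_acf = NA_real_),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("<cor_result> r = %.3f, n = %d, df = %d, p = %.3g", x$r, x$n,
              x$df, x$p))
  if (!is.na(x$df_adj))
    cat(sprintf(", df_adj = %d, p_acf = %.3g", x$df_adj, x$p_acf))
  if (!is.null(x$df_star)) cat(sprintf(", df* = %s", x$df_star))
  cat("\n")
  invisible(x)
}

#' Autocorrelation-corrected probability (effective degrees of freedom)
#'
#' Adjusts the correlation's degrees of freedom for serial autocorrelation
#' with the effective-sample-size formula
#' `1/N* = 1/N + (2/N) * sum_j rho_xx(j) * rho_yy(j)`, summing lags
#' j = 1..floor(N/5) of the biased (1/N-normalised) sample
#' autocorrelations. The corrected probability `p_acf` is the two-tailed
#' probability of the same r evaluated at `df_adj = floor(N*) - 2`
#' (floored at 2 so the t distribution is defined). When the estimated
#' lagged products sum to a negative value so large that 1/N* is
#' non-positive, no correction is applied (`df_adj = df`).
#'
#' @param x,y The [age_series()] pair used for the correlation.
#' @param result The [correlate()] result for that pair (recomputed when
#'   omitted).
#' @param max_lag_frac Lag truncation as a fraction of N (default 1/5).
#' @return The `cor_result` with `df_adj` and `p_acf` filled in.
#' @export
adjusted_p <- function(x, y, result = NULL, max_lag_frac = 0.2) {
  if (is.null(result)) result <- correlate(x, y)
  stopifnot(inherits(result, "cor_result"))
  n <- result$n
  J <- floor(n * max_lag_frac)
  if (J >= 1) {
    rxx <- stats::acf(x$values, lag.max = J, plot = FALSE,
                      demean = TRUE)$acf[-1L]
    ryy <- stats::acf(y$values, lag.max = J, plot = FALSE,
                      demean = TRUE)$acf[-1L]
    inv_nstar <- 1 / n + (2 / n) * sum(rxx * ryy)
  } else {
    inv_nstar <- 1 / n
  }
  df_adj <- if (inv_nstar <= 0) result$df
            else max(2L, as.integer(floor(1 / inv_nstar)) - 2L)
  result$df_adj <- df_adj
  result$p_acf <- two_tailed_p(result$r, df_adj)
  result
}

#' Minimal degrees of freedom keeping a correlation significant
#'
#' The smallest integer df >= 1 such that the two-tailed probability of
#' `t = |r| * sqrt(df / (1 - r^2))` is <= 0.05. A small df* means the
#' correlation would survive even a drastic loss of independent
#' information (e.g. from spatial autocorrelation). Returns `NA`
#' ("none") when no df up to `cap` achieves significance (including
#' r = 0); |r| = 1 gives df* = 1.
#'
#' @param r Pearson correlation, |r| <= 1.
#' @param cap Largest df scanned.
#' @return Integer df*, or `NA_integer_`.
#' @export
minimal_df <- function(r, cap = 100000L) {
  stopifnot(is.numeric(r), length(r) == 1, abs(r) <= 1)
  if (r == 0) return(NA_integer_)
  if (abs(r) >= 1) return(1L)
  t_of_df <- function(df) abs(r) * sqrt(df / (1 - r^2))
  # p(df) is decreasing in df for fixed r; scan in growing chunks
  chunk <- 1024L
  lo <- 1L
  while (lo <= cap) {
    dfs <- lo:min(lo + chunk - 1L, cap)
    p <- 2 * stats::pt(-t_of_df(dfs), dfs)
    hit <- which(p <= 0.05)
    if (length(hit)) return(dfs[hit[1L]])
    lo <- lo + chunk
    chunk <- chunk * 4L
  }
  NA_integer_
}

#' Pearson correlation between two richness maps
#'
#' Correlates two maps over their jointly masked cells (flattened to
#' vectors), reporting r, the classical p, and the minimal degrees of
#' freedom df* ([minimal_df()]) -- the spatial-autocorrelation diagnostic:
#' the correlation is robust when df* is far below the actual cell count.
#'
#' @param a,b [richness_map()] objects on the same grid.
#' @return A `cor_result` with an extra `df_star` field.
#' @export
correlate_maps <- function(a, b) {
  stopifnot(inherits(a, "richness_map"), inherits(b, "richness_map"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("maps are not on the same grid")
  joint <- a$mask$cells & b$mask$cells
  if (sum(joint) < 3) stop("fewer than 3 jointly masked cells")
  va <- a$values[joint]
  vb <- b$values[joint]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance on the joint mask")
  n <- sum(joint)
  r <- stats::cor(va, vb)
  out <- structure(list(r = r, n = n, df = n - 2L,
                        p = two_tailed_p(r, n - 2L),
                        df_adj = NA_integer_, p_acf = NA_real_),
                   class = "cor_result")
  out$df_star <- minimal_df(r)
  out
}

#' Correlation table for a set of age series
#'
#' Batch driver reproducing the shape of a drivers-versus-index
#' correlation table: every requested pair is aligned by construction
#' (series must share ages), correlated, and corrected for temporal
#' autocorrelation.
#'
#' @param series Named list of [age_series()] on identical ages.
#' @param pairs Optional 2-column character matrix of series names; all
#'   unordered pairs when omitted.
#' @return A data.frame with columns `pair`, `x`, `y`, `r`, `p`, `p_acf`,
#'   `df`, `df_adj`.
#' @export
correlation_table <- function(series, pairs = NULL) {
  stopifnot(is.list(series), !is.null(names(series)),
            all(nzchar(names(series))))
  nm <- names(series)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nm, 2))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    xn <- pairs[i, 1]; yn <- pairs[i, 2]
    res <- adjusted_p(series[[xn]], series[[yn]])
    data.frame(pair = paste(xn, yn, sep = " ~ "), x = xn, y = yn,
               r = res$r, p = res$p, p_acf = res$p_acf, df = res$df,
               df_adj = res$df_adj)
  })
  do.call(rbind, rows)
}
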