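#' 0-1 standardisation of an age series
#'
#' Affine rescaling `(x - min) / (max - min)`: the minimum maps to 0, the
#' maximum to 1, order is preserved. Used to remove scale effects before
#' combining diversity curves from heterogeneous databases.
#'
#' @param series An [age_series()].
#' @return The standardised [age_series()].
#' @export
standardise_01 <- function(series) {
  stopifnot(inherits(series, "age_series"))
  m1 <- min(series$values)
  m2 <- max(series$values)
  if (m2 == m1) stop("degenerate range: series is constant")
  age_series(series$ages, (series$values - m1) / (m2 - m1), series$label)
}

#' Composite fossil species richness index from multiple diversity curves
#'
#' Combines two or more fossil diversity curves into a single index that
#' damps the preservation and sampling biases of any one database. Each
#' curve is 0-1 standardised ([standardise_01()]), interpolated to the
#' target ages with shape-preserving cubics ([interpolate_to_ages()]), the
#' columns are z-scored, and a standardised PCA (PCA of the correlation
#' matrix) is applied. The first principal component is the index; its
#' sign is oriented so that it correlates positively with the across-curve
#' mean of the standardised interpolated curves (ties broken toward a
#' positive loading on the first curve), since a PCA score sign is
#' otherwise arbitrary.
#'
#' Target ages falling outside the curves' common age span are dropped
#' with a warning (no extrapolation); an error is raised if none remain.
#'
#' @param curves List of two or more [age_series()] objects.
#' @param target_ages Ages (Ma) at which the index is built, typically the
#'   simulation time slices.
#' @return An object of class `fossil_index`: `index` (an [age_series()]
#'   of PC1 scores), `explained` (variance fraction per component),
#'   `loadings` (PC1 loading per curve), `curves_used`, `matrix` (the
#'   standardised interpolated curves, columns = curves).
#' @export
build_fossil_index <- function(curves, target_ages) {
  stopifnot(is.list(curves))
  if (length(curves) < 2) stop("need at least 2 fossil curves")
  stopifnot(all(vapply(curves, inherits, logical(1), "age_series")))
  span_lo <- max(vapply(curves, function(s) min(s$ages), numeric(1)))
  span_hi <- min(vapply(curves, function(s) max(s$ages), numeric(1)))
  if (span_lo >= span_hi) stop("curves have no overlapping age span")
  tgt <- sort(unique(as.numeric(target_ages)), decreasing = TRUE)
  keep <- tgt >= span_lo - 1e-9 & tgt <= span_hi + 1e-9
  if (!any(keep)) stop("no target ages inside the curves' common age span")
  if (!all(keep))
    warning(sprintf("%d target age(s) outside the common span dropped",
                    sum(!keep)))
  tgt <- tgt[keep]
  if (length(tgt) < 3) stop("need at least 3 usable target ages")

  std <- lapply(curves, standardise_01)
  mat <- vapply(std,
                function(s) interpolate_to_ages(s, tgt)$values,
                numeric(length(tgt)))
  labels <- vapply(seq_along(curves), function(i) {
    if (nzchar(curves[[i]]$label)) curves[[i]]$label
    else sprintf("curve%d", i)
  }, character(1))
  colnames(mat) <- labels

  pca <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  scores <- pca$x[, 1L]
  loadings <- pca$rotation[, 1L]
  consensus <- rowMeans(mat)
  ori <- if (stats::sd(consensus) > 0) stats::cor(scores, consensus) else 0
  flip <- if (is.finite(ori) && abs(ori) > 1e-12) ori < 0
          else loadings[1L] < 0
  if (flip) {
    scores <- -scores
    loadings <- -loadings
  }
  explained <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(index = age_series(tgt, unname(scores),
                                    "fossil species richness index"),
                 explained = explained, loadings = loadings,
                 curves_used = labels, matrix = mat),
            class = "fossil_index")
}

#' @export
print.fossil_index <- function(x, ...) {
  cat(sprintf(
    "<fossil_index> PC1 of %d curves over %d ages; PC1 explains %.1f%%\n",
    length(x$curves_used), length(x$index$ages), 100 * x$explained[1L]))
  invisible(x)
}
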