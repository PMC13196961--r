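#' Elbow of a ranked curve by maximum Euclidean distance
#'
#' Finds the elbow of a ranked value curve: with x = rank (1..m) and
#' y = value, a straight chord is drawn from the first to the last point,
#' and the elbow is the point at maximum perpendicular distance from that
#' chord.  By default both axes are rescaled to \[0, 1\] first, which
#' makes the result invariant to units and to the number of points.
#'
#' @param values numeric vector, already sorted in the stated order.
#' @param descending logical; the expected sort order of `values`.
#' @param normalize rescale both axes to \[0, 1\] before computing
#'   distances (default `TRUE`).
#' @return A list with `index` (rank position of the elbow), `value`
#'   (the curve value there, on the original scale), `distance` (the
#'   maximum perpendicular distance, on the scale used), `degenerate`
#'   (`TRUE` when the curve is a straight line, including the all-equal
#'   case, in which case `index` is 1), and `defined` (`FALSE` when fewer
#'   than 3 points were supplied, leaving the threshold undefined).
#'   Ties are broken toward the smallest index.
#' @export
elbow_point <- function(values, descending = TRUE, normalize = TRUE) {
  stopifnot(is.numeric(values))
  m <- length(values)
  if (m < 3L) {
    return(list(index = NA_integer_, value = NA_real_, distance = NA_real_,
                degenerate = FALSE, defined = FALSE))
  }
  ok <- if (descending) !is.unsorted(rev(values)) else !is.unsorted(values)
  if (!ok) {
    stop("`values` must be sorted ", if (descending) "descending" else
      "ascending", call. = FALSE)
  }
  x <- as.numeric(seq_len(m))
  y <- values
  if (normalize) {
    x <- (x - 1) / (m - 1)
    yr <- range(y)
    y <- if (diff(yr) > 0) (y - yr[1L]) / diff(yr) else rep(0, m)
  }
  # perpendicular distance of each point from the chord through the
  # first and last points: |cross product| / chord length
  dx <- x[m] - x[1L]
  dy <- y[m] - y[1L]
  chord <- sqrt(dx^2 + dy^2)
  d <- abs(dx * (y - y[1L]) - dy * (x - x[1L])) / chord
  idx <- which.max(d)  # first maximum = smallest index
  degenerate <- d[idx] <= chord * 1e-12
  if (degenerate) idx <- 1L
  list(index = as.integer(idx), value = values[idx], distance = d[idx],
       degenerate = degenerate, defined = TRUE)
}
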