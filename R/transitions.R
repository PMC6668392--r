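#' Piecewise-linear crossing and three-point quadratic peak
#'
#' `interp_crossing()` scans `x` in increasing order for the first segment on
#' which `y` crosses `level` in the requested direction and returns the
#' linearly interpolated crossing location (warning if the curve crosses more
#' than once). `quadratic_peak()` returns the vertex of the parabola through
#' the maximal point of `y` and its two neighbours.
#'
#' @param x increasing numeric vector.
#' @param y numeric vector of the same length.
#' @param level crossing level.
#' @param direction `"down"` (y falls through `level`) or `"up"`.
#' @return The interpolated x-location.
#' @export
interp_crossing <- function(x, y, level, direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  n <- length(x)
  hit <- if (direction == "down") {
    which(y[-n] >= level & y[-1] < level)
  } else {
    which(y[-n] <= level & y[-1] > level)
  }
  if (length(hit) == 0)
    stop(sprintf("no %sward crossing of %g found", direction, level))
  if (length(hit) > 1)
    warning("multiple crossings; taking the first in increasing x")
  i <- hit[1]
  x[i] + (level - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
}

#' @rdname interp_crossing
#' @export
quadratic_peak <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  i <- which.max(y)
  if (i == 1 || i == length(y))
    stop("maximum lies on the grid boundary; widen the grid")
  x1 <- x[i - 1]; x2 <- x[i]; x3 <- x[i + 1]
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
  if (denom == 0) return(x2) # flat top: keep the grid maximum
  x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)) / denom
}

#' Locate the four transitions delimiting the five phases of degradation
#'
#' From an event-probability curve:
#' * `q1`: habitat loss at which the shrinkage probability falls below 0.99
#'   (appearance of appreciable patch splitting), by piecewise-linear
#'   interpolation;
#' * `q2`: the percolation threshold (connected to fragmented), either a
#'   wrapping-cluster estimate passed as `q_c` or the geometry's reference
#'   value;
#' * `q3`: the peak of the splitting probability, by a three-point quadratic
#'   fit around the grid maximum;
#' * `q4`: habitat loss at which the loss probability overtakes both
#'   shrinkage and splitting, by interpolating the first upward zero
#'   crossing of `p_loss - max(p_shrink, p_split)`.
#'
#' The five phases are the half-open intervals `[0, q1), [q1, q2), [q2, q3),
#' [q3, q4), [q4, 1]`.
#'
#' @param curve an `"event_curve"` from [build_curve()], or its `curve`
#'   data frame.
#' @param q_c percolation threshold as a habitat-loss fraction (`1 - p_c`),
#'   e.g. from [estimate_percolation_threshold()]. When `NULL`, the
#'   geometry's reference value is used (requires an `"event_curve"`).
#' @return An object of class `"transition_set"`: `q1..q4` and the `phases`
#'   table.
#' @export
detect_transitions <- function(curve, q_c = NULL) {
  if (inherits(curve, "event_curve")) {
    geometry <- curve$geometry
    dat <- curve$curve
  } else {
    geometry <- attr(curve, "geometry")
    dat <- curve
  }
  stopifnot(is.data.frame(dat),
            all(c("q", "p_loss", "p_shrink", "p_split") %in% names(dat)))
  dat <- dat[order(dat$q), ]
  if (is.null(q_c)) {
    if (is.null(geometry))
      stop("q_c is required when the curve carries no geometry")
    q_c <- make_lattice(geometry, 3)$q_c
  }
  q1 <- interp_crossing(dat$q, dat$p_shrink, 0.99, "down")
  q3 <- quadratic_peak(dat$q, dat$p_split)
  q4 <- interp_crossing(dat$q, dat$p_loss - pmax(dat$p_shrink, dat$p_split),
                        0, "up")
  qs <- c(q1 = q1, q2 = unname(q_c), q3 = q3, q4 = q4)
  if (is.unsorted(qs))
    warning("transitions are not strictly ordered; curve may be too noisy")
  phases <- data.frame(
    phase = 1:5,
    q_from = c(0, qs),
    q_to = c(qs, 1))
  structure(
    list(geometry = geometry, q1 = q1, q2 = unname(q_c), q3 = q3, q4 = q4,
         phases = phases),
    class = "transition_set"
  )
}

#' @export
print.transition_set <- function(x, ...) {
  cat(sprintf("transitions (%s): q1 = %.3f, q2 = %.3f, q3 = %.3f, q4 = %.3f\n",
              if (is.null(x$geometry)) "?" else x$geometry,
              x$q1, x$q2, x$q3, x$q4))
  cat("phases (habitat loss q):\n")
  print(transform(x$phases, q_from = round(q_from, 3), q_to = round(q_to, 3)),
        row.names = FALSE)
  invisible(x)
}
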