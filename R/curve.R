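#' Analytic probability of patch loss on an infinite lattice
#'
#' On an uncorrelated random map, a removal causes patch loss exactly when
#' the focal habitat site has no habitat neighbour. The probability of that
#' local configuration at a random site is `p (1 - p)^z` with `z` the
#' coordination number (6 on the triangular/hexagonal-cell adjacency, 4 on
#' the square lattice); conditioned on the removal of a habitat site it is
#' `(1 - p)^z`.
#'
#' @param p habitat fraction(s) in `[0, 1]`.
#' @param geometry `"hex6"` or `"square4"`.
#' @param conditioned if `TRUE`, return the per-removal-event probability
#'   `(1 - p)^z`; otherwise the raw per-site probability `p (1 - p)^z`.
#' @return Numeric vector of probabilities.
#' @examples
#' analytic_loss_probability(0.5, "hex6")    # 0.5 * 0.5^6
#' analytic_loss_probability(0.5, "square4") # 0.5 * 0.5^4
#' @export
analytic_loss_probability <- function(p, geometry = c("hex6", "square4"),
                                      conditioned = FALSE) {
  geometry <- match.arg(geometry)
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  z <- if (geometry == "hex6") 6 else 4
  if (conditioned) (1 - p)^z else p * (1 - p)^z
}

#' Default simulation grids
#'
#' The per-geometry habitat-fraction grids used for the event-probability
#' curves: for the six-neighbour lattice, p from 0.05 to 0.95 in steps of
#' 0.05, refined to steps of 0.01 between 0.45 and 0.55, plus 0.57, 0.63
#' and 0.67; for the square lattice, p from 0.05 to 0.95 in steps of 0.05,
#' refined to steps of 0.01 between 0.45 and 0.80. `default_q_grid()` is
#' the same grid expressed as habitat loss `q = 1 - p`.
#'
#' @param geometry `"hex6"` or `"square4"`.
#' @return Increasing numeric vector.
#' @export
default_p_grid <- function(geometry = c("hex6", "square4")) {
  geometry <- match.arg(geometry)
  p <- if (geometry == "hex6") {
    c(seq(0.05, 0.95, by = 0.05), seq(0.45, 0.55, by = 0.01), 0.57, 0.63, 0.67)
  } else {
    c(seq(0.05, 0.95, by = 0.05), seq(0.45, 0.80, by = 0.01))
  }
  sort(unique(round(p, 2)))
}

#' @rdname default_p_grid
#' @export
default_q_grid <- function(geometry = c("hex6", "square4")) {
  sort(round(1 - default_p_grid(geometry), 2))
}

#' Build event-probability and amplification curves over a q-grid
#'
#' Runs the swap dynamics once per grid point (with per-point seeds derived
#' from `seed`) and collects, per habitat-loss level `q`: the probabilities
#' of loss, shrinkage and splitting conditioned on removal events (they sum
#' to one by construction), their binomial standard errors, and the
#' amplification factor of effective habitat loss for every `m` in
#' `m_list`.
#'
#' @param geometry `"hex6"` or `"square4"`.
#' @param q_grid increasing habitat-loss levels in (0, 1); defaults to the
#'   geometry's [default_q_grid()].
#' @param n_events elementary events per grid point (default 1e5; the
#'   published curves used 6e6).
#' @param side lattice side length (default 100).
#' @param m_list minimum viable patch sizes (default 1:9).
#' @param seed integer seed for the whole curve.
#' @return An object of class `"event_curve"`: a list with `curve` (one row
#'   per q: `q, n_events, p_loss, p_shrink, p_split, se_loss, se_shrink,
#'   se_split`), `amplification` (long table `q, m, amplification, se,
#'   n_removals`), `gain`, and the per-point `seeds`.
#' @export
build_curve <- function(geometry = c("hex6", "square4"), q_grid = NULL,
                        n_events = 1e5, side = 100, m_list = 1:9,
                        seed = NULL) {
  geometry <- match.arg(geometry)
  if (is.null(q_grid)) q_grid <- default_q_grid(geometry)
  if (any(q_grid <= 0 | q_grid >= 1) || is.unsorted(q_grid, strictly = TRUE))
    stop("q_grid must be strictly increasing within (0, 1)")
  lattice <- make_lattice(geometry, side)
  if (!is.null(seed)) set.seed(seed)
  point_seeds <- sample.int(2147483646L, length(q_grid))

  rows <- vector("list", length(q_grid))
  amp <- vector("list", length(q_grid))
  gain <- vector("list", length(q_grid))
  for (i in seq_along(q_grid)) {
    tl <- run_events(lattice, q_grid[i], n_events, seed = point_seeds[i],
                     m_list = m_list)
    rows[[i]] <- data.frame(
      q = q_grid[i], n_events = n_events,
      p_loss = unname(tl$probs["loss"]),
      p_shrink = unname(tl$probs["shrinkage"]),
      p_split = unname(tl$probs["splitting"]),
      se_loss = unname(tl$se["loss"]),
      se_shrink = unname(tl$se["shrinkage"]),
      se_split = unname(tl$se["splitting"]))
    amp[[i]] <- cbind(q = q_grid[i], tl$amplification)
    gain[[i]] <- cbind(q = q_grid[i], tl$gain)
  }
  structure(
    list(geometry = geometry, side = side, n_events = n_events,
         m_list = m_list,
         curve = do.call(rbind, rows),
         amplification = do.call(rbind, amp),
         gain = do.call(rbind, gain),
         seeds = data.frame(q = q_grid, seed = point_seeds),
         seed = seed),
    class = "event_curve"
  )
}

#' @export
print.event_curve <- function(x, ...) {
  cat(sprintf("event curve: %s L=%d, %d q-points, %s events each\n",
              x$geometry, x$side, nrow(x$curve),
              format(x$n_events, big.mark = ",")))
  print(utils::head(x$curve, 4))
  if (nrow(x$curve) > 4) cat("...\n")
  invisible(x)
}
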