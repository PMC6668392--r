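#' Effective habitat loss of one removal event
#'
#' A patch counts toward a population's living area only if it has at least
#' `m` habitat sites. The effective habitat loss of a removal event is the
#' change of living area it causes: `s [s >= m] - sum_i s_i [s_i >= m]`,
#' where `s` is the affected patch size before the event and `s_i` the
#' fragment sizes after (none for a loss event, `s - 1` for a shrinkage).
#' It is never negative: removals from patches already below `m` cost
#' nothing, while splitting a size-3 patch into two singletons costs 3
#' living-area sites at `m = 2`. For `m = 1` every removal costs exactly 1.
#'
#' For events whose large sizes are capped (engine streams; see
#' [run_events()]), the equivalent form
#' `[s >= m] * (1 + sum of fragment sizes below m)` is used, which is exact
#' whenever the cap exceeds `m`.
#'
#' @param event a removal-side `"event_record"` (loss, shrinkage or
#'   splitting).
#' @param m minimum viable patch size (integer >= 1).
#' @return A non-negative integer.
#' @examples
#' lat <- make_lattice("hex6", 7)
#' ls <- landscape_from_matrix(matrix(0, 7, 7), "hex6")
#' ls$occupancy[c(11, 12, 13)] <- 1L
#' ls <- landscape_from_matrix(as.matrix(ls), "hex6")
#' ev <- classify_removal(ls, 12) # splits a 3-site patch into {1, 1}
#' effective_loss_of_event(ev, m = 2) # 3
#' @export
effective_loss_of_event <- function(event, m) {
  stopifnot(inherits(event, "event_record"))
  if (!event$event_type %in% REMOVAL_TYPES)
    stop("event is addition-side; effective loss is defined for removals")
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) stop("m must be an integer >= 1")
  s_viable <- event$capped_before[1] || event$sizes_before[1] >= m
  if (any(event$capped_after) || any(event$capped_before)) {
    cap <- min(c(event$sizes_after[event$capped_after],
                 event$sizes_before[event$capped_before]))
    if (cap <= m)
      stop("event sizes are capped below m + 1; re-run with a larger m_list")
  }
  if (!s_viable) return(0L)
  small <- !event$capped_after & event$sizes_after < m
  1L + sum(event$sizes_after[small])
}

#' Amplification factor of effective habitat loss
#'
#' Averages [effective_loss_of_event()] over a stream of removal events, for
#' each minimum viable patch size in `m`. Since every removal destroys
#' exactly one habitat site, this mean is the factor by which the loss of
#' living area amplifies the actual habitat loss; it is exactly 1 for
#' `m = 1`.
#'
#' @param events a non-empty list of removal-side `"event_record"`s (e.g.
#'   from [tally_events()]).
#' @param m integer vector of minimum viable patch sizes.
#' @return A data frame with one row per `m`: `m`, `amplification`, `se`
#'   (standard error of the mean) and `n_removals`.
#' @export
amplification_factor <- function(events, m) {
  if (length(events) == 0) stop("empty event stream")
  if (inherits(events, "event_record")) events <- list(events)
  m <- sort(unique(as.integer(m)))
  out <- lapply(m, function(mi) {
    el <- vapply(events, effective_loss_of_event, integer(1), m = mi)
    data.frame(m = mi, amplification = mean(el),
               se = if (length(el) > 1) sd(el) / sqrt(length(el)) else NA_real_,
               n_removals = length(el))
  })
  do.call(rbind, out)
}
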