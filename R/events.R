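EVENT_TYPES <- c("loss", "shrinkage", "splitting",
                 "formation", "enlargement", "coalescence")
REMOVAL_TYPES <- EVENT_TYPES[1:3]
ADDITION_TYPES <- EVENT_TYPES[4:6]

new_event_record <- function(type, site, coords, sizes_before, sizes_after,
                             capped_before = logical(length(sizes_before)),
                             capped_after = logical(length(sizes_after))) {
  structure(
    list(event_type = type, site = site, site_coords = coords,
         sizes_before = as.integer(sizes_before),
         sizes_after = as.integer(sizes_after),
         capped_before = capped_before, capped_after = capped_after),
    class = "event_record"
  )
}

#' @export
print.event_record <- function(x, ...) {
  fmt <- function(s, cp) {
    if (length(s) == 0) return("-")
    paste(ifelse(cp, paste0(">=", s), s), collapse = ",")
  }
  cat(sprintf("%s at site %d (row %d, col %d): sizes %s -> %s\n",
              x$event_type, x$site, x$site_coords[1], x$site_coords[2],
              fmt(x$sizes_before, x$capped_before),
              fmt(x$sizes_after, x$capped_after)))
  invisible(x)
}

resolve_site <- function(landscape, site) {
  if (length(site) == 2L)
    site <- site_index(landscape$lattice, site[1], site[2])
  site <- as.integer(site)
  if (length(site) != 1L || is.na(site) || site < 1L ||
      site > landscape$lattice$n_sites)
    stop("invalid site index")
  site
}

#' Classify the removal or addition of a single site
#'
#' `classify_removal()` classifies what would happen if the given habitat
#' site were removed: `"loss"` if it has no habitat neighbours (the patch
#' was that single site), `"shrinkage"` if its habitat neighbours stay
#' mutually connected after removal, `"splitting"` otherwise, with all
#' fragment sizes enumerated exactly. `classify_addition()` is the mirror:
#' `"formation"` (no adjacent patch), `"enlargement"` (one adjacent patch)
#' or `"coalescence"` (two or more adjacent patches merge). Classification
#' never mutates the landscape.
#'
#' @param landscape a `"landscape"` object.
#' @param site site index in `1..N`, or a `c(row, col)` pair.
#' @return An `"event_record"`: event type, site, and the patch sizes before
#'   and after the change (for a removal, `sizes_before` is the affected
#'   patch and `sizes_after` the fragments; for an addition, `sizes_before`
#'   lists the joined patches and `sizes_after` the merged patch).
#' @examples
#' lat <- make_lattice("square4", 5)
#' ls <- landscape_from_matrix(diag(5) * 0, "square4")
#' ls$occupancy[13] <- 1L  # single isolated site at (3,3)
#' ls <- landscape_from_matrix(matrix(ls$occupancy, 5, byrow = TRUE), "square4")
#' classify_removal(ls, c(3, 3))  # loss
#' @export
classify_removal <- function(landscape, site) {
  stopifnot(inherits(landscape, "landscape"))
  site <- resolve_site(landscape, site)
  if (landscape$occupancy[site] == 0L)
    stop("site is not a habitat site")
  res <- classify_site_cpp(landscape$occupancy, kind_code(landscape$lattice),
                           landscape$lattice$side, site - 1L, TRUE,
                           landscape$lattice$n_sites + 1L)
  ord <- order(res$parts, decreasing = TRUE)
  new_event_record(EVENT_TYPES[res$type], site,
                   site_coords(landscape$lattice, site)[1, ],
                   sizes_before = res$single,
                   sizes_after = res$parts[ord],
                   capped_before = res$single_capped,
                   capped_after = res$parts_capped[ord])
}

#' @rdname classify_removal
#' @export
classify_addition <- function(landscape, site) {
  stopifnot(inherits(landscape, "landscape"))
  site <- resolve_site(landscape, site)
  if (landscape$occupancy[site] != 0L)
    stop("site is not a non-habitat site")
  res <- classify_site_cpp(landscape$occupancy, kind_code(landscape$lattice),
                           landscape$lattice$side, site - 1L, FALSE,
                           landscape$lattice$n_sites + 1L)
  ord <- order(res$parts, decreasing = TRUE)
  new_event_record(EVENT_TYPES[res$type], site,
                   site_coords(landscape$lattice, site)[1, ],
                   sizes_before = res$parts[ord],
                   sizes_after = res$single,
                   capped_before = res$parts_capped[ord],
                   capped_after = res$single_capped)
}

#' Apply one constant-density swap
#'
#' Draws a removal target uniformly from the habitat sites and an addition
#' target uniformly from the non-habitat sites of the pre-swap state, then
#' classifies and applies the removal first and classifies the addition
#' against the intermediate state before applying it. The habitat count is
#' unchanged after the pair.
#'
#' @param landscape a `"landscape"` object with `0 < n_habitat < N`.
#' @return A list with the updated `landscape` and the two `"event_record"`s
#'   `removal` and `addition`.
#' @export
apply_swap <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  N <- landscape$lattice$n_sites
  if (landscape$n_habitat <= 0L || landscape$n_habitat >= N)
    stop("swap dynamics needs 0 < n_habitat < N")
  hab <- which(landscape$occupancy == 1L)
  non <- which(landscape$occupancy == 0L)
  rsite <- hab[sample.int(length(hab), 1L)]
  asite <- non[sample.int(length(non), 1L)]
  removal <- classify_removal(landscape, rsite)
  landscape$occupancy[rsite] <- 0L
  landscape$n_habitat <- landscape$n_habitat - 1L
  addition <- classify_addition(landscape, asite)
  landscape$occupancy[asite] <- 1L
  landscape$n_habitat <- landscape$n_habitat + 1L
  list(landscape = landscape, removal = removal, addition = addition)
}

#' Run the swap dynamics and tally elementary events
#'
#' Streams `n_events` elementary events (each removal and each addition
#' counts as one event, so `n_events/2` swaps) on a landscape at habitat
#' loss `q`, starting from a fresh uniform random configuration unless a
#' `landscape` is supplied. The run tallies the six event types and, in the
#' same pass, accumulates the effective habitat loss per removal for every
#' minimum viable patch size in `m_list` (and the mirror effective gain per
#' addition, kept separate).
#'
#' @param lattice a [make_lattice()] object.
#' @param q habitat-loss fraction (`p = 1 - q`).
#' @param n_events even positive number of elementary events.
#' @param seed optional integer seed; the whole run is deterministic given
#'   the seed.
#' @param m_list integer vector of minimum viable patch sizes (default 1:9).
#'   Patch and fragment sizes are tracked exactly up to `max(m_list) + 1`
#'   and capped above, which leaves all effective-loss values exact.
#' @param record_events keep the full event log (memory ~ `n_events`; meant
#'   for small runs and the event-stream CSV export).
#' @param landscape optional starting `"landscape"` (overrides `q`).
#' @return An object of class `"event_tally"`: counts per event type,
#'   removal-conditioned probabilities with binomial standard errors, the
#'   amplification table (one row per `m`), the mirror gain table, and the
#'   final occupancy.
#' @export
run_events <- function(lattice, q, n_events, seed = NULL, m_list = 1:9,
                       record_events = FALSE, landscape = NULL) {
  stopifnot(inherits(lattice, "lattice"))
  n_events <- as.numeric(n_events)
  if (length(n_events) != 1L || is.na(n_events) || n_events <= 0 ||
      n_events %% 2 != 0)
    stop("n_events must be a positive even number")
  m_list <- sort(unique(as.integer(m_list)))
  if (length(m_list) == 0L || any(m_list < 1L))
    stop("m_list must contain integers >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(landscape)) {
    if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
      stop("q must be in (0, 1)")
    landscape <- random_landscape(lattice, 1 - q)
  } else {
    stopifnot(inherits(landscape, "landscape"))
    q <- 1 - landscape$n_habitat / lattice$n_sites
  }
  n_pairs <- as.integer(n_events / 2)
  res <- run_events_cpp(landscape$occupancy, kind_code(lattice),
                        lattice$side, n_pairs, m_list, record_events)

  counts <- res$counts
  names(counts) <- EVENT_TYPES
  probs <- counts[REMOVAL_TYPES] / n_pairs
  se <- sqrt(probs * (1 - probs) / n_pairs)
  addition_probs <- counts[ADDITION_TYPES] / n_pairs
  addition_se <- sqrt(addition_probs * (1 - addition_probs) / n_pairs)

  mk_table <- function(sum, sumsq) {
    mean <- sum / n_pairs
    var <- pmax(0, (sumsq - n_pairs * mean^2) / (n_pairs - 1))
    data.frame(m = m_list, amplification = mean,
               se = sqrt(var / n_pairs), n_removals = n_pairs)
  }
  amplification <- mk_table(res$amp_sum, res$amp_sumsq)
  gain <- mk_table(res$gain_sum, res$gain_sumsq)
  names(gain)[names(gain) == "n_removals"] <- "n_additions"

  events <- NULL
  if (record_events) events <- decode_event_log(res, lattice)

  structure(
    list(geometry = lattice$kind, side = lattice$side, q = q,
         n_events = n_events, counts = counts,
         n_removals = n_pairs, n_additions = n_pairs,
         probs = probs, se = se,
         addition_probs = addition_probs, addition_se = addition_se,
         amplification = amplification, gain = gain,
         m_list = m_list, size_cap = res$cap,
         events = events,
         landscape_final = new_landscape(lattice, res$occ_final)),
    class = "event_tally"
  )
}

decode_event_log <- function(res, lattice) {
  n <- length(res$ev_type)
  offs <- cumsum(c(0L, res$ev_npart))
  coords <- site_coords(lattice, res$ev_site + 1L)
  data.frame(
    event_index = seq_len(n),
    side = ifelse(res$ev_type <= 3L, "removal", "addition"),
    type = EVENT_TYPES[res$ev_type],
    site_row = coords[, "row"], site_col = coords[, "col"],
    single = res$ev_single, single_capped = res$ev_single_cap != 0L,
    parts = vapply(seq_len(n), function(i) {
      if (res$ev_npart[i] == 0L) return("")
      idx <- (offs[i] + 1L):offs[i + 1L]
      paste(ifelse(res$ev_parts_cap[idx] != 0L,
                   paste0(">=", res$ev_parts[idx]), res$ev_parts[idx]),
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Rebuild event records from a recorded run
#'
#' Converts the event log of a [run_events()] call made with
#' `record_events = TRUE` into a list of `"event_record"` objects.
#'
#' @param tally an `"event_tally"` with a recorded event log.
#' @param side `"removal"`, `"addition"` or `"both"`.
#' @return List of `"event_record"`s in stream order.
#' @export
tally_events <- function(tally, side = c("both", "removal", "addition")) {
  side <- match.arg(side)
  stopifnot(inherits(tally, "event_tally"))
  ev <- tally$events
  if (is.null(ev)) stop("run_events() was not called with record_events = TRUE")
  keep <- if (side == "both") seq_len(nrow(ev)) else which(ev$side == side)
  lapply(keep, function(i) {
    parts_raw <- ev$parts[i]
    if (nzchar(parts_raw)) {
      toks <- strsplit(parts_raw, ";", fixed = TRUE)[[1]]
      capped <- startsWith(toks, ">=")
      sizes <- as.integer(sub("^>=", "", toks))
    } else {
      capped <- logical(0)
      sizes <- integer(0)
    }
    single <- ev$single[i]
    single_capped <- ev$single_capped[i]
    site <- site_index(make_lattice(tally$geometry, tally$side),
                       ev$site_row[i], ev$site_col[i])
    if (ev$side[i] == "removal")
      new_event_record(ev$type[i], site, c(ev$site_row[i], ev$site_col[i]),
                       sizes_before = single, sizes_after = sizes,
                       capped_before = single_capped, capped_after = capped)
    else
      new_event_record(ev$type[i], site, c(ev$site_row[i], ev$site_col[i]),
                       sizes_before = sizes, sizes_after = single,
                       capped_before = capped, capped_after = single_capped)
  })
}

#' @export
print.event_tally <- function(x, ...) {
  cat(sprintf("event tally: %s L=%d, q = %.3f, %s events\n",
              x$geometry, x$side, x$q, format(x$n_events, big.mark = ",")))
  cat("removal-conditioned probabilities:\n")
  print(round(x$probs, 4))
  invisible(x)
}
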