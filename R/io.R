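# Output writers. Every file starts with a '#'-prefixed metadata header
# (package version, serialized config, config hash, seed) sufficient to
# re-run it exactly; read the CSVs back with read.csv(comment.char = "#").

fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(txt))
  h <- 2166136261
  mul32 <- function(a, b) {
    lo <- a %% 65536
    hi <- (a - lo) / 65536
    (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
  }
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    h <- mul32(h, 16777619)
  }
  # h can exceed .Machine$integer.max, so format the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

meta_header <- function(config, seed) {
  cfg <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  c(sprintf("# patchdyn %s", as.character(utils::packageVersion("patchdyn"))),
    sprintf("# config: %s", cfg),
    sprintf("# config_hash: %s", fnv1a32(as.character(cfg))),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else as.character(seed)))
}

write_csv_with_header <- function(df, path, config, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(config, seed), con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation outputs
#'
#' `write_curve_csv()` writes the per-q event probabilities,
#' `write_amplification_csv()` the per-(q, m) amplification factors,
#' `write_tally_csv()` one row of event counts for a single run,
#' `write_event_stream_csv()` the optional full event log, and
#' `write_transitions_json()` the transition set. All files carry a
#' metadata header with the package version, the serialized configuration,
#' a hash of it, and the seed.
#'
#' @param curve an `"event_curve"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "event_curve"))
  df <- cbind(geometry = curve$geometry, curve$curve)
  cfg <- list(geometry = curve$geometry, side = curve$side,
              n_events = curve$n_events, q_grid = curve$curve$q,
              point_seeds = curve$seeds$seed)
  write_csv_with_header(df, path, cfg, curve$seed)
}

#' @rdname write_curve_csv
#' @export
write_amplification_csv <- function(curve, path) {
  stopifnot(inherits(curve, "event_curve"))
  df <- cbind(geometry = curve$geometry, curve$amplification)
  cfg <- list(geometry = curve$geometry, side = curve$side,
              n_events = curve$n_events, m_list = curve$m_list,
              q_grid = curve$curve$q, point_seeds = curve$seeds$seed)
  write_csv_with_header(df, path, cfg, curve$seed)
}

#' @rdname write_curve_csv
#' @param tally an `"event_tally"` from [run_events()].
#' @param seed the seed the run was started with (recorded in the header).
#' @export
write_tally_csv <- function(tally, path, seed = NULL) {
  stopifnot(inherits(tally, "event_tally"))
  df <- data.frame(geometry = tally$geometry, q = tally$q,
                   n_events = tally$n_events, t(tally$counts))
  cfg <- list(geometry = tally$geometry, side = tally$side, q = tally$q,
              n_events = tally$n_events, m_list = tally$m_list)
  write_csv_with_header(df, path, cfg, seed)
}

#' @rdname write_curve_csv
#' @export
write_event_stream_csv <- function(tally, path, seed = NULL) {
  stopifnot(inherits(tally, "event_tally"))
  if (is.null(tally$events))
    stop("run_events() was not called with record_events = TRUE")
  ev <- tally$events
  removal <- ev$side == "removal"
  df <- data.frame(
    event_index = ev$event_index, type = ev$type,
    site_row = ev$site_row, site_col = ev$site_col,
    sizes_before = ifelse(removal, as.character(ev$single), ev$parts),
    sizes_after = ifelse(removal, ev$parts, as.character(ev$single)))
  cfg <- list(geometry = tally$geometry, side = tally$side, q = tally$q,
              n_events = tally$n_events)
  write_csv_with_header(df, path, cfg, seed)
}

#' @rdname write_curve_csv
#' @param transitions a `"transition_set"`.
#' @param threshold_method short description of how q2 was obtained.
#' @export
write_transitions_json <- function(transitions, path,
                                   threshold_method = "reference",
                                   seed = NULL) {
  stopifnot(inherits(transitions, "transition_set"))
  obj <- list(
    package = "patchdyn",
    version = as.character(utils::packageVersion("patchdyn")),
    seed = if (is.null(seed)) NA else seed,
    geometry = transitions$geometry,
    q1 = transitions$q1, q2 = transitions$q2,
    q3 = transitions$q3, q4 = transitions$q4,
    phase_intervals = transitions$phases,
    threshold_method = threshold_method)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
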