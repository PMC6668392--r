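#' Write the worked example grids and phase snapshots
#'
#' Writes plain-text rasters for the three canonical single-site events on
#' a 7 x 7 torus — an isolated site (loss/formation), a perimeter site of a
#' compact patch (shrinkage/enlargement) and a bottleneck site between two
#' patches (splitting/coalescence) — for both lattice geometries, plus five
#' 20 x 20 random snapshots at the habitat-loss levels characteristic of
#' the five degradation phases (q = 0.10, 0.325, 0.50, 0.70, 0.925,
#' mid-interval values of the approximate phase ranges). A `manifest.json`
#' records, for every event grid, the focal site and the expected event
#' types when the focal site is removed and (after removing it) re-added.
#'
#' @param dir output directory (created if missing).
#' @param seed seed for the snapshot landscapes.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  manifest <- list()

  grids <- event_fixture_grids()
  for (kind in c("hex6", "square4")) {
    for (nm in names(grids)) {
      ls <- landscape_from_matrix(grids[[nm]]$grid, kind)
      file <- file.path(dir, sprintf("%s_%s.txt", sub("[46]$", "", kind), nm))
      write_raster(ls, file)
      written <- c(written, file)
      manifest[[length(manifest) + 1L]] <- list(
        file = basename(file), kind = kind,
        focal_row = grids[[nm]]$focal[1], focal_col = grids[[nm]]$focal[2],
        expected_removal = grids[[nm]]$removal,
        expected_addition = grids[[nm]]$addition)
    }
  }

  q_levels <- c(0.10, 0.325, 0.50, 0.70, 0.925)
  lat <- make_lattice("hex6", 20)
  set.seed(seed)
  for (q in q_levels) {
    ls <- random_landscape(lat, 1 - q)
    file <- file.path(dir, sprintf("snapshot_q%.3f.txt", q))
    write_raster(ls, file)
    written <- c(written, file)
    manifest[[length(manifest) + 1L]] <- list(
      file = basename(file), kind = "hex6", q = q, phase = match(q, q_levels),
      seed = seed)
  }

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, file.path(dir, "manifest.json"))
  invisible(written)
}

# The three worked configurations on a 7 x 7 grid. The same shapes realize
# the same event types under both adjacencies (verified by tests).
event_fixture_grids <- function() {
  g <- function(sites) {
    m <- matrix(0L, 7, 7)
    for (s in sites) m[s[1], s[2]] <- 1L
    m
  }
  list(
    loss = list(
      grid = g(list(c(4, 4), c(1, 1), c(1, 2))),
      focal = c(4L, 4L), removal = "loss", addition = "formation"),
    shrinkage = list(
      grid = g(list(c(3, 3), c(3, 4), c(4, 3), c(4, 4), c(5, 3))),
      focal = c(3L, 4L), removal = "shrinkage", addition = "enlargement"),
    splitting = list(
      grid = g(list(c(4, 2), c(4, 3), c(4, 4), c(4, 5), c(4, 6))),
      focal = c(4L, 4L), removal = "splitting", addition = "coalescence")
  )
}
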