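#' Generate a random landscape at habitat fraction p
#'
#' Exactly `round(p * N)` habitat sites are drawn uniformly without
#' replacement; this is the uniform measure over fixed-density
#' configurations, which is also the stationary distribution of the swap
#' dynamics (see [run_events()]).
#'
#' @param lattice a [make_lattice()] object.
#' @param p habitat fraction in `[0, 1]`.
#' @param seed optional integer seed (calls `set.seed()`); when `NULL` the
#'   current RNG state is used.
#' @return An object of class `"landscape"`: a list with `lattice`,
#'   `occupancy` (integer 0/1 vector of length N, row-major) and
#'   `n_habitat`.
#' @export
random_landscape <- function(lattice, p, seed = NULL) {
  stopifnot(inherits(lattice, "lattice"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  N <- lattice$n_sites
  n_hab <- as.integer(round(p * N))
  occ <- integer(N)
  if (n_hab > 0L) occ[sample.int(N, n_hab)] <- 1L
  new_landscape(lattice, occ)
}

new_landscape <- function(lattice, occupancy) {
  structure(
    list(lattice = lattice, occupancy = as.integer(occupancy),
         n_habitat = sum(occupancy != 0L)),
    class = "landscape"
  )
}

#' Build a landscape from a 0/1 matrix
#'
#' Row `i`, column `j` of the matrix maps to site `(i, j)`.
#'
#' @param m an `L` x `L` matrix coercible to 0/1.
#' @param kind lattice kind, `"hex6"` or `"square4"`.
#' @return A `"landscape"` object.
#' @export
landscape_from_matrix <- function(m, kind = c("hex6", "square4")) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  lattice <- make_lattice(kind, nrow(m))
  new_landscape(lattice, as.integer(t(m) != 0))
}

#' @export
as.matrix.landscape <- function(x, ...) {
  matrix(x$occupancy, nrow = x$lattice$side, byrow = TRUE)
}

#' @export
print.landscape <- function(x, ...) {
  L <- x$lattice$side
  cat(sprintf("landscape on %s %dx%d torus: %d/%d habitat sites (p = %.4f)\n",
              x$lattice$kind, L, L, x$n_habitat, x$lattice$n_sites,
              x$n_habitat / x$lattice$n_sites))
  invisible(x)
}

#' Label habitat patches (connected components)
#'
#' Flood-fill labeling of the habitat sites under the lattice adjacency.
#' Labels are assigned in order of first row-major appearance, so they are
#' stable for a fixed occupancy.
#'
#' @param landscape a `"landscape"` object.
#' @return A list with `labels` (integer vector of length N; 0 for
#'   non-habitat sites, patch id otherwise) and `sizes` (integer vector of
#'   patch sizes indexed by patch id).
#' @export
label_patches <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  res <- label_cpp(landscape$occupancy, kind_code(landscape$lattice),
                   landscape$lattice$side)
  list(labels = res$labels, sizes = res$sizes)
}

#' Does a patch wrap around the torus?
#'
#' Detects, per axis, whether any habitat patch wraps around the periodic
#' boundary. A wrapping cluster is the finite-size proxy for the spanning
#' (infinite) cluster of percolation theory. Detection uses union-find with
#' relative displacement vectors: an edge closing a cycle whose accumulated
#' displacement is a non-zero multiple of L in an axis reveals a wrap.
#'
#' @param landscape a `"landscape"` object.
#' @return Named logical vector `c(row = , col = )`.
#' @export
wrapping_cluster_exists <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  w <- wrap_cpp(landscape$occupancy, kind_code(landscape$lattice),
                landscape$lattice$side)
  c(row = w[1], col = w[2])
}

#' Read and write plain-text rasters
#'
#' The raster format is `L` lines of `L` characters, `'1'` for habitat and
#' `'0'` for non-habitat; it round-trips exactly.
#'
#' @param path file path.
#' @param kind lattice kind to attach to the landscape.
#' @return `read_raster()` returns a `"landscape"`; `write_raster()` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path, kind = c("hex6", "square4")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  L <- length(lines)
  if (L < 3L) stop("raster must have at least 3 rows")
  if (any(nchar(lines) != L)) stop("raster must be square (L lines of L characters)")
  chars <- unlist(strsplit(lines, ""))
  if (!all(chars %in% c("0", "1"))) stop("raster may contain only '0' and '1'")
  lattice <- make_lattice(kind, L)
  new_landscape(lattice, as.integer(chars == "1"))
}

#' @rdname read_raster
#' @param landscape a `"landscape"` object.
#' @export
write_raster <- function(landscape, path) {
  stopifnot(inherits(landscape, "landscape"))
  L <- landscape$lattice$side
  rows <- vapply(seq_len(L), function(i) {
    paste(landscape$occupancy[((i - 1L) * L + 1L):(i * L)], collapse = "")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Export a landscape snapshot image
#'
#' Habitat sites are drawn grey, non-habitat sites white (the usual
#' rendering convention for percolation maps). `snapshot_pgm()` writes a
#' plain-text PGM (P2); `snapshot_png()` needs the optional \pkg{png}
#' package.
#'
#' @param landscape a `"landscape"` object.
#' @param path output path.
#' @param scale integer pixel size per site.
#' @return `path`, invisibly.
#' @export
snapshot_pgm <- function(landscape, path, scale = 1L) {
  m <- as.matrix.landscape(landscape)
  m <- m[rep(seq_len(nrow(m)), each = scale), rep(seq_len(ncol(m)), each = scale)]
  vals <- ifelse(m != 0, 140L, 255L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname snapshot_pgm
#' @export
snapshot_png <- function(landscape, path, scale = 4L) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("snapshot_png() needs the 'png' package; use snapshot_pgm() instead")
  m <- as.matrix.landscape(landscape)
  m <- m[rep(seq_len(nrow(m)), each = scale), rep(seq_len(ncol(m)), each = scale)]
  img <- ifelse(m != 0, 140 / 255, 1)
  png::writePNG(img, path)
  invisible(path)
}
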