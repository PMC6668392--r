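#' Create a lattice geometry descriptor
#'
#' Defines the lattice on which landscapes live: an `L` x `L` torus with
#' either the six-neighbour triangular adjacency (`"hex6"`, the adjacency of
#' a hexagonal-cell landscape, coordination number 6, site-percolation
#' threshold exactly 1/2) or the square lattice with von Neumann
#' neighbourhood (`"square4"`, coordination number 4, threshold 0.592746).
#'
#' The six-neighbour adjacency is implemented in axial coordinates on a
#' rhombic torus: the neighbours of `(i, j)` are `(i±1, j)`, `(i, j±1)`,
#' `(i+1, j-1)` and `(i-1, j+1)`, all modulo `L`.
#'
#' @param kind `"hex6"` or `"square4"`.
#' @param side lattice side length `L` (at least 3; neighbour sets
#'   degenerate below that).
#' @return An object of class `"lattice"`: a list with `kind`, `side`,
#'   `n_sites`, `coordination` (z), `p_c` and `q_c`.
#' @examples
#' lat <- make_lattice("hex6", 10)
#' neighbors(lat, 1)
#' @export
make_lattice <- function(kind = c("hex6", "square4"), side) {
  kind <- match.arg(kind)
  side <- as.integer(side)
  if (length(side) != 1L || is.na(side) || side < 3L)
    stop("side must be a single integer >= 3")
  z <- if (kind == "hex6") 6L else 4L
  p_c <- if (kind == "hex6") 0.5 else 0.592746
  structure(
    list(kind = kind, side = side, n_sites = side * side,
         coordination = z, p_c = p_c, q_c = 1 - p_c),
    class = "lattice"
  )
}

kind_code <- function(lattice) if (lattice$kind == "hex6") 1L else 0L

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("%s lattice: %d x %d torus (N = %d sites, z = %d, p_c = %g)\n",
              x$kind, x$side, x$side, x$n_sites, x$coordination, x$p_c))
  invisible(x)
}

#' Neighbours of a site
#'
#' Returns the `z` distinct, torus-wrapped neighbours of a site under the
#' lattice's adjacency rule. Sites are 1-based row-major indices:
#' `site = (row - 1) * L + col`.
#'
#' @param lattice a [make_lattice()] object.
#' @param site a single site index in `1..N`.
#' @return Integer vector of `z` site indices.
#' @export
neighbors <- function(lattice, site) {
  stopifnot(inherits(lattice, "lattice"))
  site <- as.integer(site)
  if (length(site) != 1L || is.na(site) || site < 1L || site > lattice$n_sites)
    stop("invalid site index")
  neighbors_cpp(kind_code(lattice), lattice$side, site - 1L) + 1L
}

#' Convert between site indices and (row, col) coordinates
#'
#' @param lattice a [make_lattice()] object.
#' @param row,col 1-based coordinates.
#' @return `site_index()` returns 1-based row-major site indices;
#'   `site_coords()` returns a two-column matrix of (row, col).
#' @export
site_index <- function(lattice, row, col) {
  L <- lattice$side
  if (any(row < 1L | row > L | col < 1L | col > L))
    stop("coordinates out of range")
  (as.integer(row) - 1L) * L + as.integer(col)
}

#' @rdname site_index
#' @param site site index vector.
#' @export
site_coords <- function(lattice, site) {
  L <- lattice$side
  site <- as.integer(site)
  if (any(site < 1L | site > lattice$n_sites)) stop("invalid site index")
  cbind(row = (site - 1L) %/% L + 1L, col = (site - 1L) %% L + 1L)
}
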