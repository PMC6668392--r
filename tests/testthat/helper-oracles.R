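# Brute-force oracles, independent of the fast local classifier: they relabel
# the whole landscape before and after a trial change and compare components.

relabel <- function(occ, kind) {
  L <- as.integer(sqrt(length(occ)))
  label_patches(landscape_from_matrix(matrix(occ, L, byrow = TRUE), kind))
}

oracle_classify_removal <- function(ls, site) {
  lab <- label_patches(ls)
  id <- lab$labels[site]
  s <- lab$sizes[id]
  occ2 <- ls$occupancy
  occ2[site] <- 0L
  lab2 <- relabel(occ2, ls$lattice$kind)
  members <- setdiff(which(lab$labels == id), site)
  frags <- sort(as.integer(table(lab2$labels[members])), decreasing = TRUE)
  type <- if (length(frags) == 0) "loss"
          else if (length(frags) == 1) "shrinkage" else "splitting"
  list(type = type, sizes_before = as.integer(s), sizes_after = frags)
}

oracle_classify_addition <- function(ls, site) {
  lab <- label_patches(ls)
  nb <- neighbors(ls$lattice, site)
  ids <- unique(lab$labels[nb][lab$labels[nb] > 0L])
  parts <- sort(as.integer(lab$sizes[ids]), decreasing = TRUE)
  type <- if (length(ids) == 0) "formation"
          else if (length(ids) == 1) "enlargement" else "coalescence"
  list(type = type, sizes_before = parts,
       sizes_after = as.integer(sum(parts) + 1L))
}

# generic graph-library connected components on the same adjacency
igraph_components <- function(ls) {
  hab <- which(ls$occupancy == 1L)
  idx <- match(seq_len(ls$lattice$n_sites), hab)
  edges <- integer(0)
  for (s in hab) {
    for (t in neighbors(ls$lattice, s)) {
      if (t > s && ls$occupancy[t] == 1L) edges <- c(edges, idx[s], idx[t])
    }
  }
  g <- igraph::make_empty_graph(n = length(hab), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  membership <- integer(ls$lattice$n_sites)
  membership[hab] <- comp$membership
  list(membership = membership, sizes = as.integer(comp$csize))
}

# direct-definition effective loss: s [s >= m] - sum_i s_i [s_i >= m]
direct_effective_loss <- function(s, frags, m) {
  viable <- function(x) sum(x[x >= m])
  viable(s) - viable(frags)
}

make_split3_landscape <- function(kind) {
  # three-armed configuration whose hub removal splits a patch into 3
  # fragments; the arm directions are chosen pairwise non-adjacent under
  # the given lattice rule
  m <- matrix(0L, 9, 9)
  m[5, 5] <- 1L # hub at (5, 5)
  arms <- if (kind == "hex6") {
    list(c(1L, 0L), c(0L, -1L), c(-1L, 1L))
  } else {
    list(c(1L, 0L), c(-1L, 0L), c(0L, -1L))
  }
  for (d in arms) {
    m[5 + d[1], 5 + d[2]] <- 1L
    m[5 + 2L * d[1], 5 + 2L * d[2]] <- 1L
  }
  landscape_from_matrix(m, kind)
}
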