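test_that("neighbourhoods are z-regular, symmetric and torus-wrapped", {
  for (kind in c("hex6", "square4")) {
    for (L in c(3, 6, 10)) {
      lat <- make_lattice(kind, L)
      z <- lat$coordination
      for (s in seq_len(lat$n_sites)) {
        nb <- neighbors(lat, s)
        expect_length(nb, z)
        expect_length(unique(nb), z)
        expect_false(s %in% nb)
        for (t in nb) expect_true(s %in% neighbors(lat, t))
      }
    }
  }
})

test_that("square4 von Neumann neighbours and corner wrap are correct", {
  lat <- make_lattice("square4", 5)
  centre <- site_index(lat, 3, 3)
  expect_setequal(neighbors(lat, centre),
                  site_index(lat, c(2, 4, 3, 3), c(3, 3, 2, 4)))
  corner <- site_index(lat, 1, 1)
  expect_setequal(neighbors(lat, corner),
                  site_index(lat, c(5, 1, 2, 1), c(1, 5, 1, 2)))
})

test_that("lattice constructor validates inputs and stores thresholds", {
  expect_error(make_lattice("hex6", 2), "side")
  expect_error(neighbors(make_lattice("hex6", 5), 0), "site")
  expect_error(neighbors(make_lattice("hex6", 5), 26), "site")
  expect_equal(make_lattice("hex6", 10)$p_c, 0.5)
  expect_equal(make_lattice("square4", 10)$p_c, 0.592746)
})

test_that("random landscapes have exactly round(p*N) habitat sites", {
  lat <- make_lattice("hex6", 100)
  expect_equal(random_landscape(lat, 0.5, seed = 1)$n_habitat, 5000)
  expect_equal(random_landscape(lat, 0, seed = 1)$n_habitat, 0)
  full <- random_landscape(lat, 1, seed = 1)
  expect_equal(full$n_habitat, 10000)
  expect_equal(label_patches(full)$sizes, 10000L)
  expect_error(random_landscape(lat, 1.2), "p must")
  a <- random_landscape(lat, 0.4, seed = 99)
  b <- random_landscape(lat, 0.4, seed = 99)
  expect_identical(a$occupancy, b$occupancy)
})

test_that("patch labeling agrees with an independent graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(31)
  n_checked <- 0
  for (kind in c("hex6", "square4")) {
    lat <- make_lattice(kind, 15)
    for (p in c(0.2, 0.5, 0.8)) {
      for (rep in 1:18) {
        ls <- random_landscape(lat, p)
        lab <- label_patches(ls)
        ig <- igraph_components(ls)
        # same partition: labels must be a relabeling of memberships
        expect_true(all((lab$labels > 0) == (ig$membership > 0)))
        key <- paste(lab$labels, ig$membership)
        hab <- ls$occupancy == 1L
        expect_equal(length(unique(key[hab])),
                     length(unique(lab$labels[hab])))
        expect_equal(sort(lab$sizes), sort(ig$sizes))
        expect_equal(sum(lab$sizes), ls$n_habitat)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 100)
})

test_that("wrapping detection finds spanning patches per axis", {
  lat <- make_lattice("square4", 8)
  expect_equal(wrapping_cluster_exists(random_landscape(lat, 1)),
               c(row = TRUE, col = TRUE))
  # single full row wraps around the column axis only
  m <- matrix(0L, 8, 8)
  m[4, ] <- 1L
  expect_equal(wrapping_cluster_exists(landscape_from_matrix(m, "square4")),
               c(row = FALSE, col = TRUE))
  mc <- matrix(0L, 8, 8)
  mc[, 4] <- 1L
  expect_equal(wrapping_cluster_exists(landscape_from_matrix(mc, "square4")),
               c(row = TRUE, col = FALSE))
  # well above the square threshold most replicates wrap
  lat30 <- make_lattice("square4", 30)
  set.seed(5)
  wraps <- sum(vapply(1:100, function(i)
    any(wrapping_cluster_exists(random_landscape(lat30, 0.65))), logical(1)))
  expect_gt(wraps, 50)
})

test_that("largest-patch fraction and patch count respond monotonically to p", {
  set.seed(77)
  lat <- make_lattice("hex6", 40)
  stats_at <- function(p) {
    res <- vapply(1:20, function(i) {
      sz <- label_patches(random_landscape(lat, p))$sizes
      c(count = length(sz), lmax = max(sz) / (p * lat$n_sites))
    }, numeric(2))
    rowMeans(res)
  }
  s <- vapply(c(0.40, 0.50, 0.60), stats_at, numeric(2))
  expect_true(all(diff(s["lmax", ]) > 0))
  expect_true(all(diff(s["count", ]) < 0))
})
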