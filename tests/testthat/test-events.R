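test_that("the three worked configurations classify as loss/shrinkage/splitting", {
  grids <- patchdyn:::event_fixture_grids()
  for (kind in c("hex6", "square4")) {
    for (nm in names(grids)) {
      ls <- landscape_from_matrix(grids[[nm]]$grid, kind)
      focal <- site_index(ls$lattice, grids[[nm]]$focal[1], grids[[nm]]$focal[2])
      ev <- classify_removal(ls, focal)
      expect_equal(ev$event_type, grids[[nm]]$removal)
      # read right-to-left: adding the focal site back is the dual event
      occ2 <- ls$occupancy
      occ2[focal] <- 0L
      ls2 <- landscape_from_matrix(matrix(occ2, 7, byrow = TRUE), kind)
      ev2 <- classify_addition(ls2, focal)
      expect_equal(ev2$event_type, grids[[nm]]$addition)
      expect_equal(ev2$sizes_before, ev$sizes_after)
      expect_equal(ev2$sizes_after, ev$sizes_before)
    }
  }
})

test_that("worked splitting example: bottleneck loss makes two fragments", {
  g <- patchdyn:::event_fixture_grids()$splitting
  ls <- landscape_from_matrix(g$grid, "hex6")
  ev <- classify_removal(ls, c(4, 4))
  expect_equal(ev$event_type, "splitting")
  expect_equal(ev$sizes_before, 5L)
  expect_equal(ev$sizes_after, c(2L, 2L))
})

test_that("splitting into three fragments is representable", {
  for (kind in c("hex6", "square4")) {
    ls <- make_split3_landscape(kind)
    ev <- classify_removal(ls, c(5, 5))
    expect_equal(ev$event_type, "splitting")
    expect_equal(ev$sizes_before, 7L)
    expect_equal(ev$sizes_after, c(2L, 2L, 2L))
  }
})

test_that("classification preconditions are enforced and nothing is mutated", {
  lat <- make_lattice("hex6", 7)
  ls <- random_landscape(lat, 0.5, seed = 3)
  hab <- which(ls$occupancy == 1L)[1]
  non <- which(ls$occupancy == 0L)[1]
  expect_error(classify_removal(ls, non), "not a habitat site")
  expect_error(classify_addition(ls, hab), "not a non-habitat site")
  before <- ls$occupancy
  classify_removal(ls, hab)
  classify_addition(ls, non)
  expect_identical(ls$occupancy, before)
})

test_that("addition with all neighbours in one patch is enlargement s -> s+1", {
  m <- matrix(0L, 7, 7)
  m[3, 3:5] <- 1L
  m[4, 3] <- m[4, 5] <- 1L # ring around the empty site (4, 4)
  m[5, 3:5] <- 1L
  ls <- landscape_from_matrix(m, "square4")
  ev <- classify_addition(ls, c(4, 4))
  expect_equal(ev$event_type, "enlargement")
  expect_equal(ev$sizes_before, 8L)
  expect_equal(ev$sizes_after, 9L)
})

test_that("fast classifier agrees with the full-relabel oracle on random cases", {
  set.seed(123)
  for (kind in c("hex6", "square4")) {
    lat <- make_lattice(kind, 12)
    trials <- 0
    for (rep in 1:40) {
      ls <- random_landscape(lat, runif(1, 0.1, 0.9))
      hab <- which(ls$occupancy == 1L)
      non <- which(ls$occupancy == 0L)
      for (site in sample(hab, min(10, length(hab)))) {
        ev <- classify_removal(ls, site)
        or <- oracle_classify_removal(ls, site)
        expect_identical(ev$event_type, or$type)
        expect_identical(ev$sizes_before, or$sizes_before)
        expect_identical(ev$sizes_after, or$sizes_after)
        trials <- trials + 1
      }
      for (site in sample(non, min(10, length(non)))) {
        ev <- classify_addition(ls, site)
        or <- oracle_classify_addition(ls, site)
        expect_identical(ev$event_type, or$type)
        expect_identical(ev$sizes_before, or$sizes_before)
        expect_identical(ev$sizes_after, or$sizes_after)
        trials <- trials + 1
      }
    }
    expect_gte(trials, 700)
  }
})

test_that("fragment sizes satisfy the conservation identities", {
  set.seed(9)
  lat <- make_lattice("hex6", 15)
  for (rep in 1:30) {
    ls <- random_landscape(lat, runif(1, 0.3, 0.7))
    site <- sample(which(ls$occupancy == 1L), 1)
    ev <- classify_removal(ls, site)
    expect_equal(sum(ev$sizes_after), ev$sizes_before - 1L)
    if (ev$event_type == "splitting") expect_gte(length(ev$sizes_after), 2)
    site2 <- sample(which(ls$occupancy == 0L), 1)
    ev2 <- classify_addition(ls, site2)
    expect_equal(ev2$sizes_after, sum(ev2$sizes_before) + 1L)
  }
})

test_that("apply_swap conserves habitat and classifies both sides", {
  set.seed(21)
  lat <- make_lattice("square4", 10)
  ls <- random_landscape(lat, 0.5)
  for (i in 1:25) {
    res <- apply_swap(ls)
    expect_equal(res$landscape$n_habitat, ls$n_habitat)
    expect_true(res$removal$event_type %in% c("loss", "shrinkage", "splitting"))
    expect_true(res$addition$event_type %in%
                  c("formation", "enlargement", "coalescence"))
    ls <- res$landscape
    expect_equal(sum(ls$occupancy), ls$n_habitat)
  }
  empty <- landscape_from_matrix(matrix(0L, 5, 5), "square4")
  expect_error(apply_swap(empty), "0 < n_habitat")
})

test_that("run_events is deterministic given a seed and conserves counts", {
  lat <- make_lattice("hex6", 30)
  a <- run_events(lat, q = 0.5, n_events = 2000, seed = 17, record_events = TRUE)
  b <- run_events(lat, q = 0.5, n_events = 2000, seed = 17, record_events = TRUE)
  expect_identical(a$counts, b$counts)
  expect_identical(a$events, b$events)
  expect_identical(a$landscape_final$occupancy, b$landscape_final$occupancy)
  expect_equal(sum(a$counts[c("loss", "shrinkage", "splitting")]), a$n_removals)
  expect_equal(sum(a$counts[c("formation", "enlargement", "coalescence")]),
               a$n_additions)
  expect_equal(a$n_removals, a$n_additions)
  expect_equal(a$landscape_final$n_habitat, round(0.5 * lat$n_sites))
  expect_error(run_events(lat, 0.5, 101), "even")
  expect_error(run_events(lat, 0.5, 0), "even|positive")
})

test_that("streamed (capped) event sizes match exact classification", {
  lat <- make_lattice("hex6", 20)
  set.seed(4)
  start <- random_landscape(lat, 0.5)
  tl <- run_events(lat, q = 0.5, n_events = 400, seed = 4,
                   record_events = TRUE, landscape = start)
  cap <- tl$size_cap
  # replay the stream: reclassify each removal exactly on the evolving state
  ls <- start
  ev <- tl$events
  for (i in seq_len(nrow(ev))) {
    site <- site_index(lat, ev$site_row[i], ev$site_col[i])
    if (ev$side[i] == "removal") {
      exact <- classify_removal(ls, site)
      expect_identical(exact$event_type, ev$type[i])
      if (!ev$single_capped[i]) {
        expect_equal(exact$sizes_before, ev$single[i])
      } else {
        expect_gte(exact$sizes_before, cap)
      }
      ls$occupancy[site] <- 0L
    } else {
      exact <- classify_addition(ls, site)
      expect_identical(exact$event_type, ev$type[i])
      ls$occupancy[site] <- 1L
    }
    ls$n_habitat <- sum(ls$occupancy)
  }
})

test_that("swap dynamics is stationary: patch counts do not drift", {
  set.seed(55)
  lat <- make_lattice("hex6", 30)
  n_rep <- 30
  d <- vapply(seq_len(n_rep), function(i) {
    ls <- random_landscape(lat, 0.5)
    n0 <- length(label_patches(ls)$sizes)
    tl <- run_events(lat, q = 0.5, n_events = 2 * lat$n_sites, landscape = ls)
    n1 <- length(label_patches(tl$landscape_final)$sizes)
    n1 - n0
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(n_rep) + 1e-9)
})

test_that("removal-loss frequency matches the local-configuration prediction", {
  lat <- make_lattice("hex6", 100)
  tl <- run_events(lat, q = 0.6, n_events = 4e4, seed = 8)
  p0 <- analytic_loss_probability(0.4, "hex6", conditioned = TRUE)
  se <- sqrt(p0 * (1 - p0) / tl$n_removals)
  expect_lt(abs(tl$probs[["loss"]] - p0), 3 * se)
})
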