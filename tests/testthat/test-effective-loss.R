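mk_removal <- function(type, s, frags) {
  patchdyn:::new_event_record(type, 1L, c(1L, 1L), sizes_before = s,
                              sizes_after = frags)
}

test_that("effective loss matches the living-area definition", {
  # splitting a size-3 patch into two singletons removes 3 sites at m = 2
  split3 <- mk_removal("splitting", 3L, c(1L, 1L))
  expect_equal(effective_loss_of_event(split3, m = 2), 3L)
  # m = 1: every removal costs exactly one site
  for (ev in list(mk_removal("loss", 1L, integer(0)),
                  mk_removal("shrinkage", 5L, 4L),
                  mk_removal("splitting", 4L, c(2L, 1L)))) {
    expect_equal(effective_loss_of_event(ev, m = 1), 1L)
  }
  # removals from patches already below m cost nothing
  expect_equal(effective_loss_of_event(mk_removal("shrinkage", 4L, 3L), 5), 0L)
  expect_equal(effective_loss_of_event(mk_removal("loss", 1L, integer(0)), 2),
               0L)
})

test_that("effective loss equals the direct definition on random events", {
  set.seed(61)
  lat <- make_lattice("hex6", 14)
  for (rep in 1:60) {
    ls <- random_landscape(lat, runif(1, 0.2, 0.8))
    site <- sample(which(ls$occupancy == 1L), 1)
    ev <- classify_removal(ls, site)
    for (m in c(1, 2, 3, 5, 9)) {
      expect_equal(effective_loss_of_event(ev, m),
                   direct_effective_loss(ev$sizes_before, ev$sizes_after, m))
      expect_gte(effective_loss_of_event(ev, m), 0)
    }
  }
})

test_that("addition-side events are rejected", {
  add <- patchdyn:::new_event_record("formation", 1L, c(1L, 1L),
                                     sizes_before = integer(0),
                                     sizes_after = 1L)
  expect_error(effective_loss_of_event(add, 1), "addition-side")
  expect_error(amplification_factor(list(), 1), "empty")
})

test_that("hand-built stream averages to the enumerated mean", {
  events <- list(mk_removal("loss", 1L, integer(0)),
                 mk_removal("shrinkage", 5L, 4L),
                 mk_removal("splitting", 4L, c(2L, 1L)))
  # m = 2: effective losses are {0, 1, 2}
  af <- amplification_factor(events, m = 2)
  expect_equal(af$amplification, 1.0)
  expect_equal(af$n_removals, 3L)
  af19 <- amplification_factor(events, m = c(1, 9))
  expect_equal(af19$amplification[af19$m == 1], 1.0)
  expect_equal(af19$amplification[af19$m == 9], 0.0)
})

test_that("engine amplification equals the R-route mean over recorded events", {
  lat <- make_lattice("hex6", 25)
  tl <- run_events(lat, q = 0.55, n_events = 3000, seed = 27,
                   record_events = TRUE, m_list = 1:6)
  removals <- tally_events(tl, side = "removal")
  af <- amplification_factor(removals, m = 1:6)
  expect_equal(af$amplification, tl$amplification$amplification,
               tolerance = 1e-12)
  expect_equal(af$n_removals[1], tl$n_removals)
})

test_that("amplification is exactly 1 for m = 1 and bounded sensibly", {
  lat <- make_lattice("hex6", 40)
  for (q in c(0.3, 0.7)) {
    tl <- run_events(lat, q = q, n_events = 1e4, seed = round(100 * q))
    amp <- tl$amplification
    expect_identical(amp$amplification[amp$m == 1], 1)
    expect_true(all(amp$amplification >= 0))
  }
})
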