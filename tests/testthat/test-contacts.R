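reg_track <- function(tt_min, x, y, id, interval = 5)
  trajectory(id, T0 + tt_min * 60, x, y, regular = TRUE,
             interval_min = interval)

test_that("temporal intersection follows interval arithmetic", {
  a <- make_track(c(0, 100), c(0, 0), c(0, 0), id = "a")
  b <- make_track(c(50, 150), c(0, 0), c(0, 0), id = "b")
  expect_equal(temporal_intersection(a, b),
               c(T0 + 50 * 60, T0 + 100 * 60))
  expect_equal(temporal_intersection(a, a), c(T0, T0 + 100 * 60))
  c_ <- make_track(c(200, 300), c(0, 0), c(0, 0), id = "c")
  expect_null(temporal_intersection(a, c_))
})

test_that("the 10 m buffer is inclusive and distances are Euclidean", {
  a <- reg_track(c(0, 5, 10), c(0, 0, 0), c(0, 0, 0), "a")
  b <- reg_track(c(0, 5, 10), c(9, 11, 10), c(0, 0, 0), "b")
  ev <- detect_contacts(a, b, 10)
  expect_equal(nrow(ev), 2)          # 9 m and exactly 10 m in, 11 m out
  expect_equal(ev$distance, c(9, 10))
  expect_equal(ev$x, c(4.5, 5))      # midpoint locations
})

test_that("identical trajectories contact at every shared timestamp", {
  set.seed(1)
  a <- reg_track(0:20 * 5, rnorm(21, 0, 100), rnorm(21, 0, 100), "a")
  b <- reg_track(0:20 * 5, a$x, a$y, "b")
  ev <- detect_contacts(a, b, 10)
  expect_equal(nrow(ev), 21)
  expect_true(all(ev$distance == 0))
})

test_that("detector equals the exhaustive oracle and is symmetric/monotone", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 200
    off <- sample(0:3, 1) * 5
    a <- reg_track(0:(n - 1) * 5, cumsum(rnorm(n, 0, 6)),
                   cumsum(rnorm(n, 0, 6)), "a")
    b <- reg_track(off + 0:(n - 1) * 5, cumsum(rnorm(n, 0, 6)),
                   cumsum(rnorm(n, 0, 6)), "b")
    ev <- detect_contacts(a, b, 10)
    or <- brute_contacts(a, b, 10)
    expect_equal(nrow(ev), nrow(or))
    expect_equal(as.numeric(ev$time), as.numeric(or$time))
    expect_equal(ev$distance, or$distance)
    # symmetry after canonical ordering
    ev2 <- detect_contacts(b, a, 10)
    expect_identical(ev, ev2)
    # enlarging the buffer never loses contacts
    ev_wide <- detect_contacts(a, b, 25)
    expect_gte(nrow(ev_wide), nrow(ev))
    expect_true(all(as.numeric(ev$time) %in% as.numeric(ev_wide$time)))
  }
})

test_that("grid preconditions are enforced", {
  a <- reg_track(c(0, 5), c(0, 0), c(0, 0), "a", interval = 5)
  b <- reg_track(c(0, 10), c(0, 0), c(0, 0), "b", interval = 10)
  expect_error(detect_contacts(a, b), class = "invalid_argument")
  irr <- make_track(c(0, 7), c(0, 0), c(0, 0), id = "c")
  expect_error(detect_contacts(a, irr), class = "invalid_argument")
})

test_that("FM and MM dyads bypass to between-group without KDE", {
  a <- reg_track(0:600 * 5, rnorm(601, 0, 50), rnorm(601, 0, 50), "a")
  b <- reg_track(0:600 * 5, rnorm(601, 500, 50), rnorm(601, 0, 50), "b")
  rec <- classify_pair(a, b, sexes = c("F", "M"))
  expect_equal(rec$relationship, "between")
  expect_equal(rec$sex_class, "FM")
  expect_null(rec$weekly)
  expect_length(rec$analysis_windows, 1)
})

test_that("FF classification separates shared and disjoint ranges", {
  set.seed(6)
  g <- env_grid(60, 60, 30, xmin = 0, ymax = 1800)
  n <- 4032  # two ISO weeks at 5-min steps
  tt <- 0:(n - 1) * 5
  xa <- 600 + ou_sim(n, 5, 60, 1e4); ya <- 900 + ou_sim(n, 5, 60, 1e4)
  a <- reg_track(tt, xa, ya, "a")
  twin <- reg_track(tt, xa + rnorm(n, 0, 2), ya + rnorm(n, 0, 2), "b")
  rec <- classify_pair(a, twin, sexes = c("F", "F"), grid = g)
  expect_equal(rec$relationship, "within")
  expect_true(all(rec$weekly$overlap > 0.5))
  far <- reg_track(tt, 1200 + ou_sim(n, 5, 60, 1e4),
                   900 + ou_sim(n, 5, 60, 1e4), "c")
  rec2 <- classify_pair(a, far, sexes = c("F", "F"), grid = g)
  expect_equal(rec2$relationship, "between")
  short <- reg_track(0:100 * 5, rnorm(101), rnorm(101), "d")
  expect_error(classify_pair(a, short, c("F", "F"), grid = g),
               class = "insufficient_data")
})

test_that("overlap series classification handles temporary merges and is stable", {
  cls <- contactRSF:::classify_overlap_series
  # aggregate above threshold -> within
  expect_equal(cls(rep(0.8, 10))$relationship, "within")
  # all below -> between
  expect_equal(cls(rep(0.1, 10))$relationship, "between")
  # a >12-week above-threshold run inside a low record -> temporary,
  # with exactly that run excluded
  ser <- c(rep(0.05, 8), rep(0.9, 13), rep(0.05, 20))
  r <- cls(ser)
  expect_equal(r$relationship, "temporary")
  expect_equal(r$excluded, 9:21)
  # a 12-week run is not enough (strictly more than 12)
  ser12 <- c(rep(0.05, 8), rep(0.9, 12), rep(0.05, 20))
  expect_equal(cls(ser12)$relationship, "between")
  # stability: appending below-threshold weeks never flips between->within
  base <- rep(0.2, 10)
  expect_equal(cls(c(base, 0.4))$relationship, "between")
})

test_that("pair filtering keeps strictly more than min_contacts between-group pairs", {
  mk <- function(rel, n) {
    r <- contactRSF:::new_pair_record(c("a", "b"), "FF", rel,
                                      c(T0, T0 + 86400), NULL,
                                      list(c(T0, T0 + 86400)))
    r$n_contacts <- n
    r
  }
  out <- filter_pairs(list(mk("between", 10), mk("between", 11),
                           mk("within", 500), mk("temporary", 40)))
  expect_length(out, 2)
  expect_equal(vapply(out, `[[`, 0, "n_contacts"), c(11, 40))
  expect_true(all(vapply(out, `[[`, TRUE, "included")))
  expect_length(filter_pairs(list()), 0)
})
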