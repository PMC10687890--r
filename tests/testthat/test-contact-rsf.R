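contact_fixture <- function(n_contacts = 20, n_fix = 400, seed = 71) {
  set.seed(seed)
  env <- tiny_env(n = 40, cell = 30, n_days = 16)
  g <- env$grid
  mask <- matrix(TRUE, 40, 40)
  ov <- contactRSF:::new_grid_region(g, mask)
  tt <- 0:(n_fix - 1) * 5
  a <- trajectory("a", T0 + tt * 60, runif(n_fix, 100, 1100),
                  runif(n_fix, 100, 1100), regular = TRUE, interval_min = 5)
  b <- trajectory("b", T0 + tt * 60, runif(n_fix, 100, 1100),
                  runif(n_fix, 100, 1100), regular = TRUE, interval_min = 5)
  ctimes <- sort(sample(tt, n_contacts))
  ev <- data.frame(id_a = "a", id_b = "b", time = T0 + ctimes * 60,
                   x = runif(n_contacts, 100, 1100),
                   y = runif(n_contacts, 100, 1100), distance = 5)
  class(ev) <- c("contact_events", "data.frame")
  rec <- contactRSF:::new_pair_record(c("a", "b"), "FF", "between",
                                      range(a$time), NULL,
                                      list(range(a$time)))
  rec$n_contacts <- n_contacts
  list(env = env, ov = ov, tracks = list(a, b), ev = ev, rec = rec)
}

test_that("contact datasets cap availability at 30 per used point", {
  fx <- contact_fixture(n_contacts = 20, n_fix = 4000)
  # ~8000 candidate fixes > 600 -> capped at exactly 600
  ds <- build_contact_dataset(fx$rec, fx$ev, fx$tracks, fx$ov, fx$env,
                              ratio_cap = 30, seed = 4)
  expect_equal(sum(ds$label == 1), 20)
  expect_equal(sum(ds$label == 0), 600)
  expect_identical(
    as.data.frame(build_contact_dataset(fx$rec, fx$ev, fx$tracks, fx$ov,
                                        fx$env, ratio_cap = 30, seed = 4)),
    as.data.frame(ds))
})

test_that("the cap is not an upsampling quota", {
  fx <- contact_fixture(n_contacts = 20, n_fix = 60)
  ds <- build_contact_dataset(fx$rec, fx$ev, fx$tracks, fx$ov, fx$env)
  # 2 x 60 fixes minus 2 x 20 contact timestamps = 80 candidates < 600
  expect_equal(sum(ds$label == 0), 80)
})

test_that("contact timestamps are excluded from availability", {
  fx <- contact_fixture(n_contacts = 30, n_fix = 200)
  ds <- build_contact_dataset(fx$rec, fx$ev, fx$tracks, fx$ov, fx$env,
                              seed = 9)
  used_times <- as.numeric(fx$ev$time)
  avail_rows <- ds[ds$label == 0, ]
  fix_times <- as.numeric(fx$tracks[[1]]$time)
  # reconstruct availability timestamps by matching coordinates
  for (tr in fx$tracks) {
    hit <- match(paste(avail_rows$x, avail_rows$y),
                 paste(tr$x, tr$y))
    t_avail <- as.numeric(tr$time[hit[!is.na(hit)]])
    expect_false(any(t_avail %in% used_times))
  }
})

test_that("degenerate contact designs are rejected", {
  fx <- contact_fixture()
  empty <- contactRSF:::new_grid_region(fx$env$grid,
                                        matrix(FALSE, 40, 40))
  expect_error(build_contact_dataset(fx$rec, fx$ev, fx$tracks, empty,
                                     fx$env), class = "degenerate_input")
  no_ev <- fx$ev[0, ]
  expect_error(build_contact_dataset(fx$rec, no_ev, fx$tracks, fx$ov,
                                     fx$env), class = "degenerate_input")
  ds <- build_contact_dataset(fx$rec, fx$ev, fx$tracks, fx$ov, fx$env)
  expect_error(fit_contact_rsf(ds, character(0)),
               class = "invalid_argument")
})

test_that("pair aggregation weights by contact counts", {
  mk <- function(owner, b) contactRSF:::new_rsf_model(
    owner, "x1", c("(Intercept)" = 0, x1 = b),
    c("(Intercept)" = 0.1, x1 = 0.2), -5, 10, 300, TRUE, FALSE)
  pop <- aggregate_contact_population(list(mk("p1", 0), mk("p2", 4)),
                                      pair_contact_counts = c(100, 300))
  expect_equal(unname(pop$beta["x1"]), 3)
  single <- aggregate_contact_population(list(mk("p1", 2)), 50)
  expect_equal(unname(single$beta["x1"]), 2)
  eq <- aggregate_contact_population(list(mk("p1", 1), mk("p2", 3)),
                                     c(7, 7))
  expect_equal(unname(eq$beta["x1"]), 2)
})

mkpop <- function(covs, betas, se = 0.1) {
  terms <- c("(Intercept)", covs)
  b <- setNames(c(0, betas), terms)
  s <- setNames(rep(se, length(terms)), terms)
  structure(list(terms = terms, covariates = covs, beta = b, se = s,
                 ci_lo = b - 1.96 * s, ci_hi = b + 1.96 * s,
                 weights = 1, n_owners = 1, owners = "p"),
            class = "population_rsf")
}

test_that("identical populations compare as equivalent", {
  env <- tiny_env(n = 12, cell = 30)
  p <- mkpop("tree_canopy", 0.9)
  rep_ <- compare_rsf(p, p, env, env$dates[1])
  expect_true(all(rep_$table$difference == 0))
  expect_equal(rep_$surface_spearman, 1)
  expect_equal(rep_$surface_pearson, 1)
  expect_true(rep_$all_signs_agree)
})

test_that("negated coefficients give Spearman -1 on a monotone surface", {
  env <- tiny_env(n = 12, cell = 30)
  rep_ <- compare_rsf(mkpop("tree_canopy", 1.2), mkpop("tree_canopy", -1.2),
                      env, env$dates[1])
  expect_equal(rep_$surface_spearman, -1)
  expect_false(rep_$all_signs_agree)
  expect_equal(rep_$table$sign_contact, "+")
  expect_equal(rep_$table$sign_individual, "-")
  expect_error(compare_rsf(mkpop("road", 1), mkpop("water", 1), env,
                           env$dates[1]), class = "invalid_argument")
})

test_that("the dissociation scenario reproduces sign discordance end to end", {
  scn <- scenario_dissociation(seed = 2)
  fit <- scenario_fit(scn)
  rep_ <- compare_rsf(fit$pop_contact, fit$pop_individual, scn$env,
                      scn$env$dates[1])
  row <- rep_$table[rep_$table$covariate == "food", ]
  expect_equal(row$sign_contact, "+")
  expect_equal(row$sign_individual, "0")
  expect_false(row$sign_agreement)
})
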