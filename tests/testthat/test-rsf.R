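test_that("individual datasets honor the 30:1 design contract", {
  set.seed(14)
  env <- tiny_env(n = 30, cell = 30)
  g <- env$grid
  n <- 100
  it <- trajectory("a", T0 + 0:(n - 1) * 300,
                   rnorm(n, 450, 80), rnorm(n, 450, 80),
                   regular = TRUE, interval_min = 5)
  hr <- kde_homerange(it[, c("x", "y")], g, c(0.95, 0.5), animal_id = "a")
  ds <- build_individual_dataset(it, hr, env, ratio = 30, seed = 5)
  expect_equal(sum(ds$label == 1), 100)
  expect_equal(sum(ds$label == 0), 3000)       # 30 per used point
  avail <- ds[ds$label == 0, ]
  expect_true(all(region_contains(hr_region(hr, 0.95), avail$x, avail$y)))
  # availability inherits the paired used point's date
  expect_setequal(unique(avail$date), unique(ds$date[ds$label == 1]))
  # determinism under the seed
  ds2 <- build_individual_dataset(it, hr, env, ratio = 30, seed = 5)
  expect_identical(as.data.frame(ds), as.data.frame(ds2))
  # standardized continuous covariates
  std <- attr(ds, "standardizers")
  expect_true("tree_canopy" %in% std$covariate)
  expect_false("road" %in% std$covariate)      # binary untouched
  expect_lt(abs(mean(ds$tree_canopy)), 0.05)
  expect_true(sd(ds$tree_canopy) > 0.95 && sd(ds$tree_canopy) < 1.05)
})

exact_cor_design <- function(n, r) {
  # columns with exactly the requested sample correlation
  z1 <- scale(rnorm(n))[, 1]
  z2 <- scale(resid(lm(rnorm(n) ~ z1)))[, 1]
  data.frame(a = z1, b = r * z1 + sqrt(1 - r^2) * z2)
}

test_that("collinearity screen applies the |r| >= 0.6 rule iteratively", {
  set.seed(2)
  d <- exact_cor_design(500, 0.59)
  expect_setequal(screen_collinearity(d, 0.6), c("a", "b"))
  d2 <- exact_cor_design(500, 0.61)
  expect_equal(screen_collinearity(d2, 0.6), "a")  # later member drops
  # duplicated covariate: r = 1
  d3 <- data.frame(a = rnorm(100)); d3$b <- d3$a
  expect_equal(screen_collinearity(d3, 0.6), "a")
  # three mutually correlated at ~0.9 leave exactly one survivor
  z <- rnorm(500)
  d4 <- data.frame(a = z + rnorm(500, 0, 0.3), b = z + rnorm(500, 0, 0.3),
                   c = z + rnorm(500, 0, 0.3))
  expect_gte(min(abs(cor(d4)[upper.tri(diag(3))])), 0.6)
  expect_length(screen_collinearity(d4, 0.6), 1)
  # priority order decides the survivor
  expect_equal(screen_collinearity(d2, 0.6, priority_order = c("b", "a")),
               "b")
})

test_that("logistic RSF recovers a known selection coefficient", {
  set.seed(30)
  ds <- logistic_design(5000, beta_true = 1.0)
  m <- fit_rsf(ds, "x1")
  expect_true(m$converged)
  expect_gte(m$coef[["x1"]], 0.8); expect_lte(m$coef[["x1"]], 1.2)
  expect_equal(m$aic, 2 * m$k - 2 * m$loglik)
})

test_that("null covariates stay within 3 SE of zero", {
  set.seed(31)
  ds <- logistic_design(5000, beta_true = 0)
  m <- fit_rsf(ds, "x1")
  expect_lt(abs(m$coef[["x1"]]), 3 * m$se[["x1"]])
})

test_that("intercept-only fit equals the closed-form Bernoulli likelihood", {
  set.seed(32)
  ds <- logistic_design(200, beta_true = 0.5)
  m <- fit_rsf(ds, character(0))
  p <- mean(ds$label)
  n1 <- sum(ds$label); n0 <- sum(!ds$label)
  expect_equal(m$loglik, n1 * log(p) + n0 * log(1 - p), tolerance = 1e-6)
  expect_equal(unname(m$coef[1]), log(p / (1 - p)), tolerance = 1e-6)
})

test_that("separation triggers the ridge-stabilized fallback", {
  df <- data.frame(label = rep(c(1L, 0L), each = 50), owner = "o",
                   x = 0, y = 0, date = as.Date("2020-01-01"),
                   x1 = rep(c(1, 0), each = 50))
  ds <- contactRSF:::new_ua_dataset(df, "o", data.frame(), 1, 1)
  m <- fit_rsf(ds, "x1")
  expect_true(m$ridged)
  expect_false(m$converged)
  expect_true(all(is.finite(m$coef)))
  expect_error(fit_rsf(ds, "zz"), class = "invalid_argument")
  ds_one <- ds[ds$label == 1, ]
  expect_error(fit_rsf(ds_one, "x1"), class = "invalid_argument")
})

test_that("cumulative-AIC selection prefers the generating structure", {
  set.seed(40)
  owners <- lapply(1:3, function(i) {
    ds <- logistic_design(2000, beta_true = 1.0, owner = paste0("o", i))
    for (nm in c("n1", "n2", "n3")) ds[[nm]] <- rnorm(nrow(ds))
    ds
  })
  sel <- select_model(list(gen = "x1", noisy = c("x1", "n1", "n2", "n3")),
                      owners)
  expect_equal(sel$name, "gen")
  expect_equal(nrow(sel$table), 2)
  # bookkeeping: aic = 2 k n_owners - 2 cum_loglik
  expect_equal(sel$table$aic,
               2 * sel$table$k * sel$table$n_owners - 2 * sel$table$cum_loglik)
  single <- select_model(list(only = "x1"), owners)
  expect_equal(single$name, "only")
  expect_error(select_model(list(), owners), class = "invalid_argument")
})

test_that("population aggregation is a weighted mean with Murtaugh SEs", {
  mk <- function(owner, b, se, n) contactRSF:::new_rsf_model(
    owner, "x1", c("(Intercept)" = 0, x1 = b),
    c("(Intercept)" = 0.1, x1 = se), loglik = -10, n_used = n,
    n_avail = 30 * n, converged = TRUE, ridged = FALSE)
  ms <- list(mk("a", 1, 0.2, 10), mk("b", 2, 0.2, 10), mk("c", 3, 0.2, 10))
  # weights proportional to m_i * n_i = (0.5, 0.3, 0.2)
  pop <- aggregate_population(ms, owner_pair_counts = c(5, 3, 2),
                              owner_sample_sizes = c(10, 10, 10))
  expect_equal(unname(pop$beta["x1"]), 1.7)
  expect_equal(sum(pop$weights), 1)
  expect_equal(unname(pop$se["x1"]),
               sqrt(sum(c(0.5, 0.3, 0.2)^2 * 0.2^2)))
  # equal weights -> arithmetic mean; single owner -> that owner
  expect_equal(unname(aggregate_population(ms, c(1, 1, 1),
                                           c(1, 1, 1))$beta["x1"]), 2)
  expect_equal(unname(aggregate_population(ms[1], 1, 1)$beta["x1"]), 1)
  # containment of the weighted mean
  expect_true(pop$beta["x1"] >= 1 && pop$beta["x1"] <= 3)
  bad <- list(mk("a", 1, 0.2, 10),
              contactRSF:::new_rsf_model("b", "x2",
                                         c("(Intercept)" = 0, x2 = 1),
                                         c("(Intercept)" = 1, x2 = 1),
                                         -1, 5, 50, TRUE, FALSE))
  expect_error(aggregate_population(bad), class = "invalid_argument")
})

test_that("cross-validation withholds 20% of used points per fold", {
  set.seed(50)
  ds <- logistic_design(103, beta_true = 2, ratio = 10)
  cv <- crossvalidate(ds, "x1", k = 5, n_bins = 10, seed = 2)
  expect_length(cv$fold_rs, 5)
  expect_true(all(cv$fold_rs >= -1 & cv$fold_rs <= 1))
  # fold sizes: 103 used over 5 folds -> 20 or 21 withheld
  set.seed(2)
  fold <- sample(rep_len(1:5, 103))
  expect_true(all(abs(table(fold) - 103 / 5) <= 1))
})

test_that("a strongly informative covariate yields high Spearman r_s", {
  set.seed(51)
  ds <- logistic_design(1000, beta_true = 2, ratio = 10)
  cv <- crossvalidate(ds, "x1", seed = 3)
  expect_gt(cv$mean_rs, 0.9)
})

test_that("prediction surfaces follow the exp(beta x) -> [0,1] contract", {
  env <- tiny_env(n = 12, cell = 30)
  mkpop <- function(covs, betas) structure(
    list(terms = c("(Intercept)", covs), covariates = covs,
         beta = setNames(c(0, betas), c("(Intercept)", covs)),
         se = setNames(rep(0.1, length(covs) + 1), c("(Intercept)", covs)),
         ci_lo = setNames(rep(-1, length(covs) + 1), c("(Intercept)", covs)),
         ci_hi = setNames(rep(1, length(covs) + 1), c("(Intercept)", covs)),
         weights = 1, n_owners = 1, owners = "a"),
    class = "population_rsf")
  # all-zero coefficients -> uniform surface
  s0 <- predict_surface(mkpop("road", 0), env, env$dates[1])
  expect_true(all(s0 == 0.5))
  # single binary covariate: feature cells 1, others 0 after rescale
  s1 <- predict_surface(mkpop("road", 1.5), env, env$dates[1])
  expect_equal(sort(unique(as.vector(s1))), c(0, 1))
  expect_true(all(s1[env$static$road == 1] == 1))
  # generic surface spans [0, 1] exactly
  s2 <- predict_surface(mkpop("tree_canopy", 0.8), env, env$dates[1])
  expect_equal(min(s2), 0); expect_equal(max(s2), 1)
})

test_that("standardization round-trips: shifted/scaled covariates give the same model", {
  set.seed(60)
  n <- 800
  raw <- data.frame(
    label = rep(c(1L, 0L), c(n, n * 5)), owner = "o", x = 0, y = 0,
    date = as.Date("2020-01-01"),
    tree_canopy = c(rnorm(n, 1, 1), rnorm(n * 5, 0, 1)))
  s1 <- contactRSF:::standardize_design(raw, "tree_canopy")
  d1 <- contactRSF:::new_ua_dataset(s1$df, "o", s1$standardizers, 5, 1)
  raw2 <- raw
  raw2$tree_canopy <- raw$tree_canopy * 3 + 100   # affine transform
  s2 <- contactRSF:::standardize_design(raw2, "tree_canopy")
  d2 <- contactRSF:::new_ua_dataset(s2$df, "o", s2$standardizers, 5, 1)
  m1 <- fit_rsf(d1, "tree_canopy"); m2 <- fit_rsf(d2, "tree_canopy")
  expect_equal(m1$coef, m2$coef, tolerance = 1e-6)
  expect_equal(m1$loglik, m2$loglik, tolerance = 1e-6)
})
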