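test_that("IID fit matches the closed-form Gaussian solution", {
  set.seed(1)
  tt <- seq(0, 990, by = 10)
  x <- rnorm(100, 50, 20); y <- rnorm(100, -30, 20)
  m <- fit_movement_model(make_track(tt, x, y, error_sd = 0), "IID")
  expect_equal(m$mu, c(mean(x), mean(y)))
  v <- (mean((x - mean(x))^2) + mean((y - mean(y))^2)) / 2
  expect_equal(m$sigma2, v)
  expect_equal(m$loglik,
               sum(dnorm(x, mean(x), sqrt(v), log = TRUE)) +
                 sum(dnorm(y, mean(y), sqrt(v), log = TRUE)))
  expect_equal(m$aic, 2 * m$k - 2 * m$loglik)
})

test_that("Kalman likelihood equals the dense-covariance oracle", {
  # hand 5-fix irregular track at fixed parameters (whitebox on internals)
  tt <- c(0, 7, 20, 33, 61)
  x <- c(10, 14, 3, -5, 8); y <- c(0, 2, -4, 6, 1)
  dt <- c(0, diff(tt))
  st <- contactRSF:::ou_steps(dt, tau_p = 15, sigma2 = 40)
  pk <- contactRSF:::state_loglik(st, tt, x, y, err_var = 4)
  expect_equal(pk$ll,
               dense_loglik(tt, x, y, "OU", pk$mu, 40, tau_p = 15,
                            err_var = 4),
               tolerance = 1e-9)
  st2 <- contactRSF:::ouf_steps(dt, tau_p = 25, tau_v = 5, sigma2 = 40)
  pk2 <- contactRSF:::state_loglik(st2, tt, x, y, err_var = 4)
  expect_equal(pk2$ll,
               dense_loglik(tt, x, y, "OUF", pk2$mu, 40, tau_p = 25,
                            tau_v = 5, err_var = 4),
               tolerance = 1e-9)

  # full fits on seeded <= 50-fix tracks: reported loglik equals the dense
  # oracle evaluated at the reported parameters
  set.seed(7)
  tt3 <- cumsum(runif(40, 5, 15)); tt3 <- tt3 - tt3[1]
  xx <- ou_sim(40, 10, 45, 900) + 100
  yy <- ou_sim(40, 10, 45, 900) - 50
  tr <- make_track(tt3, xx, yy, error_sd = 3)
  for (fam in c("OU", "OUF")) {
    m <- fit_movement_model(tr, fam)
    expect_equal(m$loglik,
                 dense_loglik(tt3, xx, yy, fam, m$mu, m$sigma2,
                              tau_p = m$tau_p, tau_v = m$tau_v,
                              err_var = m$error_var),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("maximized log-likelihood is monotone under nesting IID < OU < OUF", {
  for (seed in 1:2) {
    set.seed(seed)
    n <- 150
    xx <- ou_sim(n, 10, 60, 1e4); yy <- ou_sim(n, 10, 60, 1e4)
    tr <- make_track(seq(0, by = 10, length.out = n), xx, yy, error_sd = 0)
    lls <- vapply(c("IID", "OU", "OUF"), function(f)
      fit_movement_model(tr, f)$loglik, 0)
    expect_gte(lls["OU"], lls["IID"] - 1e-6)
    expect_gte(lls["OUF"], lls["OU"] - 1e-6)
  }
})

test_that("model selection picks IID on white noise and respects candidate set", {
  set.seed(3)
  tr <- make_track(seq(0, by = 10, length.out = 300),
                   rnorm(300, 0, 50), rnorm(300, 0, 50), error_sd = 0)
  sel <- select_movement_model(tr)
  expect_equal(sel$family, "IID")
  expect_s3_class(attr(sel, "candidates"), "data.frame")
  only <- select_movement_model(tr, families = "OU")
  expect_equal(only$family, "OU")
})

test_that("fit preconditions are enforced", {
  tr <- make_track(1:5 * 10, 1:5, 1:5)
  expect_error(fit_movement_model(tr, "OU"), class = "insufficient_data")
  tr2 <- make_track(seq(0, 110, by = 10), rnorm(12), rnorm(12))
  m <- fit_movement_model(tr2, "IID")
  expect_error(interpolate(tr2, m, interval_min = 0),
               class = "invalid_argument")
})

test_that("interpolation passes exactly through zero-error observations", {
  set.seed(11)
  n <- 60
  tt <- seq(0, by = 10, length.out = n)
  tr <- make_track(tt, ou_sim(n, 10, 60, 1e4) + 500,
                   ou_sim(n, 10, 60, 1e4), error_sd = 0)
  for (fam in c("OU", "OUF", "IOU")) {
    m <- fit_movement_model(tr, fam)
    it <- interpolate(tr, m, 5)
    expect_true(is_regular(it))
    expect_equal(median(diff(as.numeric(it$time))) / 60, 5)
    idx <- match(as.numeric(tr$time), as.numeric(it$time))
    expect_false(anyNA(idx))
    expect_equal(it$x[idx], tr$x, tolerance = 1e-9)
    expect_equal(it$y[idx], tr$y, tolerance = 1e-9)
  }
})

test_that("IID interpolation returns the mean between fixes", {
  set.seed(2)
  tr <- make_track(seq(0, by = 10, length.out = 50),
                   rnorm(50, 100, 10), rnorm(50, -40, 10), error_sd = 0)
  m <- fit_movement_model(tr, "IID")
  it <- interpolate(tr, m, 5)
  between <- !(as.numeric(it$time) %in% as.numeric(tr$time))
  expect_true(any(between))
  expect_true(all(abs(it$x[between] - m$mu[1]) < 1e-9))
  expect_true(all(abs(it$y[between] - m$mu[2]) < 1e-9))
})

test_that("OU two-fix midpoint matches the closed-form kriging oracle", {
  tr <- make_track(c(0, 20), c(0, 10), c(5, -5), error_sd = 0)
  m <- contactRSF:::new_movement_model("OU", mu = c(2, 1), sigma2 = 100,
                                       tau_p = 30, tau_v = NA_real_,
                                       error_var = 0, loglik = 0, k = 4L,
                                       n = 2L)
  it <- interpolate(tr, m, 10)
  i <- which(as.numeric(it$time) == as.numeric(tr$time[1]) + 600)
  r <- exp(-10 / 30); r12 <- exp(-20 / 30)
  w <- solve(matrix(c(1, r12, r12, 1), 2), c(r, r))
  expect_equal(it$x[i], 2 + sum(w * (c(0, 10) - 2)), tolerance = 1e-8)
  expect_equal(it$y[i], 1 + sum(w * (c(5, -5) - 1)), tolerance = 1e-8)
})

test_that("interpolating an already-regular track is idempotent", {
  set.seed(5)
  n <- 100
  tr <- make_track(seq(0, by = 5, length.out = n),
                   ou_sim(n, 5, 60, 1e4), ou_sim(n, 5, 60, 1e4),
                   error_sd = 0)
  m <- fit_movement_model(tr, "OU")
  it <- interpolate(tr, m, 5)
  expect_equal(nrow(it), n)
  expect_equal(it$x, tr$x, tolerance = 1e-9)
  expect_equal(it$y, tr$y, tolerance = 1e-9)
})

test_that("movement models serialize to JSON and back losslessly", {
  set.seed(4)
  tr <- make_track(seq(0, by = 10, length.out = 50),
                   ou_sim(50, 10, 30, 400), ou_sim(50, 10, 30, 400),
                   error_sd = 2)
  m <- fit_movement_model(tr, "OU")
  f <- tempfile(fileext = ".json")
  movement_model_json(m, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(x$tau_p, m$tau_p)
  expect_equal(x$loglik, m$loglik)
  expect_equal(x$aic, 2 * x$k - 2 * x$loglik)
})
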