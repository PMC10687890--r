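# Independent oracles and fixture generators shared across the suite.
# Oracles are written from first principles (dense covariance matrices,
# exhaustive scans) and never call the code paths they check.

T0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

make_track <- function(tt_min, x, y, id = "a", error_sd = NULL, ...) {
  trajectory(id, T0 + tt_min * 60, x, y, error_sd = error_sd, ...)
}

# multivariate normal log-density via Cholesky
dmvn_log <- function(y, mu, S) {
  L <- chol(S)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# dense-covariance log-likelihood oracle for the stationary families;
# x and y independent with shared isotropic parameters
dense_loglik <- function(tt_min, x, y, family, mu, sigma2, tau_p = NA,
                         tau_v = NA, err_var = 0) {
  D <- abs(outer(tt_min, tt_min, "-"))
  C <- switch(family,
    IID = sigma2 * (D == 0),
    OU  = sigma2 * exp(-D / tau_p),
    OUF = sigma2 * (tau_p * exp(-D / tau_p) - tau_v * exp(-D / tau_v)) /
      (tau_p - tau_v))
  C <- C + diag(err_var, length(tt_min))
  dmvn_log(x, rep(mu[1], length(tt_min)), C) +
    dmvn_log(y, rep(mu[2], length(tt_min)), C)
}

# exact OU series on a regular grid (caller controls the RNG seed)
ou_sim <- function(n, dt_min, tau, sigma2) {
  a <- exp(-dt_min / tau)
  z <- numeric(n)
  z[1] <- rnorm(1, 0, sqrt(sigma2))
  for (i in 2:n) z[i] <- a * z[i - 1] + rnorm(1, 0, sqrt(sigma2 * (1 - a^2)))
  z
}

# exact OUF position series via the 2x2 position-velocity transition
ouf_sim <- function(n, dt_min, tau_p, tau_v, sigma2) {
  l1 <- 1 / tau_p; l2 <- 1 / tau_v; dl <- l2 - l1
  e1 <- exp(-l1 * dt_min); e2 <- exp(-l2 * dt_min)
  Phi <- matrix(c((l2 * e1 - l1 * e2) / dl, l1 * l2 * (e2 - e1) / dl,
                  (e1 - e2) / dl, (l2 * e2 - l1 * e1) / dl), 2, 2)
  Pinf <- diag(c(sigma2, sigma2 / (tau_p * tau_v)))
  Q <- Pinf - Phi %*% Pinf %*% t(Phi)
  Lp <- t(chol(Pinf + diag(1e-12, 2)))
  Lq <- t(chol(Q + diag(1e-12, 2)))
  z <- matrix(0, n, 2)
  z[1, ] <- drop(Lp %*% rnorm(2))
  for (i in 2:n) z[i, ] <- drop(Phi %*% z[i - 1, ]) + drop(Lq %*% rnorm(2))
  z[, 1]
}

# exhaustive all-pairs-of-timestamps contact scan (O(n^2) oracle);
# plain vectors are hoisted out of the loop so the scan itself stays a
# literal double loop over every timestamp pair
brute_contacts <- function(track_a, track_b, buffer_m) {
  ta <- as.numeric(track_a$time); tb <- as.numeric(track_b$time)
  xa <- track_a$x; ya <- track_a$y; xb <- track_b$x; yb <- track_b$y
  t_hit <- numeric(0); d_hit <- numeric(0)
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      if (ta[i] == tb[j]) {
        d <- sqrt((xa[i] - xb[j])^2 + (ya[i] - yb[j])^2)
        if (d <= buffer_m) {
          t_hit <- c(t_hit, ta[i]); d_hit <- c(d_hit, d)
        }
      }
    }
  }
  data.frame(time = as.POSIXct(t_hit, origin = "1970-01-01", tz = "UTC"),
             distance = d_hit)
}

# small environmental stack with hand-controlled layers
tiny_env <- function(n = 10, cell = 10, n_days = 2) {
  grid <- env_grid(n, n, cell, xmin = 0, ymax = n * cell)
  z <- matrix(0, n, n)
  road <- z; road[5, ] <- 1
  water <- z; water[1, 1] <- 1
  canopy <- matrix(seq(0, 1, length.out = n * n), n, n)
  dates <- seq(as.Date("2020-01-01"), by = "day", length.out = n_days)
  food <- lapply(seq_len(n_days), function(d) {
    m <- z; if (d %% 2 == 1) m[2, 2] <- 1; m
  })
  ndvi <- lapply(seq_len(n_days), function(d) canopy * 0.5 + 0.1 * d)
  contactRSF:::new_env_stack(
    grid,
    static = list(wetland = z, water = water, road = road,
                  fence_or_trail = z, ditch = z, tree_canopy = canopy),
    dynamic = list(ndvi = ndvi, food = food,
                   tmax = as.list(20 + seq_len(n_days)),
                   tmin = as.list(10 + seq_len(n_days)),
                   prcp = as.list(rep(0, n_days)),
                   rhum = as.list(rep(70, n_days)),
                   vp = as.list(rep(1.2, n_days))),
    dates = dates)
}

# home-range stand-in with a prescribed isopleth mask (tests of region
# algebra that do not depend on the KDE itself)
mask_hr <- function(grid, mask, level = 0.95, id = "x") {
  dens <- mask / (sum(mask) * grid$cell^2)
  structure(list(animal_id = id, grid = grid, density = dens,
                 isopleths = setNames(list(mask > 0), sprintf("%g", level)),
                 bandwidth = c(1, 1), n = 100L),
            class = "home_range")
}

# used-available design with a single standard-normal covariate whose true
# selection log-odds is beta_true per SD (used x ~ N(beta, 1))
logistic_design <- function(n_used, beta_true, ratio = 30, owner = "o1") {
  x_used <- rnorm(n_used, beta_true, 1)
  x_avail <- rnorm(n_used * ratio, 0, 1)
  df <- data.frame(
    label = c(rep(1L, n_used), rep(0L, n_used * ratio)),
    owner = owner, x = 0, y = 0, date = as.Date("2020-01-01"),
    x1 = c(x_used, x_avail))
  contactRSF:::new_ua_dataset(df, owner,
                              data.frame(covariate = character(),
                                         mean = numeric(), sd = numeric()),
                              ratio, 1L)
}
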