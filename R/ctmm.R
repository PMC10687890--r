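#' Continuous-time movement models
#'
#' Four Gaussian-process families for animal position are supported, in
#' increasing order of autocorrelation structure:
#' \describe{
#'   \item{IID}{uncorrelated positions about a mean (no movement memory)}
#'   \item{OU}{mean-reverting position with timescale `tau_p` (range residency)}
#'   \item{IOU}{nonstationary integrated OU: correlated velocity with
#'     timescale `tau_v`, no home-range attractor}
#'   \item{OUF}{OU foraging: range residency (`tau_p`) plus correlated
#'     velocity (`tau_v`); requires `tau_p > tau_v`}
#' }
#' The x and y coordinates are treated as independent with shared
#' timescales and an isotropic spatial variance `sigma2`. Likelihoods are
#' exact linear-Gaussian (Kalman filter) likelihoods handling irregular
#' sampling; the IOU likelihood is defined conditionally on the first fix
#' (diffuse position prior).
#'
#' @name ctmm-families
NULL

CTMM_FAMILIES <- c("IID", "OU", "IOU", "OUF")

# ---- state-space step builders ------------------------------------------
# Each builder returns per-step transition and process-noise arrays for the
# Kalman recursions. Slice 1 encodes the prior (Phi = 0, Q = P_inf) so a
# stationary start uses the same recursion; IOU instead conditions on the
# first observation.

ou_steps <- function(dt_min, tau_p, sigma2) {
  n <- length(dt_min)
  a <- exp(-dt_min / tau_p)
  Phi <- array(0, c(1, 1, n)); Q <- array(0, c(1, 1, n))
  Phi[1, 1, ] <- a; Q[1, 1, ] <- sigma2 * (1 - a^2)
  Phi[1, 1, 1] <- 0; Q[1, 1, 1] <- sigma2
  list(Phi = Phi, Q = Q, condition_first = FALSE, d = 1L)
}

ouf_steps <- function(dt_min, tau_p, tau_v, sigma2) {
  # symmetric in the two timescales; avoid the confluent case numerically
  if (abs(tau_p - tau_v) < 1e-6 * tau_p) tau_v <- tau_p / (1 + 1e-5)
  n <- length(dt_min)
  l1 <- 1 / tau_p; l2 <- 1 / tau_v; dl <- l2 - l1
  e1 <- exp(-l1 * dt_min); e2 <- exp(-l2 * dt_min)
  Phi <- array(0, c(2, 2, n))
  Phi[1, 1, ] <- (l2 * e1 - l1 * e2) / dl
  Phi[1, 2, ] <- (e1 - e2) / dl
  Phi[2, 1, ] <- l1 * l2 * (e2 - e1) / dl
  Phi[2, 2, ] <- (l2 * e2 - l1 * e1) / dl
  # Q = Pinf - Phi Pinf Phi', written out elementwise (Pinf diagonal)
  p1 <- sigma2; p2 <- sigma2 / (tau_p * tau_v)
  Q <- array(0, c(2, 2, n))
  Q[1, 1, ] <- p1 - (Phi[1, 1, ]^2 * p1 + Phi[1, 2, ]^2 * p2)
  Q[1, 2, ] <- Q[2, 1, ] <- -(Phi[1, 1, ] * Phi[2, 1, ] * p1 +
                                Phi[1, 2, ] * Phi[2, 2, ] * p2)
  Q[2, 2, ] <- p2 - (Phi[2, 1, ]^2 * p1 + Phi[2, 2, ]^2 * p2)
  Phi[, , 1] <- 0
  Q[, , 1] <- diag(c(p1, p2))
  list(Phi = Phi, Q = Q, condition_first = FALSE, d = 2L)
}

iou_steps <- function(dt_min, tau_v, sigma2_v, prior_pos_var) {
  n <- length(dt_min)
  ph <- exp(-dt_min / tau_v)
  Phi <- array(0, c(2, 2, n)); Q <- array(0, c(2, 2, n))
  Phi[1, 1, ] <- 1
  Phi[1, 2, ] <- tau_v * (1 - ph)
  Phi[2, 2, ] <- ph
  Q[1, 1, ] <- 2 * sigma2_v * tau_v *
    (dt_min - 2 * tau_v * (1 - ph) + tau_v * (1 - ph^2) / 2)
  Q[1, 2, ] <- Q[2, 1, ] <- sigma2_v * tau_v * (1 - ph)^2
  Q[2, 2, ] <- sigma2_v * (1 - ph^2)
  # slice 1 = conditional prior given the first observation
  Phi[, , 1] <- 0
  Q[, , 1] <- diag(c(prior_pos_var, sigma2_v))
  list(Phi = Phi, Q = Q, condition_first = TRUE, d = 2L)
}

# Kalman log-likelihood for one parameterisation, x/y filtered jointly
# (shared gains), GLS-profiled mean for the stationary families.
state_loglik <- function(steps, tt_min, xx, yy, err_var) {
  n <- length(tt_min)
  Rt <- rep(err_var, n)
  if (steps$condition_first) {
    kf <- kalman_innovations(cbind(xx, yy), Rt, steps$Phi, steps$Q, TRUE)
    idx <- 2:n
    S <- kf$S[idx]
    if (any(!is.finite(S)) || any(S <= 0)) return(list(ll = -Inf))
    ll <- 0
    for (j in 1:2) {
      e <- kf$E[idx, j]
      ll <- ll - 0.5 * sum(log(2 * pi * S) + e^2 / S)
    }
    return(list(ll = ll, mu = c(NA_real_, NA_real_)))
  }
  kf <- kalman_innovations(cbind(xx, yy, 1), Rt, steps$Phi, steps$Q, FALSE)
  S <- kf$S
  if (any(!is.finite(S)) || any(S <= 0)) return(list(ll = -Inf))
  e1 <- kf$E[, 3]
  den <- sum(e1^2 / S)
  if (!is.finite(den) || den <= 0) return(list(ll = -Inf))
  mu <- numeric(2); ll <- 0
  for (j in 1:2) {
    ey <- kf$E[, j]
    mu[j] <- sum(ey * e1 / S) / den
    r <- ey - mu[j] * e1
    ll <- ll - 0.5 * sum(log(2 * pi * S) + r^2 / S)
  }
  list(ll = ll, mu = mu)
}

new_movement_model <- function(family, mu, sigma2, tau_p, tau_v, error_var,
                               loglik, k, n, convergence = TRUE) {
  aic <- 2 * k - 2 * loglik
  stopifnot(isTRUE(all.equal(aic, 2 * k - 2 * loglik)))
  structure(list(family = family, mu = mu, sigma2 = sigma2,
                 tau_p = tau_p, tau_v = tau_v, error_var = error_var,
                 loglik = loglik, k = k, n = n, aic = aic,
                 convergence = convergence),
            class = "movement_model")
}

#' @export
print.movement_model <- function(x, ...) {
  cat(sprintf("<movement_model %s: loglik %.3f, k %d, AIC %.3f>\n",
              x$family, x$loglik, x$k, x$aic))
  invisible(x)
}

#' @export
logLik.movement_model <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
AIC.movement_model <- function(object, ..., k = 2) object$aic

resolve_error_var <- function(track, error_sd) {
  if (!is.null(error_sd)) return(list(var = error_sd^2, profiled = FALSE))
  es <- attr(track, "error_sd")
  if (!is.null(es)) return(list(var = es[1]^2, profiled = FALSE))
  list(var = NA_real_, profiled = TRUE)
}

#' Fit a continuous-time movement model
#'
#' Maximum-likelihood fit of one CTMM family to an irregularly sampled
#' trajectory via an exact Kalman-filter likelihood. Positive parameters
#' are optimised on the log scale with multi-start Nelder-Mead restarts;
#' the mean location is profiled by generalised least squares. The
#' measurement-error variance is fixed from the trajectory's (or the
#' argument's) error SD when supplied, otherwise profiled as a free
#' parameter.
#'
#' @param track a [trajectory()] with at least 10 fixes
#' @param family one of `"IID"`, `"OU"`, `"IOU"`, `"OUF"`
#' @param error_sd optional GPS error SD in meters (overrides the track's)
#' @param n_restarts number of jittered optimizer restarts
#' @return a `movement_model` with parameters, log-likelihood, `k` (number
#'   of free parameters) and `AIC = 2k - 2 logLik`
#' @export
fit_movement_model <- function(track, family, error_sd = NULL,
                               n_restarts = 3) {
  family <- match.arg(family, CTMM_FAMILIES)
  assert_that(nrow(track) >= 10, "insufficient_data",
              "need at least 10 fixes to fit a movement model")
  tt <- as.numeric(track$time) / 60  # minutes
  tt <- tt - tt[1]
  xx <- track$x; yy <- track$y
  n <- length(tt)
  err <- resolve_error_var(track, error_sd)

  if (family == "IID") return(fit_iid(xx, yy, err, n))

  dt <- c(0, diff(tt))
  v0 <- (var(xx) + var(yy)) / 2
  dmed <- median(diff(tt))
  span <- tt[n] - tt[1]
  vel2 <- mean(((diff(xx) / diff(tt))^2 + (diff(yy) / diff(tt))^2) / 2)

  build <- function(par) {
    # par on log scale; layout depends on family / error profiling
    p <- exp(par)
    i <- 0
    ev <- if (err$profiled) p[length(p)] else err$var
    if (family == "OU") {
      steps <- ou_steps(dt, tau_p = p[2], sigma2 = p[1])
    } else if (family == "OUF") {
      steps <- ouf_steps(dt, tau_p = max(p[2], p[3]),
                         tau_v = min(p[2], p[3]), sigma2 = p[1])
    } else { # IOU
      steps <- iou_steps(dt, tau_v = p[2], sigma2_v = p[1],
                         prior_pos_var = ev)
    }
    list(steps = steps, ev = ev, p = p)
  }
  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 60)) return(1e10)
    b <- build(par)
    ll <- state_loglik(b$steps, tt, xx, yy, b$ev)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }

  tau_inits <- c(max(span / 10, dmed), dmed * 5, span / 3)
  starts <- lapply(seq_len(max(1, n_restarts)), function(i) {
    ti <- tau_inits[((i - 1) %% length(tau_inits)) + 1]
    s <- switch(family,
      OU  = log(c(v0, ti)),
      OUF = log(c(v0, ti, max(ti / 8, dmed / 2))),
      IOU = log(c(max(vel2, 1e-8), max(ti / 5, dmed))))
    if (err$profiled) s <- c(s, log(25))
    s
  })

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, negll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    crsf_stop("fit_failure",
              sprintf("no %s restart reached a finite likelihood", family),
              data = list(family = family, starts = starts))

  b <- build(best$par)
  det <- state_loglik(b$steps, tt, xx, yy, b$ev)
  k <- switch(family, OU = 4L, OUF = 5L, IOU = 2L) +
    if (err$profiled) 1L else 0L
  p <- b$p
  if (family == "OU") {
    new_movement_model("OU", det$mu, sigma2 = p[1], tau_p = p[2],
                       tau_v = NA_real_, error_var = b$ev,
                       loglik = det$ll, k = k, n = n,
                       convergence = best$convergence == 0)
  } else if (family == "OUF") {
    new_movement_model("OUF", det$mu, sigma2 = p[1],
                       tau_p = max(p[2], p[3]), tau_v = min(p[2], p[3]),
                       error_var = b$ev, loglik = det$ll, k = k, n = n,
                       convergence = best$convergence == 0)
  } else {
    # sigma2 reported for IOU is the stationary velocity variance (m^2/min^2)
    new_movement_model("IOU", mu = c(NA_real_, NA_real_), sigma2 = p[1],
                       tau_p = NA_real_, tau_v = p[2], error_var = b$ev,
                       loglik = det$ll, k = k, n = n,
                       convergence = best$convergence == 0)
  }
}

fit_iid <- function(xx, yy, err, n) {
  mu <- c(mean(xx), mean(yy))
  vhat <- (mean((xx - mu[1])^2) + mean((yy - mu[2])^2)) / 2
  if (err$profiled) {
    # error indistinguishable from sigma2 under IID; report all as sigma2
    sigma2 <- vhat; ev <- 0
  } else {
    ev <- err$var
    sigma2 <- max(vhat - ev, 0)
  }
  vtot <- sigma2 + ev
  ll <- sum(dnorm(xx, mu[1], sqrt(vtot), log = TRUE)) +
    sum(dnorm(yy, mu[2], sqrt(vtot), log = TRUE))
  new_movement_model("IID", mu, sigma2 = sigma2, tau_p = NA_real_,
                     tau_v = NA_real_, error_var = ev, loglik = ll,
                     k = 3L, n = n)
}

#' Select the best movement model by AIC
#'
#' Fits every requested family and returns the fit minimising AIC, ties
#' (Delta AIC below 1e-9) broken toward fewer parameters. Families whose
#' fit fails are dropped; if all fail a `fit_failure` error is raised.
#'
#' @inheritParams fit_movement_model
#' @param families candidate families
#' @return the winning `movement_model`, with the full candidate table in
#'   attribute `"candidates"`
#' @export
select_movement_model <- function(track, families = CTMM_FAMILIES,
                                  error_sd = NULL, n_restarts = 3) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_movement_model(track, fam, error_sd, n_restarts),
                  crsf_error = function(e) NULL)
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits))
    crsf_stop("fit_failure", "all candidate movement-model fits failed")
  aics <- vapply(fits, `[[`, 0, "aic")
  ks <- vapply(fits, `[[`, 0L, "k")
  best_aic <- min(aics)
  tied <- which(aics <= best_aic + 1e-9)
  win <- tied[which.min(ks[tied])]
  out <- fits[[win]]
  attr(out, "candidates") <- data.frame(
    family = names(fits), loglik = vapply(fits, `[[`, 0, "loglik"),
    k = ks, aic = aics, row.names = NULL)
  out
}

#' Interpolate a trajectory onto a regular grid
#'
#' Predicts the conditional-mean (Kalman-smoother / kriging) position of
#' the fitted movement model on a regular time grid spanning the tracking
#' window. The grid is anchored at the first fix's timestamp rounded down
#' to the interval (an epoch-based lattice, so grids of different animals
#' interpolated at the same interval are aligned).
#'
#' @param track the trajectory the model was fitted on
#' @param model a `movement_model`
#' @param interval_min grid interval in minutes (default 5)
#' @return a regular [trajectory()]
#' @export
interpolate <- function(track, model, interval_min = 5) {
  assert_that(interval_min > 0, "invalid_argument", "interval must be > 0")
  tn <- as.numeric(track$time)
  step <- interval_min * 60
  anchor <- floor(tn[1] / step) * step
  grid <- seq(anchor, tn[length(tn)], by = step)
  assert_that(length(grid) > 0, "insufficient_data", "empty interpolation grid")

  ev <- model$error_var
  if (model$family == "IID") {
    shr <- if (model$sigma2 + ev > 0) model$sigma2 / (model$sigma2 + ev) else 0
    gx <- rep(model$mu[1], length(grid))
    gy <- rep(model$mu[2], length(grid))
    hit <- match(round(grid * 1e3), round(tn * 1e3))
    obs <- !is.na(hit)
    gx[obs] <- model$mu[1] + shr * (track$x[hit[obs]] - model$mu[1])
    gy[obs] <- model$mu[2] + shr * (track$y[hit[obs]] - model$mu[2])
    return(trajectory(track$animal_id[1],
                      as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
                      gx, gy, regular = TRUE, interval_min = interval_min))
  }

  smooth_coord <- function(tu, obs_flag, yobs_full, mu0) {
    dt <- c(0, diff(tu)) / 60
    steps <- switch(model$family,
      OU  = ou_steps(dt, model$tau_p, model$sigma2),
      OUF = ouf_steps(dt, model$tau_p, model$tau_v, model$sigma2),
      IOU = iou_steps(dt, model$tau_v, model$sigma2, prior_pos_var = ev))
    Rt <- ifelse(obs_flag, ev, 0)
    y <- ifelse(obs_flag, yobs_full - mu0, 0)
    kalman_smooth(y, obs_flag, Rt, steps$Phi, steps$Q,
                  steps$condition_first)
  }

  if (model$family == "IOU") {
    # condition on the first fix: smooth from the first observation, then
    # back-extrapolate any earlier grid point linearly with the smoothed
    # initial velocity
    pre <- grid[grid < tn[1]]
    tu <- sort(unique(c(grid[grid >= tn[1]], tn)))
    key <- round(tu * 1e3)
    obs_flag <- key %in% round(tn * 1e3)
    yx <- track$x[match(key, round(tn * 1e3))]
    yy <- track$y[match(key, round(tn * 1e3))]
    msx <- smooth_coord(tu, obs_flag, ifelse(obs_flag, yx, 0), 0)
    msy <- smooth_coord(tu, obs_flag, ifelse(obs_flag, yy, 0), 0)
    gi <- match(round(grid[grid >= tn[1]] * 1e3), key)
    gx <- msx[gi, 1]; gy <- msy[gi, 1]
    if (length(pre)) {
      dmin <- (tn[1] - pre) / 60
      gx <- c(msx[1, 1] - dmin * msx[1, 2], gx)
      gy <- c(msy[1, 1] - dmin * msy[1, 2], gy)
    }
  } else {
    tu <- sort(unique(c(grid, tn)))
    key <- round(tu * 1e3)
    obs_flag <- key %in% round(tn * 1e3)
    idx <- match(key, round(tn * 1e3))
    yx <- ifelse(obs_flag, track$x[idx], 0)
    yy <- ifelse(obs_flag, track$y[idx], 0)
    msx <- smooth_coord(tu, obs_flag, yx, model$mu[1])
    msy <- smooth_coord(tu, obs_flag, yy, model$mu[2])
    gi <- match(round(grid * 1e3), key)
    gx <- msx[gi, 1] + model$mu[1]
    gy <- msy[gi, 1] + model$mu[2]
  }
  trajectory(track$animal_id[1],
             as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
             gx, gy, regular = TRUE, interval_min = interval_min)
}

#' Serialize a movement model to JSON
#' @param model a `movement_model`
#' @param path optional file path; if omitted the JSON string is returned
#' @export
movement_model_json <- function(model, path = NULL) {
  x <- unclass(model)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
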