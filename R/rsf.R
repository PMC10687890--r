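#' Used-available designs and resource selection functions
#'
#' The used-available design contrasts covariates at locations an animal
#' used against locations available to it via logistic regression; the
#' exponential of the linear predictor gives relative selection strength.
#' Used points are the interpolated fixes within the pair window;
#' available points are uniform draws inside the individual's 95%
#' kernel home range at a 30:1 ratio, each inheriting the date of its
#' paired used point so dynamic covariates keep the temporal distribution
#' of use. Continuous covariates are standardized (per-owner mean/SD,
#' stored for prediction); binary covariates are left on their natural
#' scale.
#'
#' @name rsf-design
NULL

is_continuous_covariate <- function(name, values) {
  if (name %in% CONTINUOUS_LAYERS) return(TRUE)
  if (name %in% BINARY_LAYERS) return(FALSE)
  length(unique(values)) > 2
}

standardize_design <- function(df, covariates) {
  std <- data.frame(covariate = character(), mean = numeric(),
                    sd = numeric())
  for (nm in covariates) {
    if (!is_continuous_covariate(nm, df[[nm]])) next
    m <- mean(df[[nm]]); s <- sd(df[[nm]])
    if (!is.finite(s) || s == 0) s <- 1
    df[[nm]] <- (df[[nm]] - m) / s
    std <- rbind(std, data.frame(covariate = nm, mean = m, sd = s))
  }
  list(df = df, standardizers = std)
}

apply_standardizers <- function(df, standardizers) {
  for (i in seq_len(nrow(standardizers))) {
    nm <- standardizers$covariate[i]
    df[[nm]] <- (df[[nm]] - standardizers$mean[i]) / standardizers$sd[i]
  }
  df
}

new_ua_dataset <- function(df, owner, standardizers, ratio, seed) {
  attr(df, "owner") <- owner
  attr(df, "standardizers") <- standardizers
  attr(df, "ratio") <- ratio
  attr(df, "seed") <- seed
  class(df) <- c("ua_dataset", "data.frame")
  df
}

dataset_covariates <- function(dataset)
  setdiff(names(dataset), c("label", "owner", "x", "y", "date"))

#' Build an individual-level used-available dataset
#'
#' @param itrack the individual's interpolated trajectory clipped to the
#'   pair window
#' @param hr95 the individual's `home_range` fitted on the same window
#'   (its 95% isopleth defines availability)
#' @param env an `env_stack`
#' @param ratio available points per used point (default 30)
#' @param seed seed for availability sampling
#' @param layers covariates to extract (default all)
#' @return a `ua_dataset`
#' @export
build_individual_dataset <- function(itrack, hr95, env, ratio = 30,
                                     seed = 1, layers = env$layers) {
  owner <- itrack$animal_id[1]
  n_used <- nrow(itrack)
  assert_that(n_used > 0, "insufficient_data", "no used points")
  region <- hr_region(hr95, 0.95)
  set.seed(seed)
  avail <- sample_region(region, ratio * n_used)
  used_dates <- as.Date(itrack$time, tz = "UTC")
  pts <- data.frame(
    label = c(rep(1L, n_used), rep(0L, ratio * n_used)),
    owner = owner,
    x = c(itrack$x, avail$x), y = c(itrack$y, avail$y),
    date = c(used_dates, rep(used_dates, ratio)))
  covs <- extract_covariates(pts, env, layers)
  std <- standardize_design(cbind(pts, covs), layers)
  new_ua_dataset(std$df, owner, std$standardizers, ratio, seed)
}

#' Iterative collinearity screen
#'
#' While any covariate pair has `|r| >= threshold` (Pearson, pooled
#' design), the lower-priority member of the worst pair is dropped.
#' Priority defaults to position in `priority_order` (earlier = kept).
#'
#' @param dataset a `ua_dataset` (or any data.frame of covariates)
#' @param threshold correlation threshold (default 0.6)
#' @param priority_order covariate names, highest priority first; default
#'   is the column order of the design
#' @return the retained covariate names, in priority order
#' @export
screen_collinearity <- function(dataset, threshold = 0.6,
                                priority_order = NULL) {
  covs <- if (inherits(dataset, "ua_dataset")) dataset_covariates(dataset)
    else names(dataset)
  assert_that(length(covs) >= 2, "invalid_argument",
              "need at least 2 covariates to screen")
  if (is.null(priority_order)) priority_order <- covs
  covs <- covs[order(match(covs, priority_order))]
  keep <- covs
  repeat {
    X <- as.matrix(as.data.frame(dataset)[keep])
    keep_var <- apply(X, 2, function(v) sd(v) > 0)
    keep <- keep[keep_var]
    if (length(keep) < 2) break
    R <- abs(cor(as.matrix(as.data.frame(dataset)[keep])))
    diag(R) <- 0
    if (max(R) < threshold) break
    worst <- which(R == max(R), arr.ind = TRUE)[1, ]
    drop <- keep[max(worst)]  # later in priority order drops first
    keep <- setdiff(keep, drop)
  }
  keep
}

# ridge-stabilized IRLS used when ML logistic regression separates
ridge_logistic <- function(X, yy, lambda = 1e-4, maxit = 100) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)  # intercept unpenalized
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (yy - mu) / w
    H <- crossprod(X, X * w) + pen
    beta_new <- solve(H, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X, X * w) + pen
  se <- sqrt(diag(solve(H)))
  ll <- sum(yy * eta - log1p(exp(eta)))
  list(coef = drop(beta), se = se, loglik = ll)
}

new_rsf_model <- function(owner, covariates, coef, se, loglik, n_used,
                          n_avail, converged, ridged) {
  k <- length(coef)
  structure(list(owner = owner, covariates = covariates, coef = coef,
                 se = se, loglik = loglik, k = k, aic = 2 * k - 2 * loglik,
                 n_used = n_used, n_avail = n_avail,
                 converged = converged, ridged = ridged),
            class = "rsf_model")
}

#' @export
print.rsf_model <- function(x, ...) {
  cat(sprintf("<rsf_model %s: %s; loglik %.2f, AIC %.2f%s>\n", x$owner,
              paste(x$covariates, collapse = " + "), x$loglik, x$aic,
              if (x$ridged) ", ridge-stabilized" else ""))
  invisible(x)
}

#' Fit a used-available logistic RSF
#'
#' Maximum-likelihood logistic regression of used (1) against available
#' (0). Complete separation (any `|beta| > 15` or non-convergence)
#' triggers a ridge-stabilized refit (L2 penalty, lambda = 1e-4) and the
#' model is flagged.
#'
#' @param dataset a `ua_dataset`
#' @param formula character vector of covariate names (the model
#'   structure); an intercept is always included
#' @return an `rsf_model`
#' @export
fit_rsf <- function(dataset, formula) {
  miss <- setdiff(formula, dataset_covariates(dataset))
  assert_that(length(miss) == 0, "invalid_argument",
              paste("covariates not in dataset:", paste(miss, collapse = ", ")))
  assert_that(all(c(0, 1) %in% dataset$label), "invalid_argument",
              "both used and available labels must be present")
  # length(formula) == 0 gives the intercept-only model
  X <- cbind("(Intercept)" = rep(1, nrow(dataset)),
             as.matrix(as.data.frame(dataset)[formula]))
  y <- dataset$label
  r <- logit_ml(X, y)
  if (r$bad) {
    r <- ridge_logistic(X, y)
    return(new_rsf_model(attr(dataset, "owner") %||% dataset$owner[1],
                         formula, setNames(r$coef, colnames(X)),
                         setNames(r$se, colnames(X)), r$loglik,
                         sum(y == 1), sum(y == 0),
                         converged = FALSE, ridged = TRUE))
  }
  new_rsf_model(attr(dataset, "owner") %||% dataset$owner[1], formula,
                setNames(r$coef, colnames(X)), setNames(r$se, colnames(X)),
                r$loglik, sum(y == 1), sum(y == 0),
                converged = TRUE, ridged = FALSE)
}

# direct ML logistic fit on a prebuilt model matrix (no model.frame
# overhead; used heavily by model selection and cross-validation)
logit_ml <- function(X, y, start = NULL) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), start = start))
  cf <- fit$coefficients
  eta <- fit$linear.predictors
  ll <- sum(y * eta - log1p(exp(eta)))
  bad <- !fit$converged || anyNA(cf) || any(abs(cf) > 15)
  se <- rep(NA_real_, length(cf))
  if (!bad) {
    info <- tryCatch(solve(crossprod(X * sqrt(fit$weights))),
                     error = function(e) NULL)
    if (is.null(info)) bad <- TRUE else se <- sqrt(diag(info))
  }
  list(coef = cf, se = se, loglik = ll, bad = bad)
}

#' Select a model structure by cumulative-log-likelihood AIC
#'
#' Each candidate structure is fitted to every owner's dataset; the
#' candidate score is `AIC = 2 k n_owners - 2 sum(logLik)` over owners.
#' Owners for which any candidate fails are dropped from all candidates
#' for fairness. Ties (Delta AIC < 1e-9) break toward fewer parameters.
#'
#' @param candidate_formulas named list of character vectors
#' @param datasets list of `ua_dataset`, one per owner
#' @return list with `formula` (winning structure), `name`, `table`
#'   (score table) and `fits` (per-owner fits of the winner)
#' @export
select_model <- function(candidate_formulas, datasets) {
  assert_that(length(candidate_formulas) >= 1, "invalid_argument",
              "empty candidate list")
  if (is.null(names(candidate_formulas)))
    names(candidate_formulas) <- paste0("m", seq_along(candidate_formulas))
  fits <- lapply(candidate_formulas, function(f)
    lapply(datasets, function(d)
      tryCatch(fit_rsf(d, f), crsf_error = function(e) NULL)))
  ok_owner <- Reduce(`&`, lapply(fits, function(fl)
    vapply(fl, Negate(is.null), TRUE)))
  assert_that(any(ok_owner), "fit_failure",
              "no owner fits every candidate structure")
  tab <- do.call(rbind, lapply(names(candidate_formulas), function(nm) {
    fl <- fits[[nm]][ok_owner]
    cum_ll <- sum(vapply(fl, `[[`, 0, "loglik"))
    k <- length(candidate_formulas[[nm]]) + 1L
    cum_k <- k * length(fl)
    data.frame(name = nm, k = k, n_owners = length(fl),
               cum_loglik = cum_ll, aic = 2 * cum_k - 2 * cum_ll)
  }))
  best <- min(tab$aic)
  tied <- which(tab$aic <= best + 1e-9)
  win <- tied[which.min(tab$k[tied])]
  list(formula = candidate_formulas[[tab$name[win]]],
       name = tab$name[win], table = tab,
       fits = fits[[tab$name[win]]][ok_owner])
}

#' Aggregate owner-level RSFs to a weighted population RSF
#'
#' Two-stage (Murtaugh) aggregation: owner i gets weight proportional to
#' `m_i * n_i` (m = times the owner appears in a unique contact pair,
#' n = the owner's used-point count), normalized to sum to 1. The
#' population coefficient is the weighted mean, its SE
#' `sqrt(sum(w_i^2 se_i^2))`, and the 95% CI the normal interval.
#'
#' @param models list of `rsf_model` sharing one formula
#' @param owner_pair_counts numeric m_i per model (default 1)
#' @param owner_sample_sizes numeric n_i per model (default the model's
#'   used-point count)
#' @return a `population_rsf`
#' @export
aggregate_population <- function(models, owner_pair_counts = NULL,
                                 owner_sample_sizes = NULL) {
  assert_that(length(models) >= 1, "invalid_argument", "no models")
  covs <- models[[1]]$covariates
  same <- all(vapply(models, function(m) identical(m$covariates, covs), TRUE))
  assert_that(same, "invalid_argument", "models have mismatched formulas")
  m_i <- owner_pair_counts %||% rep(1, length(models))
  n_i <- owner_sample_sizes %||% vapply(models, `[[`, 0, "n_used")
  w <- m_i * n_i
  assert_that(all(w > 0), "invalid_argument", "weights must be positive")
  w <- w / sum(w)
  terms <- names(models[[1]]$coef)
  B <- vapply(models, function(m) m$coef[terms], numeric(length(terms)))
  S <- vapply(models, function(m) m$se[terms], numeric(length(terms)))
  B <- matrix(B, nrow = length(terms)); S <- matrix(S, nrow = length(terms))
  beta <- drop(B %*% w)
  se <- sqrt(drop(S^2 %*% w^2))
  # weighted-mean containment invariant
  stopifnot(all(beta >= apply(B, 1, min) - 1e-12),
            all(beta <= apply(B, 1, max) + 1e-12))
  structure(list(terms = terms, covariates = covs,
                 beta = setNames(beta, terms), se = setNames(se, terms),
                 ci_lo = setNames(beta - 1.96 * se, terms),
                 ci_hi = setNames(beta + 1.96 * se, terms),
                 weights = w, n_owners = length(models),
                 owners = vapply(models, `[[`, "", "owner")),
            class = "population_rsf")
}

#' @export
print.population_rsf <- function(x, ...) {
  cat(sprintf("<population_rsf: %d owners>\n", x$n_owners))
  print(data.frame(term = x$terms, beta = round(x$beta, 4),
                   se = round(x$se, 4), ci_lo = round(x$ci_lo, 4),
                   ci_hi = round(x$ci_hi, 4), row.names = NULL))
  invisible(x)
}

#' Fivefold cross-validation with area-adjusted Spearman rank
#'
#' Used points are randomly partitioned into k folds (all available
#' points stay in every training set: the validation statistic is a
#' used-point frequency against a fixed availability baseline). Per fold,
#' the model refit on the training data scores the withheld used points
#' and all available points; scores (`exp` of the linear predictor) are
#' binned into `n_bins` equal-interval bins of the available-score range,
#' the area-adjusted frequency (withheld-used count / available count per
#' bin, zero-available bins dropped) is computed, and the Spearman rank
#' correlation of bin rank versus adjusted frequency is reported.
#'
#' @param dataset a `ua_dataset`
#' @param formula covariate names
#' @param k folds (default 5, withholding 20% of used points per fold)
#' @param n_bins score bins (default 10)
#' @param seed fold-assignment seed
#' @return a `cv_result` with per-fold and mean Spearman r_s
#' @export
crossvalidate <- function(dataset, formula, k = 5, n_bins = 10, seed = 1) {
  used_idx <- which(dataset$label == 1)
  avail_idx <- which(dataset$label == 0)
  assert_that(length(used_idx) >= k, "insufficient_data",
              "need at least k used points")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(used_idx)))
  rs <- numeric(k)
  X <- cbind(1, as.matrix(as.data.frame(dataset)[formula]))
  y <- dataset$label
  full <- logit_ml(X, y)  # warm start for the fold refits
  for (f in seq_len(k)) {
    test_u <- used_idx[fold == f]
    rows <- c(setdiff(used_idx, test_u), avail_idx)
    m <- logit_ml(X[rows, , drop = FALSE], y[rows],
                  start = if (full$bad) NULL else full$coef)
    if (m$bad) m <- ridge_logistic(X[rows, , drop = FALSE], y[rows])
    sc <- function(r) exp(drop(X[r, , drop = FALSE] %*% m$coef))
    s_av <- sc(avail_idx); s_te <- sc(test_u)
    rng <- range(s_av)
    if (diff(rng) == 0) crsf_stop("cv_degenerate", "constant score surface")
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin_of <- function(s) pmin(pmax(findInterval(s, br,
                                                 rightmost.closed = TRUE), 1),
                               n_bins)
    na <- tabulate(bin_of(s_av), n_bins)
    nu <- tabulate(bin_of(s_te), n_bins)
    keep <- na > 0
    if (sum(keep) < 2) crsf_stop("cv_degenerate", "fewer than 2 usable bins")
    adj <- nu[keep] / na[keep]
    rs[f] <- suppressWarnings(
      cor(seq_len(sum(keep)), adj, method = "spearman"))
    if (is.na(rs[f])) rs[f] <- 0  # constant adjusted frequency
  }
  structure(list(owner = attr(dataset, "owner"), fold_rs = rs,
                 mean_rs = mean(rs), k = k, n_bins = n_bins),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s: mean r_s %.3f (folds: %s)>\n", x$owner,
              x$mean_rs, paste(round(x$fold_rs, 3), collapse = ", ")))
  invisible(x)
}

#' Predict a relative selection surface on the landscape
#'
#' Per cell, `w = exp(beta . x_standardized)` (no intercept), linearly
#' rescaled to `[0, 1]` over the extent; a constant surface maps to 0.5
#' everywhere.
#'
#' @param pop a `population_rsf`
#' @param env an `env_stack`
#' @param date the day whose dynamic covariates to use
#' @param standardizers standardization table (covariate, mean, sd) to
#'   apply to continuous covariates; typically pooled from the
#'   contributing datasets
#' @return a matrix surface on the analysis grid
#' @export
predict_surface <- function(pop, env, date, standardizers = NULL) {
  g <- env$grid
  lp <- matrix(0, g$nrow, g$ncol)
  for (nm in pop$covariates) {
    assert_that(nm %in% env$layers, "missing_data",
                sprintf("covariate %s not in the stack", nm))
    lay <- if (nm %in% names(env$static)) env$static[[nm]] else
      layer_on_date(env, nm, date)
    if (length(lay) == 1) lay <- matrix(as.numeric(lay), g$nrow, g$ncol)
    if (!is.null(standardizers) && nm %in% standardizers$covariate) {
      i <- match(nm, standardizers$covariate)
      lay <- (lay - standardizers$mean[i]) / standardizers$sd[i]
    }
    lp <- lp + pop$beta[[nm]] * lay
  }
  w <- exp(lp)
  rng <- range(w)
  if (diff(rng) == 0) return(matrix(0.5, g$nrow, g$ncol))
  (w - rng[1]) / diff(rng)
}

#' Pool standardizers across datasets (weighted by design size)
#' @param datasets list of `ua_dataset`
#' @keywords internal
#' @export
pool_standardizers <- function(datasets) {
  tabs <- lapply(datasets, attr, "standardizers")
  all_cov <- unique(unlist(lapply(tabs, `[[`, "covariate")))
  out <- data.frame(covariate = all_cov, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(all_cov)) {
    ms <- vapply(tabs, function(t) {
      j <- match(all_cov[i], t$covariate); if (is.na(j)) NA else t$mean[j]
    }, 0)
    ss <- vapply(tabs, function(t) {
      j <- match(all_cov[i], t$covariate); if (is.na(j)) NA else t$sd[j]
    }, 0)
    out$mean[i] <- mean(ms, na.rm = TRUE)
    out$sd[i] <- mean(ss, na.rm = TRUE)
  }
  out
}
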