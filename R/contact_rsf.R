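#' Build a pair-level contact used-available dataset
#'
#' Used points are the pair's direct-contact locations (midpoints, with
#' the contact's own date). Candidate available points are the union of
#' both members' interpolated fixes that fall inside the dyad's
#' home-range overlap region at non-contact timestamps (a timestamp with
#' a contact removes both animals' fixes at that timestamp — those fixes
#' are the contact). When candidates exceed `ratio_cap` per used point a
#' seeded uniform subsample of exactly `ratio_cap * n_used` is drawn; the
#' cap is never an upsampling quota. Dynamic covariates for available
#' rows use the row's own fix date (these are real fixes with real
#' dates).
#'
#' @param pair_record a `pair_record` that passed [filter_pairs()]
#' @param contacts `contact_events` for the dyad
#' @param itracks list of the two members' interpolated trajectories
#' @param overlap_polygon the dyad's 95% overlap `grid_region`
#' @param env an `env_stack`
#' @param ratio_cap maximum available:used ratio (default 30)
#' @param seed subsampling seed
#' @param layers covariates to extract
#' @return a `ua_dataset` whose owner is the pair id
#' @export
build_contact_dataset <- function(pair_record, contacts, itracks,
                                  overlap_polygon, env, ratio_cap = 30,
                                  seed = 1, layers = env$layers) {
  assert_that(!region_is_empty(overlap_polygon), "degenerate_input",
              "empty home-range overlap")
  wins <- pair_record$analysis_windows
  in_windows <- function(t) {
    ok <- rep(FALSE, length(t))
    for (w in wins) ok <- ok | (t >= w[1] & t <= w[2])
    ok
  }
  cts <- contacts[in_windows(contacts$time), , drop = FALSE]
  # a contact midpoint beyond the mapped extent carries no covariates
  cts <- cts[!is.na(cell_index(env$grid, cts$x, cts$y)$row), , drop = FALSE]
  n_used <- nrow(cts)
  assert_that(n_used > 0, "degenerate_input", "no contacts in the window")
  contact_keys <- unique(round(as.numeric(cts$time) * 1e3))

  cand <- do.call(rbind, lapply(itracks, function(tr) {
    keep <- in_windows(tr$time) &
      !(round(as.numeric(tr$time) * 1e3) %in% contact_keys) &
      region_contains(overlap_polygon, tr$x, tr$y)
    data.frame(x = tr$x[keep], y = tr$y[keep],
               date = as.Date(tr$time[keep], tz = "UTC"))
  }))
  assert_that(nrow(cand) > 0, "degenerate_input",
              "no candidate available points inside the overlap")
  cap <- ratio_cap * n_used
  if (nrow(cand) > cap) {
    set.seed(seed)
    cand <- cand[sample(nrow(cand), cap), , drop = FALSE]
  }
  pair_id <- paste(pair_record$id_a, pair_record$id_b, sep = "|")
  pts <- data.frame(
    label = c(rep(1L, n_used), rep(0L, nrow(cand))),
    owner = pair_id,
    x = c(cts$x, cand$x), y = c(cts$y, cand$y),
    date = c(as.Date(cts$time, tz = "UTC"), cand$date))
  covs <- extract_covariates(pts, env, layers)
  std <- standardize_design(cbind(pts, covs), layers)
  new_ua_dataset(std$df, pair_id, std$standardizers, ratio_cap, seed)
}

#' Fit a pair-level contact RSF
#'
#' Logistic regression of contact versus non-contact locations using the
#' model structure selected for the individual-level RSF (the
#' individual model is the null reference the contact model is compared
#' against), with the same engine and separation handling as [fit_rsf()].
#'
#' @param dataset a contact `ua_dataset` from [build_contact_dataset()]
#' @param top_individual_formula covariate names of the top-selected
#'   individual model
#' @return an `rsf_model`
#' @export
fit_contact_rsf <- function(dataset, top_individual_formula) {
  assert_that(length(top_individual_formula) >= 1, "invalid_argument",
              "empty formula")
  fit_rsf(dataset, top_individual_formula)
}

#' Aggregate pair-level contact RSFs to a population RSF
#'
#' Same weighted-mean machinery as [aggregate_population()] with pair
#' weight proportional to the pair's contact count (sample size;
#' the unique-pair multiplicity is identically 1 at pair level).
#'
#' @param pair_models list of `rsf_model`, one per pair
#' @param pair_contact_counts contacts per pair (weights)
#' @return a `population_rsf`
#' @export
aggregate_contact_population <- function(pair_models, pair_contact_counts) {
  aggregate_population(pair_models,
                       owner_pair_counts = rep(1, length(pair_models)),
                       owner_sample_sizes = pair_contact_counts)
}

#' Compare population contact-RSF and individual-RSF
#'
#' Per-covariate coefficient differences (contact minus individual) with
#' joint 95% CIs (independence assumed, `SE = sqrt(SE_c^2 + SE_i^2)`),
#' per-covariate sign-agreement flags, and Spearman/Pearson correlations
#' of the two prediction surfaces over the shared extent. Each
#' coefficient is categorized `+` / `-` / `0` by whether its own 95% CI
#' excludes zero; the sign-agreement flag is TRUE when the categories
#' match, so a positive contact coefficient against a null individual one
#' is flagged discordant.
#'
#' @param pop_contact,pop_individual `population_rsf` objects sharing
#'   covariate names
#' @param env an `env_stack`
#' @param date day for the dynamic covariates of both surfaces
#' @param std_contact,std_individual standardizer tables for the two
#'   surfaces
#' @return a `comparison_report`
#' @export
compare_rsf <- function(pop_contact, pop_individual, env, date,
                        std_contact = NULL, std_individual = NULL) {
  assert_that(identical(sort(pop_contact$covariates),
                        sort(pop_individual$covariates)),
              "invalid_argument", "covariate names do not match")
  covs <- pop_contact$covariates
  cat3 <- function(pop, nm) {
    if (pop$ci_lo[[nm]] > 0) "+" else if (pop$ci_hi[[nm]] < 0) "-" else "0"
  }
  tab <- do.call(rbind, lapply(covs, function(nm) {
    d <- pop_contact$beta[[nm]] - pop_individual$beta[[nm]]
    sed <- sqrt(pop_contact$se[[nm]]^2 + pop_individual$se[[nm]]^2)
    sc <- cat3(pop_contact, nm); si <- cat3(pop_individual, nm)
    data.frame(covariate = nm,
               beta_contact = pop_contact$beta[[nm]],
               beta_individual = pop_individual$beta[[nm]],
               difference = d, se_difference = sed,
               diff_ci_lo = d - 1.96 * sed, diff_ci_hi = d + 1.96 * sed,
               sign_contact = sc, sign_individual = si,
               sign_agreement = sc == si)
  }))
  surf_c <- predict_surface(pop_contact, env, date, std_contact)
  surf_i <- predict_surface(pop_individual, env, date, std_individual)
  structure(list(
    table = tab,
    surface_spearman = suppressWarnings(
      cor(as.vector(surf_c), as.vector(surf_i), method = "spearman")),
    surface_pearson = suppressWarnings(
      cor(as.vector(surf_c), as.vector(surf_i))),
    surface_contact = surf_c, surface_individual = surf_i,
    all_signs_agree = all(tab$sign_agreement)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$table[c("covariate", "beta_contact", "beta_individual",
                  "difference", "sign_contact", "sign_individual",
                  "sign_agreement")], row.names = FALSE)
  cat(sprintf("surface correlation: Spearman %.3f, Pearson %.3f\n",
              x$surface_spearman, x$surface_pearson))
  invisible(x)
}

#' Serialize a comparison report to JSON
#' @param report a `comparison_report`
#' @param path output path
#' @export
comparison_report_json <- function(report, path) {
  out <- list(table = report$table,
              surface_spearman = report$surface_spearman,
              surface_pearson = report$surface_pearson,
              all_signs_agree = report$all_signs_agree)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
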