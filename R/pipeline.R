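#' Pipeline configuration
#'
#' Assembles and validates the run configuration with the method's
#' standard defaults: 5-min interpolation interval, 10-m contact buffer,
#' 30 available points per used point, 95%/50% isopleths, 0.6
#' collinearity threshold, 0.5 core-overlap threshold, >10-contact pair
#' filter, fivefold cross-validation with 10 score bins.
#'
#' @param out_dir artifact output directory
#' @param seed root seed; every stage draws from a named substream
#' @param tracks_csv,env_dir optional external inputs (otherwise the
#'   simulate stage generates them)
#' @param interval_min,buffer_m,ratio,isopleths,collinearity_threshold,overlap_threshold,min_contacts,cv_folds,cv_bins,core_isopleth,min_consecutive_weeks
#'   method parameters (defaults above)
#' @param candidates named list of candidate model structures (character
#'   vectors); default: single structure of all screened covariates
#' @param weights_mode individual-weight form, `"product"` (m_i * n_i)
#' @param predict_date day used for prediction surfaces (default: first
#'   day of the stack)
#' @param sim named list overriding simulation defaults (extent_m,
#'   cell_size_m, n_days, n_food_sites, n_groups, animals_per_group,
#'   tau_p_min, sigma_m2, fix_interval_min, attraction_coeffs,
#'   gps_error_sd, visits_per_day, visit_duration_min, dropout, sex)
#' @param log_level one of "quiet", "info"
#' @return a validated `run_config`
#' @export
run_config <- function(out_dir, seed = 1, tracks_csv = NULL, env_dir = NULL,
                       interval_min = 5, buffer_m = 10, ratio = 30,
                       isopleths = c(0.95, 0.50),
                       collinearity_threshold = 0.6,
                       overlap_threshold = 0.5, min_contacts = 10,
                       cv_folds = 5, cv_bins = 10, core_isopleth = 0.50,
                       min_consecutive_weeks = 12, candidates = NULL,
                       weights_mode = "product", predict_date = NULL,
                       sim = list(), log_level = "info") {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              tracks_csv = tracks_csv, env_dir = env_dir,
              interval_min = interval_min, buffer_m = buffer_m,
              ratio = ratio, isopleths = isopleths,
              collinearity_threshold = collinearity_threshold,
              overlap_threshold = overlap_threshold,
              min_contacts = min_contacts, cv_folds = cv_folds,
              cv_bins = cv_bins, core_isopleth = core_isopleth,
              min_consecutive_weeks = min_consecutive_weeks,
              candidates = candidates, weights_mode = weights_mode,
              predict_date = predict_date,
              sim = utils::modifyList(default_sim_params(), sim),
              log_level = log_level)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

default_sim_params <- function() {
  list(extent_m = 3000, cell_size_m = 30, n_days = 14, n_food_sites = 6,
       n_groups = 2, animals_per_group = 2, tau_p_min = 60,
       tau_v_min = 15, sigma_m2 = 1e4, fix_interval_min = 10,
       attraction_coeffs = c(food = log(3)), gps_error_sd = 5,
       visits_per_day = 2, visit_duration_min = c(30, 90),
       dropout = 0.02, sex = "F", group_spread = 0.30)
}

validate_config <- function(cfg) {
  chk <- function(ok, what)
    assert_that(isTRUE(ok), "invalid_argument",
                paste("invalid configuration:", what))
  chk(cfg$interval_min > 0, "interval_min must be positive")
  chk(cfg$buffer_m > 0, "buffer_m must be positive")
  chk(cfg$ratio > 0, "ratio must be positive")
  chk(all(cfg$isopleths > 0 & cfg$isopleths < 1), "isopleths in (0,1)")
  chk(cfg$collinearity_threshold > 0 && cfg$collinearity_threshold <= 1,
      "collinearity threshold in (0,1]")
  chk(cfg$overlap_threshold >= 0 && cfg$overlap_threshold <= 1,
      "overlap threshold in [0,1]")
  chk(cfg$min_contacts >= 0, "min_contacts must be non-negative")
  chk(cfg$cv_folds >= 2, "cv_folds must be >= 2")
  chk(cfg$cv_bins >= 2, "cv_bins must be >= 2")
  chk(is.character(cfg$out_dir) && nzchar(cfg$out_dir), "out_dir required")
  invisible(TRUE)
}

#' Read / write a run configuration as YAML (lossless round-trip)
#' @param cfg a `run_config`
#' @param path YAML path
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$isopleths <- as.list(x$isopleths)
  x$sim$attraction_coeffs <- as.list(x$sim$attraction_coeffs)
  x$sim$visit_duration_min <- as.list(x$sim$visit_duration_min)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$isopleths <- as.numeric(unlist(x$isopleths))
  sim <- x$sim
  sim$attraction_coeffs <- unlist(sim$attraction_coeffs)
  sim$visit_duration_min <- as.numeric(unlist(sim$visit_duration_min))
  args <- x[setdiff(names(x), "sim")]
  args$sim <- sim
  do.call(run_config, args)
}

plog <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[contactRSF] ", fmt), ...))
}

PIPELINE_STAGES <- c("simulate", "fit_ctmm", "interpolate", "detect",
                     "classify", "filter", "individual_rsf", "select",
                     "contact_rsf", "aggregate", "compare")

#' Run the contact-RSF pipeline
#'
#' Executes the full chain
#' simulate - fit-ctmm - interpolate - detect - classify - filter -
#' individual-RSF - select - contact-RSF - aggregate - compare,
#' writing every stage's artifacts under `out_dir` and a JSON manifest
#' listing each artifact with its stage, seed and content hash. Stages
#' can be re-run individually (`stages` argument); a stage whose inputs
#' are not in memory reloads them from the artifacts of the earlier
#' stages.
#'
#' @param config a `run_config`
#' @param stages subset of `PIPELINE_STAGES` to run, in order
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  validate_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[sort(match(stages, PIPELINE_STAGES))]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$cfg <- config
  manifest_path <- file.path(config$out_dir, "manifest.json")
  state$manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else list()
  for (st in stages) {
    plog(config, "stage %s", st)
    arts <- tryCatch(
      switch(st,
        simulate = stage_simulate(state),
        fit_ctmm = stage_fit_ctmm(state),
        interpolate = stage_interpolate(state),
        detect = stage_detect(state),
        classify = stage_classify(state),
        filter = stage_filter(state),
        individual_rsf = stage_individual_rsf(state),
        select = stage_select(state),
        contact_rsf = stage_contact_rsf(state),
        aggregate = stage_aggregate(state),
        compare = stage_compare(state)),
      crsf_error = function(e) {
        write_manifest(state)
        crsf_stop("stage_failure",
                  sprintf("stage %s failed: %s", st, conditionMessage(e)))
      })
    state$manifest[[st]] <- list(
      stage = st, seed = substream_seed(config$seed, st),
      artifacts = as.list(arts),
      hashes = as.list(unname(tools::md5sum(
        file.path(config$out_dir, unlist(arts))))))
    write_manifest(state)
  }
  invisible(state$manifest)
}

write_manifest <- function(state) {
  jsonlite::write_json(state$manifest,
                       file.path(state$cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

out_path <- function(state, ...) file.path(state$cfg$out_dir, ...)

# ---- stage implementations ----------------------------------------------

stage_simulate <- function(state) {
  cfg <- state$cfg
  if (!is.null(cfg$tracks_csv) && !is.null(cfg$env_dir)) {
    state$env <- read_env_stack(cfg$env_dir)
    state$tracks <- read_tracks(cfg$tracks_csv,
                                error_sd = cfg$sim$gps_error_sd)
    state$sexes <- setNames(rep_len(cfg$sim$sex, length(state$tracks)),
                            names(state$tracks))
    return(character(0))
  }
  sp <- cfg$sim
  env <- gen_landscape(sp$extent_m, sp$cell_size_m, sp$n_days,
                       sp$n_food_sites,
                       seed = substream_seed(cfg$seed, "landscape"))
  sim <- sim_population(env, n_groups = sp$n_groups,
                        animals_per_group = sp$animals_per_group,
                        tau_p_min = sp$tau_p_min, tau_v_min = sp$tau_v_min,
                        sigma_m2 = sp$sigma_m2,
                        fix_interval_min = sp$fix_interval_min,
                        n_days = sp$n_days,
                        attraction_coeffs = sp$attraction_coeffs,
                        seed = substream_seed(cfg$seed, "movement"),
                        gps_error_sd = sp$gps_error_sd,
                        visits_per_day = sp$visits_per_day,
                        visit_duration_min = sp$visit_duration_min,
                        dropout = sp$dropout, sex = sp$sex,
                        group_spread = sp$group_spread)
  state$truth <- sim$truth
  state$sexes <- sim$truth$sex
  write_env_stack(env, out_path(state, "env"))
  # reload from the artifact so in-memory and resumed runs are identical
  state$env <- read_env_stack(out_path(state, "env"))
  write_tracks(sim$tracks, out_path(state, "tracks.csv"))
  # reload from the artifact so in-memory and resumed runs are identical
  state$tracks <- read_tracks(out_path(state, "tracks.csv"),
                              error_sd = sp$gps_error_sd)
  jsonlite::write_json(
    list(groups = as.list(sim$truth$groups),
         sex = as.list(sim$truth$sex),
         seed = sim$truth$seed,
         n_visits = nrow(sim$truth$visits),
         n_truth_contacts = nrow(sim$truth$contacts)),
    out_path(state, "truth.json"), auto_unbox = TRUE, digits = NA)
  c("tracks.csv", "truth.json", "env/manifest.json")
}

need_inputs <- function(state) {
  cfg <- state$cfg
  if (is.null(state$env)) {
    dir <- if (!is.null(cfg$env_dir)) cfg$env_dir else out_path(state, "env")
    state$env <- read_env_stack(dir)
  }
  if (is.null(state$tracks)) {
    f <- if (!is.null(cfg$tracks_csv)) cfg$tracks_csv else
      out_path(state, "tracks.csv")
    state$tracks <- read_tracks(f, error_sd = cfg$sim$gps_error_sd)
  }
  if (is.null(state$sexes)) {
    tf <- out_path(state, "truth.json")
    state$sexes <- if (file.exists(tf))
      unlist(jsonlite::read_json(tf, simplifyVector = TRUE)$sex) else
      setNames(rep_len(cfg$sim$sex, length(state$tracks)),
               names(state$tracks))
  }
  invisible(state)
}

stage_fit_ctmm <- function(state) {
  need_inputs(state)
  dir.create(out_path(state, "models"), showWarnings = FALSE)
  state$models <- lapply(state$tracks, select_movement_model)
  arts <- character(0)
  for (id in names(state$models)) {
    f <- file.path("models", paste0(id, ".json"))
    movement_model_json(state$models[[id]], out_path(state, f))
    arts <- c(arts, f)
  }
  state$models <- NULL
  load_models(state)  # artifact round-trip keeps resumed runs identical
  arts
}

load_models <- function(state) {
  if (!is.null(state$models)) return()
  need_inputs(state)
  state$models <- lapply(names(state$tracks), function(id) {
    x <- jsonlite::read_json(out_path(state, "models", paste0(id, ".json")),
                             simplifyVector = TRUE)
    structure(lapply(x, function(v) if (is.null(v)) NA_real_ else v),
              class = "movement_model")
  })
  names(state$models) <- names(state$tracks)
}

stage_interpolate <- function(state) {
  need_inputs(state); load_models(state)
  state$itracks <- lapply(names(state$tracks), function(id)
    interpolate(state$tracks[[id]], state$models[[id]],
                state$cfg$interval_min))
  names(state$itracks) <- names(state$tracks)
  write_tracks(state$itracks, out_path(state, "itracks.csv"))
  state$itracks <- NULL
  load_itracks(state)  # artifact round-trip keeps resumed runs identical
  "itracks.csv"
}

load_itracks <- function(state) {
  if (!is.null(state$itracks)) return()
  need_inputs(state)
  trs <- read_tracks(out_path(state, "itracks.csv"))
  state$itracks <- lapply(trs, function(tr) {
    attr(tr, "regular") <- TRUE
    attr(tr, "interval_min") <- state$cfg$interval_min
    tr
  })
}

all_dyads <- function(ids) {
  ids <- sort(ids)
  if (length(ids) < 2) return(list())
  cmb <- utils::combn(ids, 2)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

stage_detect <- function(state) {
  load_itracks(state)
  cfg <- state$cfg
  evs <- list()
  for (dy in all_dyads(names(state$itracks))) {
    win <- temporal_intersection(state$itracks[[dy[1]]],
                                 state$itracks[[dy[2]]])
    if (is.null(win)) next
    a <- clip_track(state$itracks[[dy[1]]], win)
    b <- clip_track(state$itracks[[dy[2]]], win)
    if (is.null(a) || is.null(b)) next
    ev <- detect_contacts(a, b, cfg$buffer_m)
    if (nrow(ev)) evs[[paste(dy, collapse = "|")]] <- ev
  }
  all_ev <- if (length(evs)) do.call(rbind, evs) else
    data.frame(id_a = character(), id_b = character(),
               time = as.POSIXct(character(), tz = "UTC"),
               x = numeric(), y = numeric(), distance = numeric())
  class(all_ev) <- c("contact_events", "data.frame")
  write_contacts(all_ev, out_path(state, "contacts.csv"))
  load_contacts(state)
  "contacts.csv"
}

load_contacts <- function(state) {
  if (!is.null(state$contacts)) return()
  df <- read.csv(out_path(state, "contacts.csv"), stringsAsFactors = FALSE)
  df <- data.frame(id_a = df$pair_a, id_b = df$pair_b,
                   time = parse_utc(df$timestamp), x = df$x, y = df$y,
                   distance = df$distance_m)
  state$contacts <- split(df, paste(df$id_a, df$id_b, sep = "|"))
}

pair_contacts <- function(state, id_a, id_b) {
  key <- paste(sort(c(id_a, id_b)), collapse = "|")
  cts <- state$contacts[[key]]
  if (is.null(cts))
    cts <- data.frame(id_a = character(), id_b = character(),
                      time = as.POSIXct(character(), tz = "UTC"),
                      x = numeric(), y = numeric(), distance = numeric())
  cts
}

stage_classify <- function(state) {
  load_itracks(state); load_contacts(state)
  cfg <- state$cfg
  recs <- list()
  for (dy in all_dyads(names(state$itracks))) {
    win <- temporal_intersection(state$itracks[[dy[1]]],
                                 state$itracks[[dy[2]]])
    if (is.null(win)) next
    rec <- tryCatch(
      classify_pair(state$itracks[[dy[1]]], state$itracks[[dy[2]]],
                    sexes = unname(state$sexes[dy]), grid = state$env$grid,
                    core_isopleth = cfg$core_isopleth,
                    overlap_threshold = cfg$overlap_threshold,
                    min_consecutive_weeks = cfg$min_consecutive_weeks,
                    contacts = pair_contacts(state, dy[1], dy[2])),
      insufficient_data = function(e) NULL)
    if (!is.null(rec)) recs[[paste(dy, collapse = "|")]] <- rec
  }
  write_pair_records(recs, out_path(state, "pairs.jsonl"))
  load_pair_records(state)
  "pairs.jsonl"
}

load_pair_records <- function(state, file = "pairs.jsonl",
                              slot = "pair_records") {
  if (!is.null(state[[slot]])) return()
  lines <- readLines(out_path(state, file))
  recs <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    x$window <- parse_utc(x$window)
    x$analysis_windows <- lapply(x$analysis_windows, parse_utc)
    x$n_contacts <- x$n_contacts %||% NA_integer_
    class(x) <- "pair_record"
    x
  })
  names(recs) <- vapply(recs, function(r)
    paste(r$id_a, r$id_b, sep = "|"), "")
  state[[slot]] <- recs
}

stage_filter <- function(state) {
  load_pair_records(state)
  keep <- filter_pairs(state$pair_records, state$cfg$min_contacts)
  names(keep) <- vapply(keep, function(r)
    paste(r$id_a, r$id_b, sep = "|"), "")
  write_pair_records(keep, out_path(state, "pairs_included.jsonl"))
  load_pair_records(state, "pairs_included.jsonl", "included_pairs")
  "pairs_included.jsonl"
}

# clip a member's interpolated track to a pair's analysis windows
clip_to_windows <- function(track, windows) {
  keep <- rep(FALSE, nrow(track))
  for (w in windows) keep <- keep | (track$time >= w[1] & track$time <= w[2])
  out <- track[keep, , drop = FALSE]
  attributes(out)[c("error_sd", "regular", "interval_min")] <-
    attributes(track)[c("error_sd", "regular", "interval_min")]
  class(out) <- class(track)
  out
}

stage_individual_rsf <- function(state) {
  load_itracks(state)
  load_pair_records(state, "pairs_included.jsonl", "included_pairs")
  cfg <- state$cfg
  # one design per individual: its pair-window subsamples stacked, with
  # availability drawn per pair window from the window-specific 95% range
  member_rows <- list()
  state$hr_cache <- list()
  state$pair_member_count <- list()
  for (key in names(state$included_pairs)) {
    rec <- state$included_pairs[[key]]
    for (id in c(rec$id_a, rec$id_b)) {
      sub <- clip_to_windows(state$itracks[[id]], rec$analysis_windows)
      # fixes beyond the mapped extent carry no covariates
      sub <- sub[!is.na(cell_index(state$env$grid, sub$x, sub$y)$row), ,
                 drop = FALSE]
      if (nrow(sub) < 30) next
      hr <- kde_homerange(sub[, c("x", "y")], state$env$grid,
                          isopleth_levels = cfg$isopleths, animal_id = id)
      state$hr_cache[[paste(key, id, sep = ":")]] <- hr
      ds <- build_individual_dataset(
        sub, hr, state$env, ratio = cfg$ratio,
        seed = substream_seed(cfg$seed, paste0("avail:", key, ":", id)))
      member_rows[[paste(key, id, sep = ":")]] <- as.data.frame(ds)
      state$pair_member_count[[id]] <-
        (state$pair_member_count[[id]] %||% 0) + 1
    }
  }
  assert_that(length(member_rows) > 0, "insufficient_data",
              "no pair-member datasets could be built")
  owners <- unique(vapply(strsplit(names(member_rows), ":"), `[`, "", 2))
  state$ind_datasets <- lapply(owners, function(id) {
    rows <- do.call(rbind,
                    member_rows[grepl(paste0(":", id, "$"), names(member_rows))])
    covs <- setdiff(names(rows), c("label", "owner", "x", "y", "date"))
    # restandardize continuous covariates on the stacked design
    raw <- rows
    std <- standardize_design(raw, covs)
    new_ua_dataset(std$df, id, std$standardizers, cfg$ratio,
                   substream_seed(cfg$seed, paste0("design:", id)))
  })
  names(state$ind_datasets) <- owners
  big <- do.call(rbind, lapply(state$ind_datasets, as.data.frame))
  data.table::fwrite(big, out_path(state, "individual_datasets.csv"))
  "individual_datasets.csv"
}

stage_select <- function(state) {
  if (is.null(state$ind_datasets)) stage_individual_rsf(state)
  cfg <- state$cfg
  pooled <- do.call(rbind, lapply(state$ind_datasets, as.data.frame))
  covs <- setdiff(names(pooled), c("label", "owner", "x", "y", "date"))
  retained <- screen_collinearity(pooled[covs],
                                  threshold = cfg$collinearity_threshold)
  cands <- cfg$candidates %||% list(screened = retained)
  cands <- lapply(cands, function(f) intersect(f, retained))
  cands <- cands[vapply(cands, length, 0L) > 0]
  sel <- select_model(cands, state$ind_datasets)
  state$selection <- sel
  state$retained <- retained
  cv <- lapply(names(state$ind_datasets), function(id)
    tryCatch(crossvalidate(state$ind_datasets[[id]], sel$formula,
                           k = cfg$cv_folds, n_bins = cfg$cv_bins,
                           seed = substream_seed(cfg$seed,
                                                 paste0("cv:", id))),
             crsf_error = function(e) NULL))
  state$cv <- cv
  jsonlite::write_json(
    list(retained = retained, top = sel$name,
         formula = sel$formula, table = sel$table,
         cv_mean_rs = vapply(cv, function(x)
           if (is.null(x)) NA_real_ else x$mean_rs, 0)),
    out_path(state, "model_selection.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows", na = "null")
  "model_selection.json"
}

stage_contact_rsf <- function(state) {
  if (is.null(state$selection)) stage_select(state)
  load_contacts(state)
  cfg <- state$cfg
  state$contact_models <- list()
  state$contact_datasets <- list()
  for (key in names(state$included_pairs)) {
    rec <- state$included_pairs[[key]]
    hra <- state$hr_cache[[paste(key, rec$id_a, sep = ":")]]
    hrb <- state$hr_cache[[paste(key, rec$id_b, sep = ":")]]
    if (is.null(hra) || is.null(hrb)) next
    ov <- overlap_region(hra, hrb, 0.95)
    ds <- tryCatch(build_contact_dataset(
      rec, pair_contacts(state, rec$id_a, rec$id_b),
      itracks = list(clip_to_windows(state$itracks[[rec$id_a]],
                                     rec$analysis_windows),
                     clip_to_windows(state$itracks[[rec$id_b]],
                                     rec$analysis_windows)),
      overlap_polygon = ov, env = state$env, ratio_cap = cfg$ratio,
      seed = substream_seed(cfg$seed, paste0("contact:", key))),
      degenerate_input = function(e) NULL)
    if (is.null(ds)) next
    m <- fit_contact_rsf(ds, state$selection$formula)
    state$contact_models[[key]] <- m
    state$contact_datasets[[key]] <- ds
  }
  assert_that(length(state$contact_models) > 0, "insufficient_data",
              "no pair supported a contact-RSF fit")
  jsonlite::write_json(
    lapply(state$contact_models, function(m)
      list(owner = m$owner, coef = as.list(m$coef), se = as.list(m$se),
           loglik = m$loglik, aic = m$aic, n_used = m$n_used,
           n_avail = m$n_avail, ridged = m$ridged)),
    out_path(state, "contact_models.json"), auto_unbox = TRUE, digits = NA)
  "contact_models.json"
}

stage_aggregate <- function(state) {
  if (is.null(state$contact_models)) stage_contact_rsf(state)
  cfg <- state$cfg
  # individual side: one model per owner, Murtaugh weights m_i * n_i
  # (the per-owner fits of the winning structure from the select stage)
  ind_models <- state$selection$fits
  m_i <- vapply(names(ind_models), function(id)
    as.numeric(state$pair_member_count[[id]] %||% 1), 0)
  state$pop_individual <- aggregate_population(
    ind_models, owner_pair_counts = m_i,
    owner_sample_sizes = vapply(ind_models, `[[`, 0, "n_used"))
  counts <- vapply(state$contact_models, `[[`, 0, "n_used")
  state$pop_contact <- aggregate_contact_population(
    unname(state$contact_models), unname(counts))
  pj <- function(pop) list(terms = pop$terms, beta = as.list(pop$beta),
                           se = as.list(pop$se), ci_lo = as.list(pop$ci_lo),
                           ci_hi = as.list(pop$ci_hi),
                           weights = pop$weights, owners = pop$owners)
  jsonlite::write_json(pj(state$pop_individual),
                       out_path(state, "population_individual.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(pj(state$pop_contact),
                       out_path(state, "population_contact.json"),
                       auto_unbox = TRUE, digits = NA)
  c("population_individual.json", "population_contact.json")
}

stage_compare <- function(state) {
  if (is.null(state$pop_contact)) stage_aggregate(state)
  cfg <- state$cfg
  date <- cfg$predict_date %||% as.character(state$env$dates[1])
  rep <- compare_rsf(state$pop_contact, state$pop_individual, state$env,
                     as.Date(date),
                     std_contact = pool_standardizers(state$contact_datasets),
                     std_individual = pool_standardizers(state$ind_datasets))
  state$comparison <- rep
  comparison_report_json(rep, out_path(state, "comparison.json"))
  write_asc(rep$surface_contact, state$env$grid,
            out_path(state, "surface_contact.asc"))
  write_asc(rep$surface_individual, state$env$grid,
            out_path(state, "surface_individual.asc"))
  c("comparison.json", "surface_contact.asc", "surface_individual.asc")
}
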