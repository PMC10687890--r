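#' Ground-truth dissociation scenario: contact drivers decoupled from
#' individual space use
#'
#' Builds a world in which the landscape driver of contact is known to
#' differ from the drivers of individual space use — the headline pattern
#' the contact-RSF framework is designed to detect. Two social groups
#' with heavily overlapping ranges move as plain OU processes with no
#' resource steering, so individual selection for the artificial-food
#' covariate is null by construction; the food layer is a regular
#' provisioning lattice (one bait cell every `food_spacing` cells in each
#' direction, emulating grid-deployed baiting). A regular lattice is
#' spatially balanced: any smooth utilization density samples it at its
#' areal fraction, so individual use of food matches its availability.
#' Between-group contact events are
#' then drawn from the dyad's visited locations inside the shared range
#' with odds multiplied by `odds` on food cells: given presence, contact
#' preferentially happens at food, although movement ignores it.
#'
#' With `odds = 1` contacts fall uniformly over visited locations and
#' both models are null for food (the negative control).
#'
#' @param seed integer seed
#' @param odds contact odds multiplier on food cells (default 3)
#' @param n_days simulated days (default 14)
#' @param n_contacts_per_pair contact events drawn per dyad (default 120)
#' @param food_spacing lattice spacing of bait cells in cells (default 2:
#'   one bait cell per 2x2 block, areal fraction 0.25)
#' @param extent_m landscape side (default 2700 m)
#' @param tau_p_min OU timescale; the default 5 min makes 10-min fixes
#'   nearly independent so logistic standard errors are calibrated
#' @param sigma_m2 OU spatial variance; the default 4e4 m^2 makes the
#'   home range span many lattice periods, so the availability mask's
#'   bait-cell fraction is close to the areal fraction (small isopleth
#'   boundary imbalance)
#' @return list: `env`, `itracks` (regular tracks used directly as the
#'   interpolation grid), `records` (between-group `pair_record`s),
#'   `contacts` (named list of `contact_events` per pair),
#'   `home_ranges` (per pair-member KDE ranges), `overlaps` (per pair),
#'   `truth` (scenario parameters)
#' @export
scenario_dissociation <- function(seed = 1, odds = 3, n_days = 14,
                                  n_contacts_per_pair = 120,
                                  food_spacing = 2, extent_m = 2700,
                                  tau_p_min = 5, sigma_m2 = 4e4) {
  env <- gen_landscape(extent_m, 30, n_days = n_days, n_food_sites = 0,
                       seed = substream_seed(seed, "scenario-landscape"))
  g <- env$grid
  food_mat <- matrix(0, g$nrow, g$ncol)
  food_mat[seq(1, g$nrow, by = food_spacing),
           seq(1, g$ncol, by = food_spacing)] <- 1
  env$dynamic$food <- rep(list(food_mat), length(env$dates))

  sim <- sim_population(
    env, n_groups = 2, animals_per_group = 2, tau_p_min = tau_p_min,
    sigma_m2 = sigma_m2, fix_interval_min = 10, n_days = n_days,
    attraction_coeffs = c(food = 0), visits_per_day = 0, dropout = 0,
    gps_error_sd = 5, group_spread = 0.08, sex = "F",
    seed = substream_seed(seed, "scenario-movement"))

  # fixes are a regular 10-min grid (no dropout): use them directly as the
  # interpolated tracks so the scenario isolates the RSF stages; the rare
  # fix beyond the mapped extent is discarded (covariates are undefined
  # there)
  itracks <- lapply(sim$tracks, function(tr) {
    ok <- !is.na(cell_index(g, tr$x, tr$y)$row)
    trajectory(tr$animal_id[1], tr$time[ok], tr$x[ok], tr$y[ok],
               regular = TRUE, interval_min = 10)
  })

  ids <- names(itracks)
  grp <- sim$truth$groups
  dyads <- Filter(function(d) grp[[d[1]]] != grp[[d[2]]], {
    cmb <- utils::combn(sort(ids), 2)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  })

  records <- list(); contacts <- list(); hrs <- list(); ovs <- list()
  set.seed(substream_seed(seed, "scenario-contacts"))
  for (dy in dyads) {
    key <- paste(dy, collapse = "|")
    win <- temporal_intersection(itracks[[dy[1]]], itracks[[dy[2]]])
    rec <- new_pair_record(dy, "FF", "between", win, weekly = NULL,
                           analysis_windows = list(win))
    hra <- kde_homerange(itracks[[dy[1]]][, c("x", "y")], g,
                         c(0.95, 0.5), animal_id = dy[1])
    hrb <- kde_homerange(itracks[[dy[2]]][, c("x", "y")], g,
                         c(0.95, 0.5), animal_id = dy[2])
    ov <- overlap_region(hra, hrb, 0.95)
    pool <- do.call(rbind, lapply(dy, function(id) {
      tr <- itracks[[id]]
      keep <- region_contains(ov, tr$x, tr$y)
      data.frame(time = tr$time[keep], x = tr$x[keep], y = tr$y[keep])
    }))
    pool <- pool[!duplicated(round(as.numeric(pool$time))), , drop = FALSE]
    fv <- extract_covariates(
      data.frame(x = pool$x, y = pool$y,
                 date = as.Date(pool$time, tz = "UTC")), env, "food")$food
    n_ev <- min(n_contacts_per_pair, nrow(pool))
    pick <- sample(nrow(pool), n_ev, prob = odds^fv)
    ev <- data.frame(id_a = dy[1], id_b = dy[2],
                     time = pool$time[pick], x = pool$x[pick],
                     y = pool$y[pick], distance = 0)
    ev <- ev[order(ev$time), ]
    rownames(ev) <- NULL
    class(ev) <- c("contact_events", "data.frame")
    rec$n_contacts <- nrow(ev)
    records[[key]] <- rec
    contacts[[key]] <- ev
    hrs[[paste(key, dy[1], sep = ":")]] <- hra
    hrs[[paste(key, dy[2], sep = ":")]] <- hrb
    ovs[[key]] <- ov
  }
  list(env = env, itracks = itracks, records = records,
       contacts = contacts, home_ranges = hrs, overlaps = ovs,
       truth = list(seed = seed, odds = odds, food_spacing = food_spacing,
                    groups = grp))
}

#' Run the RSF stages of the dissociation scenario
#'
#' Builds the individual and contact used-available designs with the
#' package machinery, fits a fixed model structure, and aggregates to the
#' two population RSFs (Murtaugh weights: individual m_i x n_i, pair
#' n_contacts).
#'
#' @param scn output of [scenario_dissociation()]
#' @param formula model structure (default `c("food", "tree_canopy")`)
#' @param ratio available:used ratio (default 30)
#' @return list with `pop_individual`, `pop_contact`, per-owner and
#'   per-pair models
#' @export
scenario_fit <- function(scn, formula = c("food", "tree_canopy"),
                         ratio = 30) {
  seed <- scn$truth$seed
  ids <- names(scn$itracks)
  # one design per individual over its (identical) pair windows
  ind_models <- list(); m_i <- c(); n_i <- c()
  for (id in ids) {
    keys <- names(scn$records)[vapply(scn$records, function(r)
      id %in% c(r$id_a, r$id_b), TRUE)]
    if (!length(keys)) next
    hr <- scn$home_ranges[[paste(keys[1], id, sep = ":")]]
    ds <- build_individual_dataset(
      scn$itracks[[id]], hr, scn$env, ratio = ratio,
      seed = substream_seed(seed, paste0("scn-avail:", id)),
      layers = formula)
    ind_models[[id]] <- fit_rsf(ds, formula)
    m_i <- c(m_i, length(keys)); n_i <- c(n_i, ind_models[[id]]$n_used)
  }
  pop_ind <- aggregate_population(unname(ind_models),
                                  owner_pair_counts = m_i,
                                  owner_sample_sizes = n_i)
  pair_models <- list(); counts <- c()
  for (key in names(scn$records)) {
    rec <- scn$records[[key]]
    ds <- build_contact_dataset(
      rec, scn$contacts[[key]],
      itracks = scn$itracks[c(rec$id_a, rec$id_b)],
      overlap_polygon = scn$overlaps[[key]], env = scn$env,
      ratio_cap = ratio,
      seed = substream_seed(seed, paste0("scn-contact:", key)),
      layers = formula)
    pair_models[[key]] <- fit_contact_rsf(ds, formula)
    counts <- c(counts, rec$n_contacts)
  }
  pop_con <- aggregate_contact_population(unname(pair_models), counts)
  list(pop_individual = pop_ind, pop_contact = pop_con,
       individual_models = ind_models, pair_models = pair_models)
}
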