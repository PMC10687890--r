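# Reduced pipeline fixture: 4 animals in 2 groups, 10 days (two ISO
# weeks), 1.2 km landscape. Small enough that a full run stays in the
# test budget while exercising every stage.
fixture_config <- function(dir, seed = 9) {
  run_config(out_dir = dir, seed = seed, log_level = "quiet",
             sim = list(extent_m = 1200, n_days = 10, n_food_sites = 4,
                        visits_per_day = 2))
}

manifest_hashes <- function(man)
  unlist(lapply(man, function(s) unname(unlist(s$hashes))))
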