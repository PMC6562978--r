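# Fixtures built in code: tiny observation frames, a one-zone landscape,
# and a scaled-down multi-zone config for pipeline-level tests.

mk_ind <- function(x, y, id = seq_along(x), session = 1L, zone = "HB",
                   demo_class = "MA", in_pouch = 0L, disturbed = 0L,
                   mother_id = NA_character_) {
  n <- length(x)
  data.frame(session = rep_len(session, n), id = as.character(id),
             x_m = x, y_m = y,
             zone = rep_len(zone, n), demo_class = rep_len(demo_class, n),
             in_pouch = rep_len(in_pouch, n),
             disturbed = rep_len(disturbed, n),
             mother_id = rep_len(mother_id, n),
             stringsAsFactors = FALSE)
}

# One rectangular cleared zone of 17.1 ha inside forest.
one_zone_landscape <- function() {
  cfg <- simulation_config(profiles = list(
    disturbance_profile("HB", cleared_area = 17.1, density_mean = 100)),
    seed = 1)
  generate_landscape(cfg)
}

# Small but fully featured survey config for pipeline tests.
small_cfg <- function(seed = 5, n_sessions = 3, chains = c(15, 30)) {
  base <- c(LA = 0.24, MA = 0.36, SA = 0.13, SUB = 0.10, YAF = 0.05, PY = 0.12)
  hb <- c(LA = 0.15, MA = 0.21, SA = 0.21, SUB = 0.11, YAF = 0.20, PY = 0.12)
  simulation_config(
    profiles = list(
      disturbance_profile("HB", 17.1, 180, 0.31, demographic_mix = hb,
                          greenness_mean = 0.3576),
      disturbance_profile("LB", 40, 75, 0.23, demographic_mix = base),
      disturbance_profile("LH", 30, 70, 0, demographic_mix = base),
      disturbance_profile("HH", 25, 40, 0, demographic_mix = base)),
    n_sessions = n_sessions, seed = seed, chain_distances = chains)
}

expect_same_partition <- function(a, b) {
  expect_identical(match(a, unique(a)), match(b, unique(b)))
}
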