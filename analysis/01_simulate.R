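#!/usr/bin/env Rscript
# Stage 1: generate the synthetic survey that stands in for the field data.
# Four disturbance zones (HB/LB/LH/HH), six crepuscular sessions, planted
# density ordering, group-size/cover slopes, demographic mixes and
# greenness. Writes the landscape (GeoJSON), the observation table and the
# planted group truth under results/data/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages(library(mobspace))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = seed)
sv <- generate_survey(cfg)

write_landscape_geojson(sv$landscape, "results/data/landscape.geojson")
write_observations_csv(sv$observations, "results/data/observations.csv")
write.csv(sv$groups, "results/data/planted_groups.csv", row.names = FALSE)
yaml::write_yaml(list(seed = seed, n_sessions = cfg$n_sessions,
                      chains = cfg$chain_distances),
                 "results/data/run_config.yaml")

v <- validate_observations(sv$observations, sv$landscape)
stopifnot(nrow(v) == 0)

cat(sprintf("Simulated %d individuals in %d planted groups over %d sessions (seed %d).\n",
            nrow(sv$observations), nrow(sv$groups), cfg$n_sessions, seed))
print(table(zone = sv$observations$zone, session = sv$observations$session))
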