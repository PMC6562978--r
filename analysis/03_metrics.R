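#!/usr/bin/env Rscript
# Stage 3: landscape and demography metrics. Grazing density per zone and
# session, zone-level demographic composition at each chain rule, and the
# positioning of vulnerable individuals (mothers, young-at-foot, pouch
# young) relative to their group centre and forested cover.

suppressMessages(library(mobspace))
obs <- read_observations_csv("results/data/observations.csv")
landscape <- read_landscape_geojson("results/data/landscape.geojson")

dens <- grazing_density(obs, landscape)
write.csv(dens, "results/density.csv", row.names = FALSE)
cat("Mean grazing density (individuals per km^2 of cleared habitat):\n")
print(aggregate(density_km2 ~ zone, dens, mean), digits = 4)

comps <- survey_compositions(obs, landscape, chains = c(15, 30, 50))
write.csv(comps, "results/compositions.csv", row.names = FALSE)
mc <- mean_composition(comps)
write.csv(mc, "results/composition_means.csv", row.names = FALSE)
cat("\nYoung-at-foot share by zone (15 m chain):\n")
print(mc[mc$demo_class == "YAF" & mc$chain_m == 15, ], digits = 3)

recs <- classify_positioning(obs, landscape, chain = 15)
write.csv(recs, "results/positioning.csv", row.names = FALSE)
pp <- positioning_proportions(recs)
write.csv(pp, "results/positioning_proportions.csv", row.names = FALSE)
cat("\nFront proportion by 20 m distance bracket (pooled zones):\n")
pool <- aggregate(cbind(front = pp$prop_front * pp$n, n = pp$n),
                  by = list(bracket = pp$bracket), FUN = sum)
pool$prop_front <- round(pool$front / pool$n, 3)
print(pool[, c("bracket", "n", "prop_front")])
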