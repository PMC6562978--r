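#!/usr/bin/env Rscript
# Stage 5: figures. (A) log grazing density by disturbance; (B) group-size
# distributions by zone and chain rule; (C) log clusteredness by zone and
# chain; (D) front proportion against distance bracket; (E) log group size
# against log distance to cover with the fitted NB slopes.

suppressMessages({library(mobspace); library(ggplot2)})
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

dens <- read.csv("results/density.csv")
groups <- read.csv("results/groups.csv")
pp <- read.csv("results/positioning_proportions.csv")
zlev <- c("HB", "LB", "LH", "HH")
zcol <- c(HB = "#1b7837", LB = "#a6dba0", LH = "#92c5de", HH = "#2166ac")
thm <- theme_minimal(base_size = 11)

p <- ggplot(dens[dens$density_km2 > 0, ],
            aes(factor(zone, zlev), log(density_km2), fill = zone)) +
  geom_boxplot(show.legend = FALSE) + scale_fill_manual(values = zcol) +
  labs(x = "Human disturbance", y = "log grazing density (per km2)") + thm
ggsave("results/figures/density.png", p, width = 5, height = 4, dpi = 150)

p <- ggplot(groups, aes(factor(zone, zlev), log(size), fill = zone)) +
  geom_violin(show.legend = FALSE) + facet_wrap(~chain_m) +
  scale_fill_manual(values = zcol) +
  labs(x = "Human disturbance", y = "log group size") + thm
ggsave("results/figures/group_size.png", p, width = 8, height = 4, dpi = 150)

p <- ggplot(groups[!is.na(groups$mean_nn_m), ],
            aes(factor(zone, zlev), log(mean_nn_m), fill = zone)) +
  geom_boxplot(show.legend = FALSE) + facet_wrap(~chain_m) +
  scale_fill_manual(values = zcol) +
  labs(x = "Human disturbance", y = "log mean NN distance (m)") + thm
ggsave("results/figures/clusteredness.png", p, width = 8, height = 4, dpi = 150)

p <- ggplot(pp, aes(bracket + 10, prop_front, colour = zone)) +
  geom_point(aes(size = n), alpha = 0.7) +
  geom_smooth(aes(weight = n), method = "glm",
              method.args = list(family = "binomial"), se = FALSE,
              linewidth = 0.6) +
  scale_colour_manual(values = zcol) +
  labs(x = "Group distance from cover (m, bracket midpoint)",
       y = "Proportion of vulnerable individuals in front") + thm
ggsave("results/figures/positioning.png", p, width = 6, height = 4, dpi = 150)

p <- ggplot(groups, aes(log(pmax(gdc, 1)), log(size), colour = zone)) +
  geom_point(alpha = 0.3, size = 0.8) +
  geom_smooth(method = "lm", se = FALSE, linewidth = 0.7) +
  facet_wrap(~chain_m) + scale_colour_manual(values = zcol) +
  labs(x = "log distance to cover (m)", y = "log group size") + thm
ggsave("results/figures/size_vs_cover.png", p, width = 9, height = 4, dpi = 150)

cat("Wrote 5 figures under results/figures/\n")
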