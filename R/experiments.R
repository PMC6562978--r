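# Validation experiments: published-summary arithmetic, oracle equivalence
# of the chain rule, parameter recovery for the NB cover model, type-I
# calibration of every test, and planted-effect recovery on full synthetic
# surveys. Shared by the test suite and scripts/acceptance.R.

#' Arithmetic checks on the published survey summaries
#'
#' Recomputes, from the bundled table of published summary numbers, the
#' mean number of undisturbed individuals per session and the greenness
#' difference between the greenest and next-greenest disturbance types.
#'
#' @return List with `mean_undisturbed_per_session` and
#'   `greenness_diff_hb_hh` (percentage points).
#' @export
reported_arithmetic <- function() {
  path <- system.file("extdata", "reported_survey_totals.csv",
                      package = "mobspace", mustWork = TRUE)
  v <- utils::read.csv(path)
  g <- function(k) v$value[v$quantity == k]
  list(
    mean_undisturbed_per_session = (g("total_recorded") - g("disturbed")) /
      g("n_sessions"),
    greenness_diff_hb_hh = g("greenness_pct_HB") - g("greenness_pct_HH")
  )
}

#' Oracle equivalence and nesting of the chain-rule partition
#'
#' Compares [assign_groups()] against the independent brute-force
#' components ([chain_components_bruteforce()]) on random point sets at
#' 15/30/50 m, and checks that partitions nest as the threshold grows.
#'
#' @param n_instances Number of random instances.
#' @param max_points Maximum points per instance.
#' @param chains Thresholds tested (m).
#' @param seed RNG seed.
#' @return List: `n_instances`, `n_mismatch`, `n_nesting_violations`.
#' @export
experiment_chain_oracle <- function(n_instances = 100, max_points = 500,
                                    chains = c(15, 30, 50), seed = 1) {
  set.seed(seed)
  mism <- 0L; nest_bad <- 0L
  same_partition <- function(a, b)
    identical(match(a, unique(a)), match(b, unique(b)))
  for (i in seq_len(n_instances)) {
    n <- sample(5:max_points, 1)
    side <- stats::runif(1, 100, 1200)  # varied point density
    xy <- cbind(stats::runif(n, 0, side), stats::runif(n, 0, side))
    ind <- data.frame(id = seq_len(n), session = 1L,
                      x_m = xy[, 1], y_m = xy[, 2], in_pouch = 0L)
    prev <- NULL
    for (ch in sort(chains)) {
      part <- assign_groups(ind, ch)
      lab <- part$assignment$group[match(ind$id, part$assignment$id)]
      if (!same_partition(lab, chain_components_bruteforce(xy, ch)))
        mism <- mism + 1L
      if (!is.null(prev)) {
        # every finer group must lie inside one coarser group
        if (any(tapply(lab, prev, function(v) length(unique(v))) > 1))
          nest_bad <- nest_bad + 1L
      }
      prev <- lab
    }
  }
  list(n_instances = n_instances, n_mismatch = mism,
       n_nesting_violations = nest_bad)
}

# Distinct base seeds get non-overlapping replicate seed windows (kept
# well inside 32-bit integer range).
.rep_seed_base <- function(seed) (as.integer(seed) * 100003L) %% 1500000000L

#' Parameter recovery for the NB group-size/cover model
#'
#' Simulates replicate surveys with planted per-zone slopes of log group
#' size on log distance-to-cover (default: HB 0.5, LB 0.25, LH 0, HH 0),
#' fits [groupsize_cover_glmm()] to each, and reports how often the HB
#' slope is detected (CI excludes 0), the LH slope CI covers 0, and each
#' zone's CI covers its planted slope.
#'
#' @param n_reps Number of replicate surveys.
#' @param seed Base seed (replicate r uses `seed + r`).
#' @param groups_per_zone Planted groups per zone across the survey.
#' @param betas Named per-zone slopes.
#' @return List with `hb_detect_rate`, `lh_cover_rate`, `coverage` (named
#'   by zone), `n_reps`, `mean_groups_per_zone`.
#' @export
experiment_nb_recovery <- function(n_reps = 100, seed = 1,
                                   groups_per_zone = 300,
                                   betas = c(HB = 0.5, LB = 0.25,
                                             LH = 0, HH = 0)) {
  n_sessions <- 6
  gps <- groups_per_zone / n_sessions
  area_ha <- 150; area_km2 <- area_ha / 100
  profs <- lapply(names(betas), function(z) {
    p <- disturbance_profile(z, cleared_area = area_ha, density_mean = 1,
                             cover_slope_beta = betas[[z]])
    p$density_mean <- gps * p$mean_group_size *
      (1 - p$demographic_mix["PY"]) / area_km2
    p
  })
  names(profs) <- names(betas)
  hb_det <- logical(n_reps); lh_cov <- logical(n_reps)
  covr <- matrix(NA, n_reps, length(betas), dimnames = list(NULL, names(betas)))
  ngrp <- numeric(n_reps)
  base <- .rep_seed_base(seed)
  for (r in seq_len(n_reps)) {
    cfg <- simulation_config(profiles = profs, n_sessions = n_sessions,
                             seed = base + r)
    sv <- generate_survey(cfg)
    fit <- groupsize_cover_glmm(sv$groups)
    co <- fit$coef
    ngrp[r] <- nrow(sv$groups) / length(betas)
    for (z in names(betas)) {
      row <- co[co$term == paste0("zone", z, ":logd"), ]
      covr[r, z] <- row$lower <= betas[[z]] && betas[[z]] <= row$upper
      if (z == "HB") hb_det[r] <- row$detected
      if (z == "LH") lh_cov[r] <- !row$detected
    }
  }
  list(hb_detect_rate = mean(hb_det), lh_cover_rate = mean(lh_cov),
       coverage = colMeans(covr), n_reps = n_reps,
       mean_groups_per_zone = mean(ngrp))
}

#' Type-I error calibration of the inferential layer
#'
#' Simulates each test's own null and reports rejection rates at alpha =
#' 0.05: the moment tests on N(0,1) samples (n = 200); the one-way
#' ANOVA F test and the Tukey HSD family on equal log-normal densities
#' (4 zones x 6 sessions); and the zone likelihood-ratio test of each
#' mixed-model structure on null data of 4 zones x 6 sessions x 10 groups
#' with a real session effect (SD 0.1) but no zone effect.
#'
#' @param n_reps Replicates per test (>= 500 for a stable rate).
#' @param seed RNG seed.
#' @param alpha Nominal level.
#' @return Named list of rejection rates: `skewness`, `kurtosis`, `anova`,
#'   `tukey_family`, `lmm_groupsize`, `lmm_clusteredness`,
#'   `lmm_demography`, `lmm_greenness`.
#' @export
experiment_type1 <- function(n_reps = 500, seed = 1, alpha = 0.05) {
  set.seed(seed)
  zones <- .ZONES
  rej <- list(skewness = 0, kurtosis = 0, anova = 0, tukey_family = 0,
              lmm_groupsize = 0, lmm_clusteredness = 0,
              lmm_demography = 0, lmm_greenness = 0)
  null_groups <- function() {
    d <- expand.grid(zone = zones, session = 1:6, g = 1:10)
    eff <- stats::rnorm(6, 0, 0.1)
    d$y <- eff[d$session] + stats::rnorm(nrow(d))
    d$size_f <- factor(sample(1:8, nrow(d), replace = TRUE))
    d$session <- factor(d$session)
    d
  }
  for (r in seq_len(n_reps)) {
    rej$skewness <- rej$skewness +
      (dagostino_skewness(stats::rnorm(200))$p.value < alpha)
    rej$kurtosis <- rej$kurtosis +
      (anscombe_kurtosis(stats::rnorm(200))$p.value < alpha)
    dens <- expand.grid(zone = zones, session = 1:6)
    dens$density_km2 <- stats::rlnorm(nrow(dens))
    fa <- density_anova(dens)
    rej$anova <- rej$anova + (fa$anova$p < alpha)
    rej$tukey_family <- rej$tukey_family + any(fa$contrasts$p_adj < alpha)
    d <- null_groups()
    rej$lmm_groupsize <- rej$lmm_groupsize +
      (.lmm_lrt_zone(y ~ zone + (1 | session), d) < alpha)
    rej$lmm_clusteredness <- rej$lmm_clusteredness +
      (.lmm_lrt_zone(y ~ zone + (1 | session) + (1 | size_f), d) < alpha)
    d2 <- null_groups()
    d2$y <- pmin(pmax(0.3 + 0.1 * d2$y, 0), 1)  # proportion-like response
    rej$lmm_demography <- rej$lmm_demography +
      (.lmm_lrt_zone(y ~ zone + (1 | session) + (1 | size_f), d2) < alpha)
    d3 <- null_groups()
    d3$y <- 0.34 + 0.01 * d3$y
    rej$lmm_greenness <- rej$lmm_greenness +
      (.lmm_lrt_zone(y ~ zone + (1 | session), d3) < alpha)
  }
  lapply(rej, function(v) v / n_reps)
}

#' Planted-effect recovery on full synthetic surveys
#'
#' Generates replicate surveys under the default profiles (density ordered
#' HB > LB ~ LH > HH, elevated young-at-foot share at HB, edge bias
#' decaying with distance) and reports how often the full pipeline finds:
#' a significant HB-HH Tukey contrast on log density; a significant HB-HH
#' contrast on the young-at-foot proportion (15 m chain); and a declining
#' front proportion across 20 m distance brackets (negative Spearman rank
#' correlation, pooled over zones).
#'
#' @param n_reps Number of replicate surveys.
#' @param seed Base seed.
#' @return List of rates: `density_hb_hh`, `yaf_hb_hh`, `front_decline`,
#'   plus `n_reps`.
#' @export
experiment_planted_effects <- function(n_reps = 50, seed = 1) {
  dens_hit <- yaf_hit <- trend_hit <- logical(n_reps)
  base <- .rep_seed_base(seed)
  for (r in seq_len(n_reps)) {
    cfg <- simulation_config(seed = base + r)
    sv <- generate_survey(cfg)
    dens <- grazing_density(sv$observations, sv$landscape)
    fa <- suppressWarnings(density_anova(dens))
    p_hbhh <- fa$contrasts$p_adj[grepl("HB", fa$contrasts$contrast) &
                                   grepl("HH", fa$contrasts$contrast)]
    dens_hit[r] <- length(p_hbhh) == 1 && p_hbhh < 0.05
    comp <- survey_compositions(sv$observations, sv$landscape, chains = 15)
    fy <- demography_lmm(comp, "YAF")
    py <- fy$contrasts$p_adj[grepl("HB", fy$contrasts$contrast) &
                               grepl("HH", fy$contrasts$contrast)]
    est <- fy$contrasts$estimate[grepl("HB", fy$contrasts$contrast) &
                                   grepl("HH", fy$contrasts$contrast)]
    yaf_hit[r] <- length(py) == 1 && py < 0.05 && est > 0
    recs <- classify_positioning(sv$observations, sv$landscape, chain = 15)
    pp <- positioning_proportions(recs)
    pooled <- stats::aggregate(cbind(front = pp$prop_front * pp$n, n = pp$n),
                               by = list(bracket = pp$bracket), FUN = sum)
    pooled <- pooled[pooled$n >= 5, ]
    trend_hit[r] <- nrow(pooled) >= 5 &&
      stats::cor(pooled$bracket, pooled$front / pooled$n,
                 method = "spearman") < 0
  }
  list(density_hb_hh = mean(dens_hit), yaf_hb_hh = mean(yaf_hit),
       front_decline = mean(trend_hit), n_reps = n_reps)
}
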