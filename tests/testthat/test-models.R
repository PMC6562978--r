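# Statistical layer: ANOVA, LMMs, NB mixed model, GAM, greenness models.

test_that("density ANOVA reproduces a hand-computed two-group F", {
  # log densities {1,2,3} vs {4,5,6}: F = MSB/MSW = 13.5/1 = 13.5
  d <- data.frame(zone = rep(c("HB", "LB"), each = 3), session = rep(1:3, 2),
                  density_km2 = exp(1:6))
  fit <- density_anova(d)
  expect_equal(fit$anova$F, 13.5, tolerance = 1e-9)
  expect_equal(fit$anova$df1, 1)
  expect_equal(fit$anova$df2, 4)
  # with two groups Tukey HSD equals the F-test p (ptukey quadrature)
  expect_equal(fit$contrasts$p_adj, fit$anova$p, tolerance = 1e-4)
})

test_that("identical densities give F = 0 and all pairwise p = 1", {
  d <- expand.grid(zone = c("HB", "LB", "LH", "HH"), session = 1:6)
  d$density_km2 <- 50
  fit <- density_anova(d)
  expect_equal(fit$anova$F, 0)
  expect_equal(fit$anova$p, 1)
  expect_true(all(fit$contrasts$p_adj == 1))
  expect_equal(nrow(fit$contrasts), 6)
})

test_that("density ANOVA handles zero cells and rejects degenerate designs", {
  d <- expand.grid(zone = c("HB", "LB"), session = 1:3)
  d$density_km2 <- rep(0, 6)
  expect_error(density_anova(d), "all densities")
  # one empty zone-session is dropped (not surveyed), with a warning
  d$density_km2 <- c(0, 1, 2, 3, 4, 5)
  expect_warning(fit <- density_anova(d), "dropped")
  expect_equal(fit$nobs, 5)
  # a zone left with fewer than two positive cells cannot be compared
  d2 <- expand.grid(zone = c("HB", "LB"), session = 1:3)
  d2$density_km2 <- c(0, 1, 0, 2, 1, 3)
  expect_error(suppressWarnings(density_anova(d2)), "too few")
  expect_error(density_anova(data.frame(zone = "HB", session = 1:3,
                                        density_km2 = 1:3)), ">= 2 zones")
})

test_that("the group-size LMM reduces to OLS with one observation per cell", {
  set.seed(41)
  d <- expand.grid(zone = c("HB", "LB", "LH", "HH"), session = 1:6)
  d$chain_m <- 15
  d$size <- rpois(nrow(d), 8) + 1
  fit <- groupsize_lmm(d)
  ols <- lm(log(size) ~ zone, data = transform(
    d, zone = factor(zone, levels = c("HB", "LB", "LH", "HH"))))
  expect_equal(unname(lme4::fixef(fit$extra$model)), unname(coef(ols)),
               tolerance = 1e-6)
  expect_lte(fit$sigma_session, 1e-3)  # boundary fit, flagged via sigma
  expect_equal(nrow(fit$contrasts), 6)
})

test_that("Tukey-adjusted contrast p-values are never below unadjusted ones", {
  sv <- generate_survey(small_cfg(seed = 42))
  parts <- survey_partitions(sv$observations, sv$landscape, chains = 15)
  fit <- clusteredness_lmm(parts)
  emm <- emmeans::emmeans(fit$extra$model, "zone", lmer.df = "satterthwaite")
  p_tuk <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))$p.value
  p_non <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))$p.value
  expect_true(all(p_tuk >= p_non - 1e-12))
  # CI invariant for coefficient tables
  nb <- groupsize_cover_glmm(sv$groups)
  expect_true(all(nb$coef$lower <= nb$coef$estimate + 1e-9))
  expect_true(all(nb$coef$estimate <= nb$coef$upper + 1e-9))
})

test_that("single-zone inputs give an LRT p of 1", {
  sv <- generate_survey(simulation_config(profiles = list(
    disturbance_profile("LB", 60, 90)), seed = 43, n_sessions = 4))
  parts <- survey_partitions(sv$observations, sv$landscape, chains = 15)
  fit <- clusteredness_lmm(parts)
  expect_equal(fit$lrt_p, 1)
})

test_that("the NB mixed model without random effect matches a plain NB GLM", {
  sv <- generate_survey(small_cfg(seed = 44, n_sessions = 6))
  g <- sv$groups
  fit <- groupsize_cover_glmm(g, random_effect = FALSE)
  g$zone <- factor(g$zone, levels = c("HB", "LB", "LH", "HH"))
  g$logd <- log(pmax(g$gdc, 1))
  oracle <- MASS::glm.nb(size ~ zone + zone:logd, data = g)
  est <- fit$coef$estimate
  names(est) <- fit$coef$term
  expect_equal(est[names(coef(oracle))], coef(oracle), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(fit$extra$theta, oracle$theta, tolerance = 1e-3)
})

test_that("a session effect planted at zero is estimated at the boundary", {
  sv <- generate_survey(small_cfg(seed = 45))
  fit <- groupsize_cover_glmm(sv$groups)
  expect_lte(fit$sigma_session, 1e-3)
})

test_that("demography LMM flags the planted young-at-foot excess direction", {
  sv <- generate_survey(small_cfg(seed = 46, n_sessions = 6))
  comp <- survey_compositions(sv$observations, sv$landscape, chains = 15)
  fit <- demography_lmm(comp, "YAF")
  hb_rows <- grepl("HB -", fit$contrasts$contrast)
  expect_true(all(fit$contrasts$estimate[hb_rows] > 0))
  expect_error(demography_lmm(comp, "ZZ"))
})

test_that("positioning GAM finds a planted zone offset and monotone decay", {
  set.seed(47)
  n <- 500
  mk <- function(zone, off) {
    gdc <- runif(n, 0, 200)
    p <- plogis(1.2 - 0.015 * gdc + off)
    data.frame(zone = zone, gdc = gdc,
               side = ifelse(rbinom(n, 1, p) == 1, "front", "behind"))
  }
  recs <- rbind(mk("HB", -1.2), mk("LB", 0), mk("LH", 0), mk("HH", 0))
  fit <- positioning_gam(recs)
  hb_rows <- grepl("HB", fit$contrasts$contrast)
  expect_true(all(fit$contrasts$p[hb_rows] < 0.05))
  expect_gte(nrow(fit$contrasts), 6)
  # predicted front probability declines with distance in every zone
  grid <- expand.grid(zone = c("HB", "LB", "LH", "HH"),
                      gdc = seq(5, 195, by = 10))
  pr <- predict(fit$extra$model, newdata = grid, type = "response")
  for (z in unique(grid$zone)) {
    pz <- pr[grid$zone == z]
    expect_lt(cor(grid$gdc[grid$zone == z], pz, method = "spearman"), 0)
  }
})

test_that("the GAM smooth stays near one effective df under a flat null", {
  set.seed(48)
  hits <- 0
  for (r in 1:20) {
    gdc <- runif(400, 0, 200)
    recs <- data.frame(zone = sample(c("HB", "LB"), 400, TRUE), gdc = gdc,
                       side = ifelse(rbinom(400, 1, 0.6) == 1,
                                     "front", "behind"))
    fit <- positioning_gam(recs)
    hits <- hits + (fit$extra$edf <= 1.5)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("greenness models detect planted zone differences, not size links", {
  covers <- matrix(NA, 8, 4)
  green_hit <- logical(8)
  for (r in 1:8) {
    # study-scale zones: the greenness gap is small, so the contrast needs
    # the full default group counts to be reliably detectable
    sv <- generate_survey(simulation_config(seed = 100 + r))
    fits <- greenness_models(sv$groups)
    ctr <- fits$greenness$contrasts
    hb <- grepl("HB -", ctr$contrast)
    green_hit[r] <- all(ctr$p_adj[hb] < 0.05) &&
      all(ctr$estimate[hb] > 0)
    slope_rows <- grepl(":greenness", fits$size_vs_greenness$coef$term)
    covers[r, ] <- !fits$size_vs_greenness$coef$detected[slope_rows]
  }
  # HB is planted greener than every other zone
  expect_gte(mean(green_hit), 0.9)
  # no greenness -> size effect is planted, so slope CIs should cover zero
  expect_gte(mean(covers), 0.9)
})
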