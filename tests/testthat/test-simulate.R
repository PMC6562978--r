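# Synthetic survey generator: determinism, planted structure, greenness
# patches, and parameter recovery at the single-fit level.

test_that("surveys are bit-identical under a fixed seed and differ across seeds", {
  s1 <- generate_survey(small_cfg(seed = 31))
  s2 <- generate_survey(small_cfg(seed = 31))
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$groups, s2$groups)
  s3 <- generate_survey(small_cfg(seed = 32))
  expect_false(identical(s1$observations, s3$observations))
})

test_that("a survey has the configured number of sessions", {
  sv <- generate_survey(small_cfg(seed = 33, n_sessions = 6))
  expect_setequal(unique(sv$observations$session), 1:6)
})

test_that("a degenerate demographic mix yields only that class", {
  cfg <- simulation_config(profiles = list(
    disturbance_profile("LB", 50, 80,
                        demographic_mix = c(1, 0, 0, 0, 0, 0))),
    seed = 34, n_sessions = 2)
  sv <- generate_survey(cfg)
  expect_true(all(sv$observations$demo_class == "LA"))
})

test_that("pouch young ride with an adult mother at her coordinates", {
  sv <- generate_survey(small_cfg(seed = 35))
  obs <- sv$observations
  py <- obs[obs$demo_class == "PY", ]
  expect_true(all(py$in_pouch == 1L))
  expect_true(all(!is.na(py$mother_id)))
  mrow <- match(py$mother_id, obs$id)
  expect_true(all(obs$demo_class[mrow] %in% c("LA", "MA", "SA")))
  expect_equal(py$x_m, obs$x_m[mrow])
  expect_equal(py$y_m, obs$y_m[mrow])
})

test_that("the 15 m chain rule recovers the planted partition exactly", {
  sv <- generate_survey(small_cfg(seed = 36))
  for (s in unique(sv$observations$session)) {
    obs_s <- sv$observations[sv$observations$session == s, ]
    p <- assign_groups(obs_s, 15)
    lab <- p$assignment$group[match(obs_s$id, p$assignment$id)]
    expect_same_partition(lab, match(obs_s$grp, unique(obs_s$grp)))
  }
})

test_that("realized densities are calibrated to the profile means", {
  profs <- lapply(list(c("HB", 0.31), c("LB", 0.23), c("LH", 0), c("HH", 0)),
                  function(v) disturbance_profile(v[1], cleared_area = 150,
                                                  density_mean = 100,
                                                  cover_slope_beta = as.numeric(v[2])))
  cfg <- simulation_config(profiles = profs, n_sessions = 200, seed = 37)
  sv <- generate_survey(cfg)
  dens <- grazing_density(sv$observations, sv$landscape)
  m <- tapply(dens$density_km2, dens$zone, mean)
  expect_true(all(abs(m / 100 - 1) < 0.05))
})

test_that("a flat planted slope leaves log size uncorrelated with log distance", {
  # Poisson limit: enormous NB dispersion, beta = 0
  prof <- disturbance_profile("LB", cleared_area = 200, density_mean = 200,
                              cover_slope_beta = 0,
                              groupsize_dispersion = 1e8)
  cfg <- simulation_config(profiles = list(prof), n_sessions = 25, seed = 38)
  sv <- generate_survey(cfg)
  g <- sv$groups
  expect_gt(nrow(g), 500)
  ct <- cor.test(log(g$size), log(pmax(g$gdc, 1)))
  expect_gt(ct$p.value, 0.01)
})

test_that("a planted slope of 0.5 is recovered within the fit's own CI", {
  prof <- disturbance_profile("LB", cleared_area = 200, density_mean = 200,
                              cover_slope_beta = 0.5)
  cfg <- simulation_config(profiles = list(prof), n_sessions = 20, seed = 39)
  sv <- generate_survey(cfg)
  expect_gt(nrow(sv$groups), 400)
  fit <- groupsize_cover_glmm(sv$groups)
  sl <- fit$coef[fit$coef$term == "logd", ]
  expect_true(sl$lower <= 0.5 && 0.5 <= sl$upper)
})

test_that("greenness patches hit their target mean", {
  # quantisation only
  p <- simulate_greenness_patch(0.3576, noise_sd = 0, size = 400)
  expect_lt(abs(greenness(p) - 0.3576), 1 / 255)
  # equal channels at 1/3
  p3 <- simulate_greenness_patch(1 / 3, noise_sd = 0, size = 16)
  expect_true(all(p3[, , 1] == p3[, , 2] & p3[, , 2] == p3[, , 3]))
  # CLT bound with noise
  p4 <- simulate_greenness_patch(0.5, noise_sd = 0.02, size = 1e4, seed = 8)
  expect_lt(abs(greenness(p4) - 0.5), 0.01)
  expect_error(simulate_greenness_patch(1.2, 0, 10), "mean_greenness")
  expect_error(simulate_greenness_patch(0.5, 0, 0), "size")
  # all channel values are valid 8-bit
  expect_true(all(p4 >= 0 & p4 <= 255))
})

test_that("patches survive a PNG round trip", {
  p <- simulate_greenness_patch(0.41, noise_sd = 0.01, size = 64^2, seed = 9)
  f <- tempfile(fileext = ".png")
  write_patch_png(p, f)
  p2 <- read_patch_png(f)
  expect_equal(unclass(p2), unclass(p), ignore_attr = TRUE)
  expect_equal(greenness(p2), greenness(p), tolerance = 1e-12)
  unlink(f)
})

test_that("sessions reject zones without a profile", {
  ls <- generate_landscape(small_cfg(seed = 40))
  cfg_missing <- small_cfg(seed = 40)
  cfg_missing$profiles$HB <- NULL
  expect_error(simulate_session(ls, cfg_missing, 1), "no profile")
})
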