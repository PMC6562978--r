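# Positioning, density and greenness metrics.

# A group on the horizontal midline of the one-zone rectangle: the nearest
# forest edge is the left wall, so IDC/GDC are just x offsets.
.posit_fixture <- function(xs, classes, in_pouch = NULL, mother = NULL) {
  ls <- one_zone_landscape()
  r <- ls$polygons$HB
  x0 <- min(r[, 1]); ymid <- mean(range(r[, 2]))
  n <- length(xs)
  ind <- mk_ind(x = x0 + xs, y = rep(ymid, n), id = as.character(seq_len(n)),
                demo_class = classes,
                in_pouch = if (is.null(in_pouch)) rep(0L, n) else in_pouch,
                mother_id = if (is.null(mother)) rep(NA_character_, n) else mother)
  list(landscape = ls, ind = ind)
}

test_that("positioning sign convention: front = closer to the edge", {
  # mother at 10 m, two others at 40 m: GDC 30, IDC 10 -> delta +20, front
  fx <- .posit_fixture(c(10, 40, 40), c("MA", "LA", "YAF"),
                       mother = c(NA, NA, "1"))
  rec <- classify_positioning(fx$ind, fx$landscape, chain = 100)
  m <- rec[rec$id == "1", ]
  expect_equal(m$delta, 20)
  expect_equal(m$side, "front")
  expect_equal(m$gdc, 30)
  # mother at 30 m, two others at 0 m: GDC 10, IDC 30 -> delta -20, behind
  fx2 <- .posit_fixture(c(30, 0, 0), c("MA", "LA", "YAF"),
                        mother = c(NA, NA, "1"))
  rec2 <- classify_positioning(fx2$ind, fx2$landscape, chain = 100)
  m2 <- rec2[rec2$id == "1", ]
  expect_equal(m2$delta, -20)
  expect_equal(m2$side, "behind")
})

test_that("exact ties are conservatively assigned behind", {
  # mother at 20 with a pouch joey; other member at 20 too -> IDC = GDC
  fx <- .posit_fixture(c(20, 20, 20), c("MA", "LA", "PY"),
                       in_pouch = c(0L, 0L, 1L), mother = c(NA, NA, "1"))
  rec <- classify_positioning(fx$ind, fx$landscape, chain = 100)
  expect_true(all(rec$delta == 0))
  expect_true(all(rec$side == "behind"))
})

test_that("groups without vulnerable members yield no records", {
  fx <- .posit_fixture(c(10, 20), c("MA", "LA"))
  rec <- classify_positioning(fx$ind, fx$landscape, chain = 100)
  expect_equal(nrow(rec), 0)
})

test_that("reflecting a group about its centre flips every non-tied side", {
  fx <- .posit_fixture(c(10, 25, 40, 55), c("MA", "YAF", "YAF", "LA"),
                       mother = c(NA, "1", "1", NA))
  rec <- classify_positioning(fx$ind, fx$landscape, chain = 100)
  ctr_x <- mean(fx$ind$x_m)
  ind2 <- fx$ind
  ind2$x_m <- 2 * ctr_x - ind2$x_m   # mirror along the cover gradient
  rec2 <- classify_positioning(ind2, fx$landscape, chain = 100)
  both <- merge(rec, rec2, by = "id")
  nt <- both[both$delta.x != 0, ]
  expect_true(all(nt$side.x != nt$side.y))
})

test_that("front proportions aggregate correctly by bracket", {
  rec <- data.frame(zone = "HB", gdc = c(30, 30, 30, 30),
                    side = c("front", "front", "front", "behind"))
  pp <- positioning_proportions(rec)
  expect_equal(pp$prop_front, 0.75)
  expect_equal(pp$bracket, 20)   # [20, 40) bin
  rec$side <- "front"
  expect_equal(positioning_proportions(rec)$prop_front, 1)
})

test_that("grazing density is count over cleared km^2 and conserves totals", {
  ls <- one_zone_landscape()
  r <- ls$polygons$HB
  ctr <- colMeans(r)
  ind <- mk_ind(x = ctr[1] + seq_len(12), y = rep(ctr[2], 12))
  d <- grazing_density(ind, ls)
  expect_equal(d$density_km2, 12 / 0.171, tolerance = 1e-12)
  expect_equal(round(d$density_km2, 2), 70.18)
  # doubling counts doubles density
  ind2 <- rbind(ind, mk_ind(x = ctr[1] - seq_len(12), y = rep(ctr[2], 12),
                            id = paste0("b", 1:12)))
  expect_equal(grazing_density(ind2, ls)$density_km2, 2 * d$density_km2)
  # conservation over a synthetic survey: sum(density * area) = count
  sv <- generate_survey(small_cfg(seed = 23))
  dens <- grazing_density(sv$observations, sv$landscape)
  areas <- sv$landscape$zones
  dens$area_km2 <- areas$area_ha[match(dens$zone, areas$zone)] / 100
  for (s in unique(dens$session)) {
    ds <- dens[dens$session == s, ]
    expect_equal(sum(ds$density_km2 * ds$area_km2),
                 sum(sv$observations$session == s &
                       sv$observations$in_pouch == 0))
  }
  # an empty zone has density zero
  only_hb <- sv$observations[sv$observations$zone == "HB", ]
  d0 <- grazing_density(only_hb, sv$landscape)
  expect_true(all(d0$density_km2[d0$zone == "LH"] == 0))
})

test_that("greenness equals the green share of total brightness", {
  grey <- array(120, dim = c(4, 4, 3))
  expect_equal(greenness(grey), 1 / 3, tolerance = 1e-12)
  pure <- array(0, dim = c(2, 2, 3)); pure[, , 2] <- 200
  expect_equal(greenness(pure), 1)
  set.seed(15)
  a <- array(sample(0:255, 64 * 64 * 3, TRUE), dim = c(64, 64, 3))
  # independent per-pixel double-loop oracle
  num <- 0; den <- 0
  for (i in 1:64) for (j in 1:64) {
    num <- num + a[i, j, 2]
    den <- den + sum(a[i, j, ])
  }
  expect_equal(greenness(a), num / den, tolerance = 1e-12)
  # invariant to uniform channel rescaling
  expect_equal(greenness(a / 255), greenness(a), tolerance = 1e-12)
  expect_error(greenness(array(0, dim = c(2, 2, 3))), "all-black")
  expect_error(greenness(matrix(1, 2, 2)), "RGB")
})
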