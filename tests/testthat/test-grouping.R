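# Chain-rule partitioning and per-group metrics.

test_that("collinear points chain into one group beyond the threshold span", {
  ind <- mk_ind(x = seq(0, 48, by = 12), y = rep(0, 5))
  p <- assign_groups(ind, 15)
  expect_equal(nrow(p$groups), 1)
  expect_equal(p$groups$size, 5)
})

test_that("well-separated points stay singletons", {
  ind <- mk_ind(x = c(0, 40, 80), y = c(0, 0, 0))
  p <- assign_groups(ind, 30)
  expect_equal(nrow(p$groups), 3)
  expect_true(all(p$groups$size == 1))
})

test_that("pairs at exactly the chain distance are linked (closed threshold)", {
  ind <- mk_ind(x = c(0, 15), y = c(0, 0))
  expect_equal(nrow(assign_groups(ind, 15)$groups), 1)
  ind2 <- mk_ind(x = c(0, 15.0001), y = c(0, 0))
  expect_equal(nrow(assign_groups(ind2, 15)$groups), 2)
})

test_that("partitions equal brute-force components and nest across thresholds", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    side <- runif(1, 100, 800)
    xy <- cbind(runif(n, 0, side), runif(n, 0, side))
    ind <- mk_ind(x = xy[, 1], y = xy[, 2])
    prev <- NULL
    for (ch in c(15, 30, 50)) {
      p <- assign_groups(ind, ch)
      lab <- p$assignment$group[match(ind$id, p$assignment$id)]
      expect_same_partition(lab, chain_components_bruteforce(xy, ch))
      if (!is.null(prev)) {
        expect_true(all(tapply(lab, prev,
                               function(v) length(unique(v))) == 1))
        expect_lte(length(unique(lab)), length(unique(prev)))
      }
      prev <- lab
    }
  }
})

test_that("the partition is invariant to input order", {
  set.seed(12)
  ind <- mk_ind(x = runif(80, 0, 300), y = runif(80, 0, 300))
  p1 <- assign_groups(ind, 30)
  p2 <- assign_groups(ind[sample(nrow(ind)), ], 30)
  a1 <- p1$assignment[order(p1$assignment$id), ]
  a2 <- p2$assignment[order(p2$assignment$id), ]
  expect_same_partition(a1$group, a2$group)
  expect_identical(a1$group, a2$group)  # min-id ordering makes labels stable
})

test_that("group sizes obey the pouch-young rule and conserve individuals", {
  g <- mk_ind(x = c(0, 5, 10, 5), y = c(0, 0, 0, 0),
              demo_class = c("LA", "MA", "SA", "PY"),
              in_pouch = c(0L, 0L, 0L, 1L), mother_id = c(NA, NA, NA, "2"))
  expect_equal(group_size(g), 3)
  expect_equal(group_size(g, include_in_pouch = TRUE), 4)
  g2 <- mk_ind(x = c(0, 5, 10, 5), y = c(0, 0, 0, 0),
               demo_class = c("LA", "MA", "SA", "YAF"))
  expect_equal(group_size(g2), 4)
  expect_equal(group_size(mk_ind(1, 1)), 1)
  # conservation across a session
  sv <- generate_survey(small_cfg(seed = 21))
  obs1 <- sv$observations[sv$observations$session == 1, ]
  p <- assign_groups(obs1, 15)
  expect_equal(sum(p$groups$size), sum(obs1$in_pouch == 0))
  expect_equal(sum(p$groups$n_total), nrow(obs1))
})

test_that("centroids are coordinate-wise means of out-of-pouch members", {
  expect_equal(group_centroid(mk_ind(c(0, 10), c(0, 0))), c(5, 0))
  expect_equal(group_centroid(mk_ind(3, 4)), c(3, 4))
  set.seed(13)
  g <- mk_ind(runif(50, 0, 100), runif(50, 0, 100))
  expect_equal(group_centroid(g), c(mean(g$x_m), mean(g$y_m)),
               tolerance = 1e-9)
  # an in-pouch joey at the mother's point must not double-weight her
  g$in_pouch[1] <- 1L
  expect_equal(group_centroid(g), c(mean(g$x_m[-1]), mean(g$y_m[-1])),
               tolerance = 1e-9)
})

test_that("clusteredness matches hand-computed nearest-neighbour means", {
  expect_equal(group_clusteredness(cbind(c(0, 8), c(0, 0))), 8)
  expect_equal(group_clusteredness(cbind(c(0, 10, 30), c(0, 0, 0))),
               mean(c(10, 10, 20)))
  expect_error(group_clusteredness(cbind(1, 1)), "singleton")
  # every chain-rule group is bounded by its chain distance
  sv <- generate_survey(small_cfg(seed = 22))
  parts <- survey_partitions(sv$observations, sv$landscape, chains = 15)
  expect_true(all(parts$mean_nn_m <= 15, na.rm = TRUE))
})

test_that("degenerate inputs are handled", {
  expect_error(assign_groups(mk_ind(c(1, 2), c(1, 2), id = c("a", "a")), 15),
               "duplicate")
  p <- assign_groups(mk_ind(numeric(0), numeric(0)), 15)
  expect_equal(nrow(p$groups), 0)
  expect_error(assign_groups(mk_ind(1, 1), 0), "positive")
})

test_that("pouch young inherit the mother's group; disturbed are excluded", {
  ind <- rbind(
    mk_ind(c(0, 10, 100), c(0, 0, 0), id = c("m", "b", "far")),
    mk_ind(0, 0, id = "joey", demo_class = "PY", in_pouch = 1L,
           mother_id = "m"))
  p <- assign_groups(ind, 15)
  a <- p$assignment
  expect_equal(a$group[a$id == "joey"], a$group[a$id == "m"])
  ind$disturbed[ind$id == "far"] <- 1L
  p2 <- assign_groups(ind, 15)
  expect_false("far" %in% p2$assignment$id)
})
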