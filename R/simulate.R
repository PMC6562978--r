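# Synthetic survey generator.
#
# The generative model mirrors the fitted models downstream: group seeds
# fall uniformly in cleared habitat (>= 25 m inside the forest edge, so
# that whole groups fit in the clearing); total group size is negative
# binomial with log mean = intercept + beta * log(distance-to-cover) +
# session effect; members are chained within 12 m steps of one another
# (so a 15 m chain-rule recovers the planted groups exactly) and groups
# are seeded >= 66 m apart (so no two planted groups ever link);
# demographic classes are i.i.d. from the zone's mix; pouch young ride on
# a mother's coordinates; vulnerable individuals are biased toward the
# cover-facing side of the group with probability decaying in the group's
# distance from cover.

.SEED_MARGIN <- 25   # m: seeds this far inside the clearing
.SEED_MINSEP <- 66   # m: inter-seed hard core; members stay within 25 m of
                     # their seed, so inter-group gaps exceed 16 m > 15 m
.MEMBER_RADIUS <- 25 # m: cap on member displacement from the seed
.MAX_STEP <- 12      # m: cap on chaining steps between members

# Deterministic grid of distance-to-cover over admissible seed locations,
# memoised per ring — pure geometry, recomputed every session otherwise.
.grid_cache <- new.env(parent = emptyenv())

.grid_cover_dists <- function(ring, margin = .SEED_MARGIN, n = 40) {
  key <- paste(c(signif(as.numeric(ring), 10), margin, n), collapse = "|")
  hit <- .grid_cache[[key]]
  if (!is.null(hit)) return(hit)
  xs <- seq(min(ring[, 1]), max(ring[, 1]), length.out = n)
  ys <- seq(min(ring[, 2]), max(ring[, 2]), length.out = n)
  g <- expand.grid(x = xs, y = ys)
  keep <- point_in_ring(g$x, g$y, ring)
  d <- dist_to_ring(g$x[keep], g$y[keep], ring)
  d <- d[d >= margin]
  if (!length(d)) stop("cleared polygon too small for the 25 m seed margin")
  .grid_cache[[key]] <- d
  d
}

# Latent NB mean mu such that the observed (zero-truncated) mean is m:
# mu / (1 - (theta/(theta+mu))^theta) = m. A group-size draw of 0 means no
# group forms, so planting the *observed* mean keeps the fitted log-linear
# slope an unbiased estimand; the fixed point mu = m * (1 - p0(mu)) is a
# contraction and converges in a few iterations.
.latent_nb_mean <- function(m, theta) {
  mu <- m
  for (i in 1:40) {
    p0 <- (theta / (theta + mu))^theta
    mu_new <- m * (1 - p0)
    if (max(abs(mu_new - mu)) < 1e-10) { mu <- mu_new; break }
    mu <- mu_new
  }
  mu
}

.place_seeds <- function(ring, n, margin = .SEED_MARGIN, min_sep = .SEED_MINSEP) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  bx <- range(ring[, 1]); by <- range(ring[, 2])
  acc <- matrix(NA_real_, n, 2); k <- 0; rounds <- 0
  while (k < n && rounds < 100) {
    rounds <- rounds + 1
    m <- 4L * (n - k)
    px <- runif(m, bx[1], bx[2]); py <- runif(m, by[1], by[2])
    ok <- point_in_ring(px, py, ring)
    ok[ok] <- dist_to_ring(px[ok], py[ok], ring) >= margin
    for (i in which(ok)) {
      if (k > 0 &&
          min((acc[1:k, 1] - px[i])^2 + (acc[1:k, 2] - py[i])^2) < min_sep^2)
        next
      k <- k + 1; acc[k, ] <- c(px[i], py[i])
      if (k == n) break
    }
  }
  if (k < n)
    warning(sprintf("placed only %d of %d group seeds (zone too crowded)", k, n))
  acc[seq_len(k), , drop = FALSE]
}

# Chain members around a seed: each new member within .MAX_STEP of an
# existing one and within .MEMBER_RADIUS of the seed. Seeds sit at least
# .SEED_MARGIN (= .MEMBER_RADIUS) inside the clearing, so every such
# candidate is automatically inside the polygon.
.place_members <- function(seed, n, spacing) {
  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- seed
  if (n == 1) return(pos)
  r2 <- .MEMBER_RADIUS^2
  steps <- pmin(runif(n, 0.4 * spacing, 1.6 * spacing), .MAX_STEP)
  angs <- runif(n, 0, 2 * pi)
  for (k in 2:n) {
    a <- pos[sample.int(k - 1, 1), ]
    cand <- a + steps[k] * c(cos(angs[k]), sin(angs[k]))
    if (sum((cand - seed)^2) > r2) cand <- (a + seed) / 2
    pos[k, ] <- cand
  }
  pos
}

#' Simulate one survey session
#'
#' Draws, for every zone in the landscape, group seeds, negative-binomial
#' group sizes whose log mean depends on log distance-to-cover with the
#' zone's slope, member positions chained within the 15 m rule, i.i.d.
#' demographic classes, mother links for dependent young, and a
#' cover-facing positional bias for vulnerable individuals. Uses the
#' current RNG state; seed the stream (or use [generate_survey()]) for
#' reproducibility.
#'
#' @param landscape A `"mob_landscape"` from [generate_landscape()].
#' @param config A [simulation_config()]; must hold a profile for every
#'   zone of the landscape.
#' @param session_id Integer session number.
#' @param session_effect Optional pre-drawn session random intercept (log
#'   scale); drawn from `N(0, session_sd)` if `NULL`.
#'
#' @return List with `observations` (one row per individual: session, id,
#'   x_m, y_m, zone, demo_class, in_pouch, disturbed, mother_id, grp) and
#'   `groups` (planted per-group truth: session, zone, grp, n_total, size,
#'   gdc, greenness).
#' @export
simulate_session <- function(landscape, config, session_id, session_effect = NULL) {
  stopifnot(inherits(landscape, "mob_landscape"), inherits(config, "mob_config"))
  zs <- names(landscape$polygons)
  missing_p <- setdiff(zs, names(config$profiles))
  if (length(missing_p))
    stop("no profile for zone(s): ", paste(missing_p, collapse = ", "))
  if (is.null(session_effect))
    session_effect <- stats::rnorm(1, 0, config$session_sd)
  obs <- list(); gtab <- list()
  for (z in zs) {
    p <- config$profiles[[z]]
    ring <- landscape$polygons[[z]]
    area_km2 <- .ring_area(ring) / 1e6
    mixv <- p$demographic_mix
    beta <- p$cover_slope_beta
    theta <- p$groupsize_dispersion
    # Intercept pinned so the zone-average *observed* group size is
    # mean_group_size; -sd^2/2 keeps the session-marginal mean on target.
    dg <- .grid_cover_dists(ring)
    a <- log(p$mean_group_size) - log(mean(pmax(dg, 1)^beta)) +
      session_effect - config$session_sd^2 / 2
    # a size draw of 0 means no group forms at that seed; the latent NB
    # mean absorbs the truncation so observed sizes follow the planted
    # log-linear law and realized density hits density_mean
    mu_grid <- .latent_nb_mean(exp(a + beta * log(pmax(dg, 1))), theta)
    lambda <- p$density_mean * area_km2 /
      (mean(mu_grid) * (1 - mixv["PY"]))
    n_seed <- stats::rpois(1, lambda)
    seeds <- .place_seeds(ring, n_seed)
    if (!nrow(seeds)) next
    d_seed <- dist_to_ring(seeds[, 1], seeds[, 2], ring)
    mu <- .latent_nb_mean(exp(a + beta * log(pmax(d_seed, 1))), theta)
    n_tot <- stats::rnbinom(nrow(seeds), mu = mu, size = theta)
    keep <- which(n_tot > 0)
    if (!length(keep)) next
    tot <- sum(n_tot[keep])
    xv <- yv <- rep(NA_real_, tot)
    clsv <- character(tot)
    momv <- rep(NA_integer_, tot)          # survey-global member index
    grpv <- integer(tot)
    g_n <- g_size <- integer(length(keep))
    g_gdc <- g_green <- numeric(length(keep))
    off <- 0L
    for (j in seq_along(keep)) {
      gi <- keep[j]
      n <- n_tot[gi]
      cls <- sample(DEMO_CLASSES, n, replace = TRUE, prob = mixv)
      # every pouch young needs an adult mother in the group
      if (any(cls == "PY") && !any(cls %in% .ADULT_CLASSES)) {
        mix_np <- mixv[DEMO_CLASSES != "PY"]
        cls[cls == "PY"] <- sample(names(mix_np), sum(cls == "PY"),
                                   replace = TRUE, prob = mix_np)
      }
      op <- which(cls != "PY")              # out-of-pouch members get points
      py <- which(cls == "PY")
      pos <- .place_members(seeds[gi, ], length(op), p$within_group_spacing)
      # mother links: each dependent young attaches to a random adult
      mother <- rep(NA_integer_, n)
      adults <- op[cls[op] %in% .ADULT_CLASSES]
      for (dep in c(py, op[cls[op] == "YAF"]))
        if (length(adults)) mother[dep] <- adults[sample.int(length(adults), 1)]
      # vulnerable positional bias: swap points so mothers/YAF land on the
      # cover-facing side with probability decaying in the group's GDC;
      # swapping permutes the same point set, preserving planted geometry.
      ctr <- colMeans(pos)
      gdc <- dist_to_ring(ctr[1], ctr[2], ring)
      idc <- dist_to_ring(pos[, 1], pos[, 2], ring)
      vul_op <- sort(unique(c(stats::na.omit(mother), op[cls[op] == "YAF"])))
      vul_rows <- match(vul_op, op)
      p_front <- 0.5 + 0.45 * exp(-p$edge_bias_decay * gdc)
      for (v in vul_rows) {
        want_front <- stats::runif(1) < p_front
        is_front <- idc[v] < gdc
        if (want_front != is_front) {
          partners <- setdiff(which((idc < gdc) == want_front), vul_rows)
          if (length(partners)) {
            w <- partners[sample.int(length(partners), 1)]
            pos[c(v, w), ] <- pos[c(w, v), ]
            idc[c(v, w)] <- idc[c(w, v)]
          }
        }
      }
      idx <- off + seq_len(n)
      xv[idx[op]] <- pos[, 1]; yv[idx[op]] <- pos[, 2]
      if (length(py)) {
        mrow <- match(mother[py], op)
        xv[idx[py]] <- pos[mrow, 1]; yv[idx[py]] <- pos[mrow, 2]
      }
      clsv[idx] <- cls
      momv[idx][!is.na(mother)] <- off + mother[!is.na(mother)]
      grpv[idx] <- j
      g_n[j] <- n; g_size[j] <- length(op); g_gdc[j] <- gdc
      g_green[j] <- min(max(stats::rnorm(1, p$greenness_mean, p$greenness_sd),
                            0.01), 0.99)
      off <- off + n
    }
    ids <- sprintf("s%d_%s_i%d", session_id, z, seq_len(tot))
    grp_ids <- sprintf("s%d_%s_g%d", session_id, z, seq_along(keep))
    obs[[length(obs) + 1L]] <- data.frame(
      session = session_id, id = ids, x_m = xv, y_m = yv, zone = z,
      demo_class = clsv, in_pouch = as.integer(clsv == "PY"),
      disturbed = 0L,
      mother_id = ids[momv],
      grp = grp_ids[grpv], stringsAsFactors = FALSE)
    gtab[[length(gtab) + 1L]] <- data.frame(
      session = session_id, zone = z, grp = grp_ids,
      n_total = g_n, size = g_size, gdc = g_gdc, greenness = g_green,
      stringsAsFactors = FALSE)
  }
  list(observations = if (length(obs)) do.call(rbind, obs) else .empty_obs(),
       groups = if (length(gtab)) do.call(rbind, gtab) else .empty_groups())
}

.empty_obs <- function() data.frame(
  session = integer(), id = character(), x_m = numeric(), y_m = numeric(),
  zone = character(), demo_class = character(), in_pouch = integer(),
  disturbed = integer(), mother_id = character(), grp = character(),
  stringsAsFactors = FALSE)

.empty_groups <- function() data.frame(
  session = integer(), zone = character(), grp = character(),
  n_total = integer(), size = integer(), gdc = numeric(),
  greenness = numeric(), stringsAsFactors = FALSE)

#' Generate a complete multi-session survey dataset
#'
#' Builds the landscape, draws per-session random intercepts and simulates
#' `n_sessions` i.i.d. sessions. Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"mob_survey"`: `landscape`, `observations`
#'   (all sessions stacked), `groups` (planted truth table), `config`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "mob_config"))
  set.seed(config$seed)
  landscape <- generate_landscape(config)
  effects <- stats::rnorm(config$n_sessions, 0, config$session_sd)
  sess <- lapply(seq_len(config$n_sessions), function(s)
    simulate_session(landscape, config, s, session_effect = effects[s]))
  structure(list(
    landscape = landscape,
    observations = do.call(rbind, lapply(sess, `[[`, "observations")),
    groups = do.call(rbind, lapply(sess, `[[`, "groups")),
    config = config
  ), class = "mob_survey")
}

#' @export
print.mob_survey <- function(x, ...) {
  cat("Synthetic survey:", x$config$n_sessions, "sessions,",
      nrow(x$observations), "individuals,",
      nrow(x$groups), "planted groups, seed", x$config$seed, "\n")
  invisible(x)
}

#' Simulate an RGB forage patch with known greenness
#'
#' Emits an 8-bit RGB patch whose relative green channel brightness (sum of
#' green digital numbers over the sum of all three channels) equals
#' `mean_greenness` up to pixel noise and 8-bit quantisation. Pixels share
#' a fixed total brightness of 240 digital numbers so the patch greenness
#' is the mean of the per-pixel green fractions.
#'
#' @param mean_greenness Target green fraction, in (0, 1).
#' @param noise_sd SD of per-pixel Gaussian noise on the green fraction.
#' @param size Number of pixels (>= 1).
#' @param seed Optional integer seed.
#' @return Integer array (h x w x 3) of class `"greenness_patch"`, values
#'   in 0..255.
#' @export
simulate_greenness_patch <- function(mean_greenness, noise_sd = 0, size = 64^2,
                                     seed = NULL) {
  if (!is.numeric(mean_greenness) || mean_greenness <= 0 || mean_greenness >= 1)
    stop("mean_greenness must lie in (0, 1)")
  if (size < 1) stop("size must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(size)
  g <- pmin(pmax(stats::rnorm(n, mean_greenness, noise_sd), 0), 1)
  total <- 240L                      # per-pixel brightness, digital numbers
  G <- as.integer(round(g * total))
  rem <- total - G
  R <- rem %/% 2L
  B <- rem - R
  h <- floor(sqrt(n))
  if (h * (n %/% h) != n) h <- 1L
  w <- n %/% h
  arr <- array(0L, dim = c(h, w, 3))
  arr[, , 1] <- R; arr[, , 2] <- G; arr[, , 3] <- B
  structure(arr, class = "greenness_patch")
}

#' Write a greenness patch to PNG
#'
#' @param patch A `"greenness_patch"` (or any h x w x 3 array, 0..255).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_patch_png <- function(patch, path) {
  png::writePNG(unclass(patch) / 255, path)
  invisible(path)
}

#' Read an RGB image patch from PNG or JPEG-decoded array
#'
#' @param path PNG file.
#' @return Integer array (h x w x 3) of class `"greenness_patch"`.
#' @export
read_patch_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3 && dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  structure(array(as.integer(round(a * 255)), dim = dim(a)),
            class = "greenness_patch")
}
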