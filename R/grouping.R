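#' Assign individuals to groups by the chain rule
#'
#' The chain rule links any two individuals within `chain_distance` metres
#' and takes the transitive closure: groups are the connected components of
#' the threshold graph, equivalently a single-linkage clustering cut at the
#' chain distance (the threshold is closed: pairs at exactly the chain
#' distance link). Pouch young carry no point of their own — they ride with
#' their mother and inherit her group. Individuals flagged as disturbed
#' during the survey are excluded (they are retained only for density).
#'
#' @param individuals Data frame for a single session with columns `id`,
#'   `x_m`, `y_m`, `in_pouch`, optionally `mother_id` and `disturbed`.
#' @param chain_distance Positive chain distance in metres (15, 30 and 50 m
#'   are the conventional choices for eastern grey kangaroos).
#'
#' @return A list of class `"mob_partition"`: `chain` (m), `assignment`
#'   (data.frame id, group) and `groups` (per-group summary: group, size
#'   excluding pouch young, n_total including them, cx, cy, mean_nn_m —
#'   `NA` for singletons). Group ids are integers ordered by each group's
#'   minimum member id.
#' @export
assign_groups <- function(individuals, chain_distance) {
  if (!is.numeric(chain_distance) || length(chain_distance) != 1 ||
      chain_distance <= 0)
    stop("chain_distance must be a single positive number")
  ind <- as.data.frame(individuals)
  if (nrow(ind) && length(unique(ind$session)) > 1)
    stop("assign_groups expects individuals from a single session")
  if (anyDuplicated(ind$id)) stop("duplicate individual ids")
  if (!is.null(ind$disturbed)) ind <- ind[!(ind$disturbed %in% 1L), , drop = FALSE]
  if (is.null(ind$in_pouch)) ind$in_pouch <- 0L
  pts <- ind[ind$in_pouch == 0L, , drop = FALSE]
  if (nrow(pts) == 0) {
    return(structure(list(chain = chain_distance,
                          assignment = data.frame(id = character(), group = integer()),
                          groups = .empty_group_summary()),
                     class = "mob_partition"))
  }
  if (any(!is.finite(pts$x_m)) || any(!is.finite(pts$y_m)))
    stop("non-finite coordinates")
  if (nrow(pts) == 1) {
    comp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(cbind(pts$x_m, pts$y_m)), method = "single")
    comp <- stats::cutree(hc, h = chain_distance)
  }
  # stable ids: order components by their minimum member id (numeric-aware)
  ids_chr <- as.character(pts$id)
  ids_num <- suppressWarnings(as.numeric(ids_chr))
  key <- if (!anyNA(ids_num)) {
    vapply(split(ids_num, comp), min, numeric(1))
  } else {
    vapply(split(ids_chr, comp), function(v) sort(v)[1], character(1))
  }
  relab <- stats::setNames(as.integer(rank(key, ties.method = "first")),
                           names(key))
  group <- unname(relab[as.character(comp)])
  assignment <- data.frame(id = as.character(pts$id), group = group,
                           stringsAsFactors = FALSE)
  # pouch young inherit the mother's group
  pys <- ind[ind$in_pouch == 1L, , drop = FALSE]
  if (nrow(pys)) {
    mg <- assignment$group[match(as.character(pys$mother_id), assignment$id)]
    if (anyNA(mg)) {
      # fall back to co-located point (pouch young share mother coordinates)
      for (i in which(is.na(mg))) {
        hit <- which(abs(pts$x_m - pys$x_m[i]) < 1e-9 &
                       abs(pts$y_m - pys$y_m[i]) < 1e-9)[1]
        if (!is.na(hit)) mg[i] <- group[hit]
      }
    }
    assignment <- rbind(assignment,
                        data.frame(id = as.character(pys$id), group = mg,
                                   stringsAsFactors = FALSE))
  }
  summ <- .group_summary(ind, assignment, pts)
  structure(list(chain = chain_distance, assignment = assignment, groups = summ),
            class = "mob_partition")
}

.empty_group_summary <- function() data.frame(
  group = integer(), size = integer(), n_total = integer(),
  cx = numeric(), cy = numeric(), mean_nn_m = numeric())

.group_summary <- function(ind, assignment, pts) {
  gids <- sort(unique(assignment$group[!is.na(assignment$group)]))
  out <- lapply(gids, function(g) {
    members <- assignment$id[assignment$group %in% g]
    mpts <- pts[as.character(pts$id) %in% members, , drop = FALSE]
    xy <- cbind(mpts$x_m, mpts$y_m)
    data.frame(group = g,
               size = nrow(mpts),
               n_total = length(members),
               cx = mean(xy[, 1]), cy = mean(xy[, 2]),
               mean_nn_m = if (nrow(mpts) > 1) group_clusteredness(xy) else NA_real_)
  })
  do.call(rbind, out)
}

#' @export
print.mob_partition <- function(x, ...) {
  cat("Chain-rule partition at", x$chain, "m:", nrow(x$groups), "group(s),",
      nrow(x$assignment), "individual(s)\n")
  invisible(x)
}

#' Group size under the pouch-young counting rule
#'
#' Pouch young are not counted in group size unless out of the pouch
#' (young-at-foot count).
#'
#' @param group Data frame of one group's members with column `in_pouch`.
#' @param include_in_pouch Count pouch young too (the demography
#'   denominator)? Default `FALSE`.
#' @return Integer count.
#' @export
group_size <- function(group, include_in_pouch = FALSE) {
  if (nrow(group) == 0) stop("empty group")
  if (include_in_pouch) nrow(group) else sum(group$in_pouch == 0L)
}

#' Geometric centre of a group
#'
#' Arithmetic mean of member coordinates, pouch young excluded (they share
#' the mother's point).
#'
#' @param group Data frame with `x_m`, `y_m`, `in_pouch`.
#' @return Numeric `c(x, y)`.
#' @export
group_centroid <- function(group) {
  g <- group[group$in_pouch == 0L, , drop = FALSE]
  if (nrow(g) == 0) stop("group has no out-of-pouch members")
  c(mean(g$x_m), mean(g$y_m))
}

#' Group clusteredness: mean nearest-neighbour distance
#'
#' For each member, the distance to its nearest other member; clusteredness
#' is the mean of these, defined for groups of size > 1. Any chain-rule
#' group at chain distance c has clusteredness <= c.
#'
#' @param xy Either an n x 2 coordinate matrix or a data frame with
#'   `x_m`, `y_m` (pouch young rows, if present, should be excluded first).
#' @return Mean nearest-neighbour distance in metres.
#' @export
group_clusteredness <- function(xy) {
  if (is.data.frame(xy)) {
    if (!is.null(xy$in_pouch)) xy <- xy[xy$in_pouch == 0L, , drop = FALSE]
    xy <- cbind(xy$x_m, xy$y_m)
  }
  n <- nrow(xy)
  if (n < 2) stop("clusteredness is undefined for singleton groups")
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Partition every session of a survey at several chain distances
#'
#' @param observations Observation table covering one or more sessions.
#' @param landscape A `"mob_landscape"` (adds each group's zone and
#'   distance-to-cover of its centre).
#' @param chains Chain distances in metres.
#' @return A data.frame with one row per (session, chain, group): size,
#'   n_total, centroid, mean nearest-neighbour distance, zone, gdc; plus an
#'   `assignments` attribute (data.frame session, chain_m, group_id,
#'   individual_id).
#' @export
survey_partitions <- function(observations, landscape = NULL,
                              chains = c(15, 30, 50)) {
  out <- list(); asg <- list()
  for (s in sort(unique(observations$session))) {
    obs_s <- observations[observations$session == s, , drop = FALSE]
    for (ch in chains) {
      part <- assign_groups(obs_s, ch)
      if (!nrow(part$groups)) next
      g <- part$groups
      g$session <- s; g$chain_m <- ch
      if (!is.null(landscape)) {
        g$zone <- zone_of(g$cx, g$cy, landscape)
        g$gdc <- distance_to_cover(g$cx, g$cy, landscape, zone = g$zone)
      }
      out[[length(out) + 1L]] <- g
      a <- part$assignment
      asg[[length(asg) + 1L]] <- data.frame(session = s, chain_m = ch,
                                            group_id = a$group,
                                            individual_id = a$id)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "assignments") <- do.call(rbind, asg)
  res
}

#' Brute-force chain-rule components (validation reference)
#'
#' Independent O(n^2) breadth-first traversal of the closed threshold
#' graph, kept as a cross-check for [assign_groups()].
#'
#' @param xy n x 2 coordinate matrix.
#' @param chain_distance Threshold in metres.
#' @return Integer component labels (arbitrary but consistent numbering).
#' @export
chain_components_bruteforce <- function(xy, chain_distance) {
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  adj <- as.matrix(stats::dist(xy)) <= chain_distance
  comp <- rep(NA_integer_, n); cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
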