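#' Generate a synthetic landscape of cleared polygons inside forest
#'
#' Lays out one rectangular cleared polygon per profile on a grid, each
#' fully surrounded by forest (polygons are separated and bordered by at
#' least `forest_gap` metres of forest). Rectangle areas equal the
#' profiles' `cleared_area` exactly by construction; aspect ratio is 2:1.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"mob_landscape"` with elements `extent`
#'   (c(width, height), metres), `zones` (data.frame of zone, area_ha) and
#'   `polygons` (named list of unclosed n x 2 rings, metres).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "mob_config"))
  profs <- config$profiles
  gap <- config$forest_gap
  if (length(profs) == 0) {
    return(structure(list(extent = c(0, 0),
                          zones = data.frame(zone = character(), area_ha = numeric()),
                          polygons = list()),
                     class = "mob_landscape"))
  }
  nz <- length(profs)
  ncol_grid <- ceiling(sqrt(nz))
  nrow_grid <- ceiling(nz / ncol_grid)
  # 2:1 rectangles, metres
  w <- vapply(profs, function(p) sqrt(2 * p$cleared_area * 1e4), numeric(1))
  h <- vapply(profs, function(p) p$cleared_area * 1e4, numeric(1)) / w
  col_w <- numeric(ncol_grid); row_h <- numeric(nrow_grid)
  for (i in seq_len(nz)) {
    r <- (i - 1) %/% ncol_grid + 1
    cc <- (i - 1) %% ncol_grid + 1
    col_w[cc] <- max(col_w[cc], w[i])
    row_h[r] <- max(row_h[r], h[i])
  }
  need_w <- sum(col_w) + gap * (ncol_grid + 1)
  need_h <- sum(row_h) + gap * (nrow_grid + 1)
  extent <- config$landscape_extent
  if (is.null(extent)) {
    extent <- c(need_w, need_h)
  } else {
    extent <- rep(extent, length.out = 2)
    if (extent[1] < need_w || extent[2] < need_h)
      stop(sprintf(paste0("cannot pack %d cleared polygons (need %.0f x %.0f m ",
                          "incl. %g m forest gaps) into a %.0f x %.0f m extent"),
                   nz, need_w, need_h, gap, extent[1], extent[2]))
  }
  polys <- vector("list", nz)
  x0 <- gap + cumsum(c(0, col_w[-ncol_grid] + gap))
  y0 <- gap + cumsum(c(0, row_h[-nrow_grid] + gap))
  for (i in seq_len(nz)) {
    r <- (i - 1) %/% ncol_grid + 1
    cc <- (i - 1) %% ncol_grid + 1
    polys[[i]] <- .ring_rect(x0[cc], y0[r], x0[cc] + w[i], y0[r] + h[i])
  }
  names(polys) <- names(profs)
  structure(list(
    extent = extent,
    zones = data.frame(zone = names(profs),
                       area_ha = vapply(profs, `[[`, numeric(1), "cleared_area"),
                       row.names = NULL),
    polygons = polys
  ), class = "mob_landscape")
}

#' @export
print.mob_landscape <- function(x, ...) {
  cat("Landscape:", nrow(x$zones), "cleared zone(s) in a",
      sprintf("%.0f x %.0f m", x$extent[1], x$extent[2]), "forest block\n")
  if (nrow(x$zones)) print(x$zones)
  invisible(x)
}

#' Locate the cleared zone containing each point
#'
#' @param x,y Point coordinates (metres).
#' @param landscape A `"mob_landscape"`.
#' @return Character vector of zone labels, `NA` for points in forest.
#' @export
zone_of <- function(x, y, landscape) {
  out <- rep(NA_character_, length(x))
  for (z in names(landscape$polygons)) {
    hit <- is.na(out) & point_in_ring(x, y, landscape$polygons[[z]])
    out[hit] <- z
  }
  out
}

#' Write / read a landscape as GeoJSON
#'
#' Cleared polygons become `Polygon` features with properties `zone`,
#' `class = "cleared"` and `area_ha`; the surrounding forest is a single
#' polygon feature whose interior rings are the cleared polygons.
#'
#' @param landscape A `"mob_landscape"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landscape_geojson <- function(landscape, path) {
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  feat <- lapply(names(landscape$polygons), function(z) {
    ring <- close_ring(landscape$polygons[[z]])
    list(type = "Feature",
         properties = list(zone = z, class = "cleared",
                           area_ha = .ring_area(landscape$polygons[[z]]) / 1e4),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1, as.numeric, simplify = FALSE)))))
  })
  outer <- close_ring(.ring_rect(0, 0, landscape$extent[1], landscape$extent[2]))
  holes <- lapply(landscape$polygons, function(r)
    unname(apply(close_ring(r[rev(seq_len(nrow(r))), , drop = FALSE]), 1,
                 as.numeric, simplify = FALSE)))
  forest <- list(type = "Feature",
                 properties = list(zone = NA, class = "forest", area_ha = NA),
                 geometry = list(type = "Polygon",
                                 coordinates = c(list(unname(apply(outer, 1, as.numeric, simplify = FALSE))),
                                                 unname(holes))))
  gj <- list(type = "FeatureCollection", features = c(feat, list(forest)))
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA, null = "null"), path)
  invisible(path)
}

#' @rdname write_landscape_geojson
#' @export
read_landscape_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- list(); zones <- character(); areas <- numeric(); extent <- c(0, 0)
  for (f in gj$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    if (identical(f$properties$class, "cleared")) {
      z <- f$properties$zone
      polys[[z]] <- unname(ring)
      zones <- c(zones, z)
      areas <- c(areas, f$properties$area_ha)
    } else {
      extent <- c(max(ring[, 1]), max(ring[, 2]))
    }
  }
  structure(list(extent = extent,
                 zones = data.frame(zone = zones, area_ha = areas),
                 polygons = polys),
            class = "mob_landscape")
}

#' Distance from points to forested cover
#'
#' The distance from a point in cleared habitat to the nearest forest edge,
#' i.e. to the boundary of the cleared polygon containing it (forest fills
#' everything outside the cleared polygons).
#'
#' @param x,y Coordinates (metres) of points inside cleared habitat.
#' @param landscape A `"mob_landscape"`.
#' @param zone Optional zone label(s); located by point-in-polygon if
#'   missing.
#' @return Numeric vector of distances (m), `>= 0`.
#' @export
distance_to_cover <- function(x, y, landscape, zone = NULL) {
  if (is.null(zone)) zone <- zone_of(x, y, landscape)
  zone <- rep_len(zone, length(x))
  if (anyNA(zone)) {
    bad <- which(is.na(zone))[1]
    stop(sprintf("point (%.1f, %.1f) is not inside any cleared polygon",
                 x[bad], y[bad]))
  }
  out <- numeric(length(x))
  for (z in unique(zone)) {
    if (!z %in% names(landscape$polygons))
      stop("unknown zone: ", z)
    i <- zone == z
    if (any(!point_in_ring(x[i], y[i], landscape$polygons[[z]]))) {
      j <- which(i)[which(!point_in_ring(x[i], y[i], landscape$polygons[[z]]))[1]]
      stop(sprintf("point (%.1f, %.1f) is outside the cleared polygon of zone %s",
                   x[j], y[j], z))
    }
    out[i] <- dist_to_ring(x[i], y[i], landscape$polygons[[z]])
  }
  out
}
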