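# Planar geometry helpers for rectangular/polygonal cleared habitat.
# Coordinates are metres in a local projected frame; rings are unclosed
# n x 2 matrices traversed counter-clockwise.

.ring_rect <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin),
        y = c(ymin, ymin, ymax, ymax))
}

#' @keywords internal
#' @noRd
point_in_ring <- function(x, y, ring) {
  # Ray casting, vectorised over points; boundary points count as inside.
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- ring[c(2:n, 1), 1]; ye <- ring[c(2:n, 1), 2]
  inside <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > y) != (ye[i] > y))
    if (any(crosses)) {
      xint <- xs[i] + (y[crosses] - ys[i]) * (xe[i] - xs[i]) / (ye[i] - ys[i])
      inside[crosses] <- xor(inside[crosses], x[crosses] < xint)
    }
  }
  inside | dist_to_ring(x, y, ring) < 1e-9
}

#' @keywords internal
#' @noRd
dist_to_ring <- function(x, y, ring) {
  # Minimum Euclidean distance from each point to the ring's edges.
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- ring[c(2:n, 1), 1]; ye <- ring[c(2:n, 1), 2]
  best <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    dx <- xe[i] - xs[i]; dy <- ye[i] - ys[i]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (x - xs[i])^2 + (y - ys[i])^2
    } else {
      t <- pmin(1, pmax(0, ((x - xs[i]) * dx + (y - ys[i]) * dy) / len2))
      d2 <- (x - (xs[i] + t * dx))^2 + (y - (ys[i] + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' @keywords internal
#' @noRd
nearest_ring_point <- function(x, y, ring) {
  # Single point -> nearest point on ring boundary (for the cover direction).
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- ring[c(2:n, 1), 1]; ye <- ring[c(2:n, 1), 2]
  best <- Inf; bx <- NA_real_; by <- NA_real_
  for (i in seq_len(n)) {
    dx <- xe[i] - xs[i]; dy <- ye[i] - ys[i]
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) 0 else min(1, max(0, ((x - xs[i]) * dx + (y - ys[i]) * dy) / len2))
    px <- xs[i] + t * dx; py <- ys[i] + t * dy
    d2 <- (x - px)^2 + (y - py)^2
    if (d2 < best) { best <- d2; bx <- px; by <- py }
  }
  c(bx, by)
}

# Area of a simple polygon ring (shoelace), in square metres.
.ring_area <- function(ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- ring[c(2:n, 1), 1]; ye <- ring[c(2:n, 1), 2]
  abs(sum(xs * ye - xe * ys)) / 2
}
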