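# Moment-based normality tests, implemented from the published
# normalising transformations: D'Agostino (1970) for sample skewness and
# Anscombe & Glynn (1983) for sample kurtosis. Both use the biased
# (1/n) central moments, the convention of the classical tests; kurtosis
# is reported non-excess (a normal sample tends to 3, leptokurtic > 3).

.sample_g1 <- function(x) {
  m <- x - mean(x)
  m2 <- mean(m^2)
  mean(m^3) / m2^1.5
}

.sample_g2 <- function(x) {
  m <- x - mean(x)
  mean(m^4) / mean(m^2)^2
}

#' D'Agostino test of skewness
#'
#' Transforms the sample skewness `g1 = m3 / m2^(3/2)` to an approximately
#' standard normal Z via D'Agostino's (1970) normalisation and returns a
#' two-sided p-value against the null of a normal (symmetric) population.
#'
#' @param x Numeric vector, `n >= 8`.
#' @return A list of class `"mob_moment_test"`: `statistic` (g1), `z`,
#'   `p.value`, `n`, `method`.
#' @export
dagostino_skewness <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("D'Agostino skewness test needs n >= 8")
  if (stats::var(x) == 0) stop("zero variance")
  g1 <- .sample_g1(x)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * asinh(y / alpha)
  structure(list(statistic = g1, z = z,
                 p.value = 2 * stats::pnorm(-abs(z)),
                 n = n, method = "D'Agostino skewness"),
            class = "mob_moment_test")
}

#' Anscombe-Glynn test of kurtosis
#'
#' Transforms the sample kurtosis `g2 = m4 / m2^2` (non-excess; normal = 3)
#' to an approximately standard normal Z via the Anscombe & Glynn (1983)
#' transformation and returns a two-sided p-value. The approximation is
#' intended for n of 20 or more; smaller samples (n >= 5) are accepted
#' with reduced accuracy.
#'
#' @param x Numeric vector, `n >= 5`.
#' @return A list of class `"mob_moment_test"`: `statistic` (g2), `z`,
#'   `p.value`, `n`, `method`.
#' @export
anscombe_kurtosis <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 5) stop("Anscombe-Glynn kurtosis test needs n >= 5")
  if (stats::var(x) == 0) stop("zero variance")
  g2 <- .sample_g2(x)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z <- (1 - 2 / (9 * a) -
          ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  structure(list(statistic = g2, z = z,
                 p.value = 2 * stats::pnorm(-abs(z)),
                 n = n, method = "Anscombe-Glynn kurtosis"),
            class = "mob_moment_test")
}

#' @export
print.mob_moment_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, Z = %.4f, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$z, x$p.value, x$n))
  invisible(x)
}
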