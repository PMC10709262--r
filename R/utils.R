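# small numeric utilities shared across modules

#' Circular mean of angles
#'
#' @param theta numeric vector of angles in radians.
#' @return mean direction in `[0, 2*pi)`.
#' @export
circular_mean <- function(theta) {
  (atan2(mean(sin(theta)), mean(cos(theta)))) %% (2 * pi)
}

#' Circular correlation between two angle vectors
#'
#' Jammalamadaka-SenGupta circular correlation coefficient:
#' \deqn{\rho = \frac{\sum \sin(a_i - \bar a)\sin(b_i - \bar b)}
#'   {\sqrt{\sum \sin^2(a_i - \bar a) \sum \sin^2(b_i - \bar b)}}}
#' where \eqn{\bar a, \bar b} are circular means. Invariant to rotations of
#' either variable; changes sign under reflection.
#'
#' @param a,b numeric vectors of angles in radians, same length.
#' @return correlation in `[-1, 1]`.
#' @export
circular_cor <- function(a, b) {
  stopifnot(length(a) == length(b))
  sa <- sin(a - circular_mean(a))
  sb <- sin(b - circular_mean(b))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(0)
  sum(sa * sb) / den
}

#' Shannon entropy of a count vector
#'
#' @param counts non-negative counts per category.
#' @param base logarithm base (default natural).
#' @return entropy in nats (or chosen base); 0 for a single category.
#' @export
shannon_entropy <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items
#' (Hubert & Arabie). 1 for identical partitions (up to relabelling),
#' about 0 for independent ones.
#'
#' @param x,y label vectors of equal length (any atomic type).
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  ch2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(ch2(tab))
  a <- sum(ch2(rowSums(tab)))
  b <- sum(ch2(colSums(tab)))
  n <- length(x)
  expected <- a * b / ch2(n)
  maxi <- (a + b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
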