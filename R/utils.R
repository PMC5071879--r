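# Small numerical helpers shared across modules.

#' Trapezoidal integral
#'
#' @param x strictly increasing abscissae.
#' @param y ordinates, same length as `x`.
#' @return The trapezoidal-rule integral of `y` over `x`.
#' @keywords internal
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Convert a Gaussian FWHM to a standard deviation
#' @param fwhm full width at half maximum (> 0).
#' @keywords internal
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Measure the FWHM of a single-peaked sampled curve
#'
#' Linear interpolation between grid points is used to locate the two
#' half-maximum crossings around the global maximum.
#'
#' @param x grid (increasing).
#' @param y sampled curve with a single dominant maximum.
#' @return Width between the two half-maximum crossings.
#' @keywords internal
measure_fwhm <- function(x, y) {
  imax <- which.max(y)
  half <- y[imax] / 2
  cross <- function(idx) {
    # idx: indices on one side ordered away from the peak
    below <- which(y[idx] < half)
    if (length(below) == 0L) return(NA_real_)
    j <- idx[below[1L]]                    # first point below half max
    k <- j + sign(imax - j)                # neighbour towards the peak
    x[j] + (half - y[j]) * (x[k] - x[j]) / (y[k] - y[j])
  }
  left <- cross(rev(seq_len(imax - 1L)))
  right <- cross(seq(imax + 1L, length(y)))
  right - left
}

#' Sign of the permutation that sorts a vector ascending
#' @param x numeric vector with distinct entries.
#' @return +1 or -1 (parity of the number of inversions).
#' @keywords internal
perm_sign <- function(x) {
  n <- length(x)
  if (n < 2L) return(1)
  inv <- 0L
  for (i in seq_len(n - 1L)) inv <- inv + sum(x[i] > x[(i + 1L):n])
  if (inv %% 2L == 0L) 1 else -1
}

#' All permutations of 1..n (n small)
#' @param n size; intended for n <= 6.
#' @return matrix with one permutation per row.
#' @keywords internal
permutations <- function(n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }
  do.call(rbind, out)
}

# deterministic integer sub-seed derived from a master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset) * 9973L) %% 2147483587L
}
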