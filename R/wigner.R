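# Ground-state harmonic Wigner sampling of nuclear geometries and momenta.
#
# For each normal mode of (angular) frequency omega the vibrational
# ground-state Wigner function is a product of Gaussians in the
# dimensionless normal coordinate Q and its conjugate momentum P, each with
# mean 0 and variance 1/2. Sampled Q are mapped back to Cartesian
# displacements via the mass-weighted normal modes.

# hbar in amu * Angstrom^2 / fs
.hbar_amu_A2_fs <- 1.054571817e-34 / (1.66053906660e-27 * 1e-20 / 1e-15)
# speed of light in cm / fs
.c_cm_fs <- 2.99792458e-5

#' Angular frequency (1/fs) from a wavenumber (1/cm)
#' @param wavenumber vibrational wavenumber in cm^-1.
#' @export
omega_from_wavenumber <- function(wavenumber) 2 * pi * .c_cm_fs * wavenumber

#' Harmonic vibrational model
#'
#' @param geometry equilibrium Cartesian coordinates in Angstrom: numeric
#'   vector of length 3*N (x1, y1, z1, x2, ...) or an N-by-3 matrix.
#' @param masses atomic masses in amu, length N.
#' @param frequencies vibrational wavenumbers in cm^-1, one per mode.
#' @param modes 3N-by-n_modes matrix of mass-weighted normal-mode
#'   displacement vectors; columns must be orthonormal.
#' @return An object of class `harmonic_model`.
#' @export
harmonic_model <- function(geometry, masses, frequencies, modes) {
  if (is.matrix(geometry)) geometry <- as.numeric(t(geometry))
  n_atoms <- length(masses)
  stopifnot(length(geometry) == 3L * n_atoms)
  modes <- as.matrix(modes)
  stopifnot(nrow(modes) == 3L * n_atoms, ncol(modes) == length(frequencies))
  gram <- crossprod(modes)
  if (max(abs(gram - diag(ncol(modes)))) > 1e-6)
    stop("normal modes must be orthonormal in mass-weighted coordinates")
  structure(list(geometry = geometry, masses = as.numeric(masses),
                 frequencies = as.numeric(frequencies), modes = modes,
                 n_atoms = n_atoms),
            class = "harmonic_model")
}

#' @export
print.harmonic_model <- function(x, ...) {
  cat(sprintf("<harmonic_model: %d atoms, %d modes, %.0f..%.0f cm^-1>\n",
              x$n_atoms, length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Sample geometries from the ground-state Wigner distribution
#'
#' Draws, for every retained mode, a dimensionless coordinate and momentum
#' independently from N(0, variance 1/2) and transforms the coordinates to
#' Cartesian displacements about the equilibrium geometry. Modes with
#' wavenumber at or below `freq_threshold` (translations/rotations, or
#' imaginary modes encoded as non-positive wavenumbers) are excluded; if a
#' retained mode has a non-positive wavenumber an error is thrown unless
#' `skip_bad_modes = TRUE`.
#'
#' @param model a [harmonic_model()].
#' @param n number of samples (>= 1).
#' @param seed integer RNG seed; the draw is reproducible per seed.
#' @param freq_threshold wavenumber cut (cm^-1) below which modes are
#'   dropped (default 10).
#' @param momenta if `TRUE` (default) also return Cartesian momenta in
#'   amu * Angstrom / fs.
#' @param skip_bad_modes silently drop non-positive-frequency modes instead
#'   of erroring (default `FALSE`).
#' @return An object of class `wigner_sample`: list with `geometries`
#'   (n-by-3N matrix, Angstrom), `momenta` (n-by-3N or `NULL`), the
#'   dimensionless draws `Q` and `P` (n-by-n_modes), `mode_index` (columns
#'   of the model retained) and `seed`.
#' @export
wigner_sample <- function(model, n, seed, freq_threshold = 10,
                          momenta = TRUE, skip_bad_modes = FALSE) {
  stopifnot(inherits(model, "harmonic_model"), n >= 1)
  keep <- which(model$frequencies > freq_threshold)
  if (!skip_bad_modes && any(model$frequencies[keep] <= 0))
    stop("non-positive frequency among sampled modes; raise freq_threshold or set skip_bad_modes")
  if (length(keep) == 0L) stop("no modes survive the frequency threshold")
  set.seed(as.integer(seed))
  n_modes <- length(keep)
  Q <- matrix(stats::rnorm(n * n_modes, sd = sqrt(0.5)), n, n_modes)
  P <- matrix(stats::rnorm(n * n_modes, sd = sqrt(0.5)), n, n_modes)
  omega <- omega_from_wavenumber(model$frequencies[keep])
  L <- model$modes[, keep, drop = FALSE]
  m3 <- rep(model$masses, each = 3L)
  # mass-weighted normal coordinate q_mw = sqrt(hbar/omega) * Q  [sqrt(amu) A]
  q_mw <- Q %*% diag(sqrt(.hbar_amu_A2_fs / omega), n_modes) %*% t(L)
  disp <- sweep(q_mw, 2L, sqrt(m3), "/")
  geoms <- sweep(disp, 2L, model$geometry, "+")
  mom <- NULL
  if (momenta) {
    p_mw <- P %*% diag(sqrt(.hbar_amu_A2_fs * omega), n_modes) %*% t(L)
    mom <- sweep(p_mw, 2L, sqrt(m3), "*")
  }
  structure(list(geometries = geoms, momenta = mom, Q = Q, P = P,
                 displacements = disp, mode_index = keep, seed = seed),
            class = "wigner_sample")
}

#' Vibrational energy expectation of a Wigner sample
#'
#' Per-mode expectation of the harmonic energy
#' `hbar*omega*(Q^2 + P^2)/... ` evaluated from the dimensionless draws:
#' `E_k = hbar*omega_k * mean(Q_k^2 + P_k^2)`. For the exact ground-state
#' Wigner distribution this converges to the zero-point energy
#' `hbar*omega_k / 2`.
#'
#' @param sample a [wigner_sample()].
#' @param model the [harmonic_model()] the sample came from.
#' @return Numeric vector of per-mode energies (amu A^2 / fs^2).
#' @export
wigner_mode_energies <- function(sample, model) {
  omega <- omega_from_wavenumber(model$frequencies[sample$mode_index])
  .hbar_amu_A2_fs * omega * colMeans(sample$Q^2 + sample$P^2)
}
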