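# Static photoelectron spectra from Dyson norms and state energies:
# channel amplitudes, stick spectra, Gaussian broadening, component mixing,
# bright/dark classification and geometry-ensemble averaging.

#' Ionization-channel amplitude
#'
#' The amplitude of a channel is the Dyson norm scaled by the binding
#' energy, `W = dE * norm`, by analogy with the oscillator strength of a
#' bound-bound transition. Channels with negative binding energy are closed
#' and get `W = 0`; their positions are flagged in the `"closed"` attribute.
#'
#' @param norm Dyson norm(s), >= 0.
#' @param dE binding energy (eV), `V_ion - V_source`; vectorised.
#' @return Numeric amplitudes with a logical attribute `closed`.
#' @export
channel_amplitude <- function(norm, dE) {
  stopifnot(all(norm >= 0))
  closed <- dE < 0
  w <- ifelse(closed, 0, dE * norm)
  attr(w, "closed") <- closed
  w
}

#' Stick spectrum of one source state
#'
#' One stick per open channel, at binding energy `dE = V_ion - V_source`
#' (plus an optional global shift) with height `W = dE * norm`. Channels
#' with `dE < 0` (ion below the source) are omitted.
#'
#' @param source a [ci_state()] with a finite `energy`.
#' @param ions list of [ci_state()] ion states with finite energies.
#' @param norms numeric Dyson norms, one per ion state (or a named vector
#'   keyed by ion label covering every ion).
#' @param shift global binding-energy shift in eV added to every stick
#'   position (default 0; see the package vignette on the equivalent
#'   probe-energy correction).
#' @return A data frame with columns `energy`, `height`, `source`, `ion`.
#' @export
stick_spectrum <- function(source, ions, norms, shift = 0) {
  stopifnot(inherits(source, "ci_state"))
  labels <- vapply(ions, function(s) s$label, "")
  if (!is.null(names(norms))) {
    if (!all(labels %in% names(norms)))
      stop("missing Dyson norm for requested channel(s): ",
           paste(setdiff(labels, names(norms)), collapse = ", "))
    norms <- unname(norms[labels])
  }
  if (length(norms) != length(ions))
    stop("need one Dyson norm per ion state")
  dE <- vapply(ions, function(s) s$energy, 0) - source$energy
  if (any(!is.finite(dE))) stop("all state energies must be set to build a spectrum")
  open <- dE >= 0
  data.frame(energy = dE[open] + shift,
             height = dE[open] * norms[open],
             source = rep(source$label, sum(open)),
             ion = labels[open],
             stringsAsFactors = FALSE)
}

#' Uniform energy grid constructor
#' @param from,to grid limits in eV.
#' @param step grid step in eV (default 0.01).
#' @export
energy_grid <- function(from = 0, to = 14, step = 0.01) seq(from, to, by = step)

#' Gaussian broadening of a stick spectrum
#'
#' Convolves each stick with a unit-area Gaussian of the given FWHM, so the
#' integrated intensity equals the summed stick heights whenever the grid
#' covers all the spectral mass. If any stick lies closer than 5 standard
#' deviations to a grid edge a coverage warning is attached to the result's
#' metadata (and raised once as an R warning).
#'
#' @param sticks data frame with columns `energy` and `height` (e.g. from
#'   [stick_spectrum()]); may be empty.
#' @param grid uniform increasing energy grid (eV); see [energy_grid()].
#' @param fwhm Gaussian full width at half maximum in eV (default 0.2).
#' @param normalize if `TRUE`, rescale the result to a maximum of 1
#'   (presentation option; default `FALSE`).
#' @return An object of class `spectrum_grid`: list with `energy`,
#'   `intensity` and `meta` (fwhm, axis kind, warnings).
#' @export
broaden <- function(sticks, grid = energy_grid(), fwhm = 0.2, normalize = FALSE) {
  stopifnot(fwhm > 0, length(grid) >= 2, all(diff(grid) > 0))
  sigma <- fwhm_to_sigma(fwhm)
  warn <- character(0)
  intensity <- numeric(length(grid))
  if (nrow(sticks) > 0) {
    if (min(sticks$energy) - 5 * sigma < grid[1] ||
        max(sticks$energy) + 5 * sigma > grid[length(grid)]) {
      warn <- "grid does not cover all sticks +/- 5 sigma; integrated intensity will be low"
      warning(warn, call. = FALSE)
    }
    dens <- outer(sticks$energy, grid,
                  function(e, g) stats::dnorm(g, mean = e, sd = sigma))
    intensity <- as.numeric(crossprod(dens, sticks$height))
  }
  if (normalize && max(intensity) > 0) intensity <- intensity / max(intensity)
  spectrum_grid(grid, intensity,
                meta = list(fwhm = fwhm, shift = 0, axis = "binding",
                            normalized = normalize, warnings = warn))
}

spectrum_grid <- function(energy, intensity, meta = list()) {
  stopifnot(length(energy) == length(intensity), all(diff(energy) > 0),
            all(is.finite(intensity)))
  structure(list(energy = energy, intensity = intensity, meta = meta),
            class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("<spectrum_grid: %d points, %.2f..%.2f eV, max intensity %.4g>\n",
              length(x$energy), min(x$energy), max(x$energy), max(x$intensity)))
  invisible(x)
}

#' Weighted mixture of spectra on a common grid
#'
#' Weights are normalised to sum to one (so the mixture is invariant under
#' rescaling all weights by a common factor); the raw weights are recorded
#' in the metadata. Grids must agree exactly -- no silent resampling.
#'
#' @param spectra list of `spectrum_grid` objects on an identical grid.
#' @param weights non-negative weights, not all zero (e.g. tautomer
#'   abundances `c(keto = 29, syn = 17, anti = 37, imino = 17)`).
#' @return A `spectrum_grid` with the mixed intensity.
#' @export
mix_components <- function(spectra, weights) {
  stopifnot(length(spectra) == length(weights), all(weights >= 0), sum(weights) > 0)
  g <- spectra[[1L]]$energy
  for (s in spectra[-1L]) {
    if (length(s$energy) != length(g) || max(abs(s$energy - g)) > 0)
      stop("component spectra are on different grids; resample explicitly first")
  }
  w <- weights / sum(weights)
  intensity <- numeric(length(g))
  for (i in seq_along(spectra)) intensity <- intensity + w[i] * spectra[[i]]$intensity
  spectrum_grid(g, intensity,
                meta = list(fwhm = spectra[[1L]]$meta$fwhm, axis = "binding",
                            raw_weights = weights, fractions = w,
                            components = names(weights)))
}

#' Bright/dark classification of excited states
#'
#' Among the candidate states, the one with the largest transition-dipole
#' norm to the ground state is labelled the bright `"pipi*"` state and the
#' other considered state `"npi*"` (remaining candidates, if any, are
#' labelled `"other"`). When the top two norms agree within `rel_tol`
#' relative, the tie is broken towards the lower state index and a `mixed`
#' attribute is set.
#'
#' @param dipole_norms numeric vector (length >= 2) of transition dipole
#'   moment norms to the ground state, in candidate-state order.
#' @param rel_tol relative tolerance declaring two norms "equal" (default
#'   0.02).
#' @return Character labels, one per candidate, with attribute `mixed`.
#' @export
classify_bright_dark <- function(dipole_norms, rel_tol = 0.02) {
  if (length(dipole_norms) < 2L)
    stop("need at least two candidate states to classify bright/dark")
  ord <- order(dipole_norms, decreasing = TRUE)
  top2 <- sort(ord[1:2])
  mixed <- FALSE
  scale <- max(abs(dipole_norms[top2]), .Machine$double.eps)
  if (abs(dipole_norms[top2[1L]] - dipole_norms[top2[2L]]) <= rel_tol * scale) {
    bright <- top2[1L]  # tie: lower index wins
    mixed <- TRUE
  } else bright <- ord[1L]
  dark <- setdiff(top2, bright)
  if (length(dark) == 0L) dark <- ord[2L]
  labels <- rep("other", length(dipole_norms))
  labels[bright] <- "pipi*"
  labels[dark[1L]] <- "npi*"
  attr(labels, "mixed") <- mixed
  labels
}

#' Geometry-ensemble averaged spectrum
#'
#' Pools the stick lists of all sampled geometries with weight
#' 1/N_geometries each and broadens the pooled sticks; by linearity this
#' equals the mean of the per-geometry broadened spectra.
#'
#' @param stick_lists list (one element per geometry) of stick data frames.
#' @inheritParams broaden
#' @return A `spectrum_grid`.
#' @export
ensemble_spectrum <- function(stick_lists, grid = energy_grid(), fwhm = 0.2,
                              normalize = FALSE) {
  stopifnot(length(stick_lists) >= 1L)
  pooled <- do.call(rbind, stick_lists)
  if (is.null(pooled))
    pooled <- data.frame(energy = numeric(0), height = numeric(0))
  pooled$height <- pooled$height / length(stick_lists)
  broaden(pooled, grid = grid, fwhm = fwhm, normalize = normalize)
}
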