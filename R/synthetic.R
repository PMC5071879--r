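# Synthetic fixtures: toy CI wavefunction pairs with controllable orbital
# overlap regimes, and trajectory ensembles with known pathway lifetimes.
# Everything is generated in code from a seed; no external data.

#' Toy-system specification
#'
#' @param n_spatial number of spatial orbitals.
#' @param n_electrons source-state electron count (`<= 2 * n_spatial`).
#' @param n_source_terms number of determinant terms in the source CI
#'   expansion (capped at the size of the spin sector).
#' @param n_ion_terms determinant terms per random ion state.
#' @param n_ion_states number of random ion states (ignored when
#'   `complete_ion = TRUE`).
#' @param regime orbital-overlap regime: `"identical"` (both MO sets equal
#'   and orthonormal), `"rotated"` (ion MOs are a random orthogonal
#'   rotation of the source MOs) or `"random-spd"` (independent MO sets,
#'   each orthonormalised against a random symmetric-positive-definite AO
#'   overlap).
#' @param complete_ion if `TRUE`, the ion family is the complete
#'   determinant basis of the (n-1)-electron space (both reachable spin
#'   sectors), enabling the completeness sum rule.
#' @param seed integer seed.
#' @return An object of class `toy_system_spec`.
#' @export
toy_system_spec <- function(n_spatial = 4, n_electrons = 3,
                            n_source_terms = 5, n_ion_terms = 4,
                            n_ion_states = 3,
                            regime = c("identical", "rotated", "random-spd"),
                            complete_ion = FALSE, seed = 1) {
  regime <- match.arg(regime)
  stopifnot(n_electrons >= 1, n_electrons <= 2 * n_spatial,
            n_source_terms >= 1, n_ion_terms >= 1, n_ion_states >= 1)
  structure(list(n_spatial = as.integer(n_spatial),
                 n_electrons = as.integer(n_electrons),
                 n_source_terms = as.integer(n_source_terms),
                 n_ion_terms = as.integer(n_ion_terms),
                 n_ion_states = as.integer(n_ion_states),
                 regime = regime, complete_ion = complete_ion,
                 seed = as.integer(seed)),
            class = "toy_system_spec")
}

# random orthogonal matrix with a deterministic sign fix
random_orthogonal <- function(n) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), n)
}

# orthonormalise the columns of X against metric S: t(C) S C = I
orthonormalize_against <- function(X, S) {
  G <- crossprod(X, S %*% X)
  e <- eigen(G, symmetric = TRUE)
  X %*% e$vectors %*% diag(1 / sqrt(e$values), ncol(X)) %*% t(e$vectors)
}

random_ci_vector <- function(dets, k) {
  idx <- if (length(dets) <= k) seq_along(dets) else sort(sample(length(dets), k))
  # CI coefficients of real multireference states span several orders of
  # magnitude, so draw signed magnitudes log-uniformly over ~2.5 decades;
  # this keeps screening thresholds in the 1e-4 region meaningful.
  coefs <- sign(stats::rnorm(length(idx))) * 10^stats::runif(length(idx), -2.5, 0)
  coefs <- coefs / sqrt(sum(coefs^2))
  list(dets = dets[idx], coefs = coefs)
}

#' Generate a toy CI wavefunction pair
#'
#' Builds a normalised random n-electron source state, an (n-1)-electron
#' ion family (random CI states, or the complete determinant basis of the
#' ionised space when `complete_ion = TRUE`) and the spatial-orbital
#' overlap matrix of the requested regime. Ion energies are placed at
#' 8-12 eV above the source so the states can also feed the spectra
#' module.
#'
#' @param spec a [toy_system_spec()].
#' @return List with `source` ([ci_state()]), `ions` (list of
#'   [ci_state()]), `overlap` ([orbital_overlap()]), the generating MO
#'   coefficient matrices `c_source`, `c_ion`, the AO overlap `s_ao`, and
#'   `spec`.
#' @export
make_toy_system <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  set.seed(spec$seed)
  n_sp <- spec$n_spatial
  n <- spec$n_electrons
  n_a <- ceiling(n / 2); n_b <- n - n_a
  basis_src <- spin_orbital_basis(n_sp, "source")
  basis_ion <- spin_orbital_basis(n_sp, "ion")

  src_dets <- all_determinants(n_sp, n_a, n_b)
  sv <- random_ci_vector(src_dets, spec$n_source_terms)
  source <- ci_state(basis_src, sv$dets, sv$coefs, energy = 0,
                     multiplicity = n_a - n_b + 1L, label = "S0")

  ion_sectors <- list(c(n_a - 1L, n_b), c(n_a, n_b - 1L))
  ion_sectors <- Filter(function(s) all(s >= 0) & all(s <= n_sp), ion_sectors)
  if (spec$complete_ion) {
    ion_dets <- unlist(lapply(ion_sectors, function(s)
      all_determinants(n_sp, s[1L], s[2L])), recursive = FALSE)
    ions <- lapply(seq_along(ion_dets), function(k)
      ci_state(basis_ion, ion_dets[k], 1, energy = 8 + 4 * (k - 1) / length(ion_dets),
               label = sprintf("D%d", k - 1L)))
  } else {
    sec <- ion_sectors[[1L]]
    ion_dets <- all_determinants(n_sp, sec[1L], sec[2L])
    ions <- lapply(seq_len(spec$n_ion_states), function(k) {
      iv <- random_ci_vector(ion_dets, spec$n_ion_terms)
      ci_state(basis_ion, iv$dets, iv$coefs,
               energy = 8 + 4 * (k - 1) / spec$n_ion_states,
               label = sprintf("D%d", k - 1L))
    })
  }

  if (spec$regime == "identical") {
    c_source <- diag(n_sp); c_ion <- diag(n_sp); s_ao <- diag(n_sp)
  } else if (spec$regime == "rotated") {
    c_source <- diag(n_sp); s_ao <- diag(n_sp)
    c_ion <- random_orthogonal(n_sp)
  } else {
    A <- matrix(stats::rnorm(n_sp * n_sp), n_sp, n_sp)
    s_ao <- crossprod(A) / n_sp + diag(n_sp) * 0.5
    c_source <- orthonormalize_against(matrix(stats::rnorm(n_sp * n_sp), n_sp, n_sp), s_ao)
    c_ion <- orthonormalize_against(matrix(stats::rnorm(n_sp * n_sp), n_sp, n_sp), s_ao)
  }
  overlap <- build_orbital_overlap(c_source, c_ion, s_ao,
                                   source_basis = basis_src, ion_basis = basis_ion)
  list(source = source, ions = ions, overlap = overlap,
       c_source = c_source, c_ion = c_ion, s_ao = s_ao, spec = spec)
}

#' Trajectory-ensemble specification
#'
#' Defines a synthetic surface-hopping-like ensemble: each trajectory is
#' assigned a mechanistic pathway (drawn by fraction), hops from the bright
#' state to the dark state at an exponentially distributed hop time, and
#' leaves the excited manifold (to a state whose ionization channel is
#' closed at the probe energy) at an exponentially distributed event time
#' with the pathway's lifetime.
#'
#' @param pathways data frame with columns `label`, `tau` (fs, > 0) and
#'   `fraction` (non-negative, summing to 1).
#' @param n_trajectories ensemble size.
#' @param dt time stride in fs (default 5).
#' @param t_max total simulated time in fs; must be a multiple of `dt`.
#' @param hop_tau bright-to-dark hop time constant in fs (default 25).
#' @param tautomer tautomer tag for every trajectory (default `"enol"`).
#' @param templates per-state channel templates: named list mapping each
#'   state label to `list(dE = , norm = )`, binding energy in eV and Dyson
#'   norm of its single ionization channel. The terminal state's channel
#'   should be closed at the probe energy.
#' @param seed integer seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(pathways, n_trajectories = 300, dt = 5, t_max = 1400,
                          hop_tau = 25, tautomer = "enol",
                          templates = list(
                            "pipi*" = list(dE = 4.2, norm = 0.76),
                            "npi*" = list(dE = 4.0, norm = 0.80),
                            "S0" = list(dE = 8.5, norm = 0.90)),
                          seed = 1) {
  stopifnot(is.data.frame(pathways),
            all(c("label", "tau", "fraction") %in% names(pathways)),
            all(pathways$tau > 0), all(pathways$fraction >= 0),
            abs(sum(pathways$fraction) - 1) < 1e-8,
            dt > 0, abs(t_max / dt - round(t_max / dt)) < 1e-9,
            length(templates) == 3L)
  structure(list(pathways = pathways, n_trajectories = as.integer(n_trajectories),
                 dt = dt, t_max = t_max, hop_tau = hop_tau,
                 tautomer = tautomer, templates = templates,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Shipped demonstration ensemble
#'
#' Three pathways with well-separated lifetimes spanning tens of
#' femtoseconds to more than a picosecond (60, 250 and 1100 fs), 100
#' trajectories per pathway on average, 5 fs stride, 1400 fs total time --
#' a deliberately multi-scale fixture for the lifetime-identifiability
#' demonstration.
#'
#' @param seed integer seed.
#' @return An [ensemble_spec()].
#' @export
demo_ensemble_spec <- function(seed = 1) {
  ensemble_spec(
    pathways = data.frame(label = c("fast-CI", "OOP", "ISC"),
                          tau = c(60, 250, 1100),
                          fraction = c(1, 1, 1) / 3),
    n_trajectories = 300, dt = 5, t_max = 1400, hop_tau = 25,
    tautomer = "enol", seed = seed)
}

#' Simulate a synthetic trajectory ensemble
#'
#' Draws pathway assignments, hop times and terminal event times per the
#' spec and materialises one [trajectory_record()] per trajectory: the
#' bright state carries weight 1 before the hop, the dark state between
#' hop and terminal event, and the terminal state afterwards; each state
#' contributes one ionization channel with the spec's template binding
#' energy and Dyson norm.
#'
#' @param spec an [ensemble_spec()].
#' @return List of [trajectory_record()].
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  times <- seq(0, spec$t_max, by = spec$dt)
  nt <- length(times)
  states <- names(spec$templates)
  bright <- states[1L]; dark <- states[2L]; terminal <- states[3L]
  n <- spec$n_trajectories
  path_idx <- sample(nrow(spec$pathways), n, replace = TRUE,
                     prob = spec$pathways$fraction)
  hop_times <- stats::rexp(n, rate = 1 / spec$hop_tau)
  event_times <- stats::rexp(n, rate = 1 / spec$pathways$tau[path_idx])
  energies <- matrix(0, nt, length(states), dimnames = list(NULL, states))
  channels <- lapply(states, function(s)
    list(source = s, ion = "D0", energy_ion = spec$templates[[s]]$dE,
         norm = spec$templates[[s]]$norm))
  lapply(seq_len(n), function(k) {
    w <- matrix(0, nt, length(states), dimnames = list(NULL, states))
    t_hop <- min(hop_times[k], event_times[k])
    w[, bright] <- as.numeric(times < t_hop)
    w[, dark] <- as.numeric(times >= t_hop & times < event_times[k])
    w[, terminal] <- as.numeric(times >= event_times[k])
    trajectory_record(id = sprintf("traj-%04d", k),
                      tautomer = spec$tautomer,
                      pathway = spec$pathways$label[path_idx[k]],
                      times = times, weights = w, energies = energies,
                      channels = channels)
  })
}

#' Diatomic harmonic model for sampler checks
#'
#' A minimal synthetic harmonic model: one stretching mode of a
#' heteronuclear diatomic, with the mass-weighted mode vector built
#' analytically. Useful as the smallest system on which the Wigner
#' sampler's per-mode statistics can be verified.
#'
#' @param wavenumber stretch wavenumber in cm^-1 (default 1600).
#' @param masses two atomic masses in amu (default C and O).
#' @param bond bond length in Angstrom (default 1.2).
#' @return A [harmonic_model()].
#' @export
synthetic_diatomic_model <- function(wavenumber = 1600, masses = c(12.011, 15.999),
                                     bond = 1.2) {
  geom <- c(0, 0, 0, bond, 0, 0)
  # mass-weighted stretch along x, orthogonal to the centre-of-mass motion
  v <- c(sqrt(1 / (1 + masses[1L] / masses[2L])), 0, 0,
         -sqrt(1 / (1 + masses[2L] / masses[1L])), 0, 0)
  v <- v / sqrt(sum(v^2))
  harmonic_model(geom, masses, wavenumber, matrix(v, ncol = 1))
}

#' Random polyatomic harmonic model (synthetic)
#'
#' A seeded random harmonic model with orthonormal mass-weighted modes,
#' for exercising the sampler on more than one mode.
#'
#' @param n_atoms number of atoms (default 3).
#' @param n_modes number of modes (default `3 * n_atoms - 6`).
#' @param seed integer seed.
#' @return A [harmonic_model()].
#' @export
synthetic_harmonic_model <- function(n_atoms = 3,
                                     n_modes = max(1, 3 * n_atoms - 6),
                                     seed = 1) {
  set.seed(as.integer(seed))
  geom <- stats::rnorm(3 * n_atoms, sd = 1)
  masses <- stats::runif(n_atoms, 1, 16)
  q <- random_orthogonal(3 * n_atoms)[, seq_len(n_modes), drop = FALSE]
  freqs <- sort(stats::runif(n_modes, 300, 3200))
  harmonic_model(geom, masses, freqs, q)
}
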