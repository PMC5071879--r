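# CI-type electronic states: linear combinations of Slater determinants in
# one spin-orbital basis, plus screening of CSF expansions.

#' CI state over Slater determinants
#'
#' @param basis a [spin_orbital_basis()].
#' @param dets list of normal-form occupation vectors (integer, strictly
#'   increasing), all with the same electron count.
#' @param coefs numeric CI coefficients, one per determinant.
#' @param energy state energy V (eV).
#' @param multiplicity spin multiplicity 2S+1 (informational).
#' @param label state label, e.g. `"S0"`, `"pipi*"`, `"D0"`.
#' @param diagnostics optional character vector of warnings carried with the
#'   state (e.g. a degenerate screened expansion).
#' @return An object of class `ci_state`.
#' @export
ci_state <- function(basis, dets, coefs, energy = NA_real_,
                     multiplicity = NA_integer_, label = "",
                     diagnostics = character(0)) {
  stopifnot(inherits(basis, "so_basis"), length(dets) == length(coefs))
  dets <- lapply(dets, function(d) sort(as.integer(d)))
  if (length(dets)) {
    n_el <- length(dets[[1L]])
    if (!all(vapply(dets, length, 0L) == n_el))
      stop("all determinants of a CI state must share one electron count")
    if (any(unlist(dets) > 2L * basis$n_spatial) || any(unlist(dets) < 1L))
      stop("spin-orbital index outside the basis")
    if (any(vapply(dets, anyDuplicated, 0L) > 0L))
      stop("determinant has a repeated spin-orbital index")
  } else n_el <- NA_integer_
  nrm2 <- sum(coefs^2)
  if (is.finite(nrm2) && nrm2 > 1 + 1e-8)
    stop(sprintf("squared CI norm %.10f exceeds 1", nrm2))
  structure(list(basis = basis, dets = dets, coefs = as.numeric(coefs),
                 n_electrons = n_el, energy = energy,
                 multiplicity = multiplicity, label = as.character(label),
                 diagnostics = diagnostics),
            class = "ci_state")
}

#' @export
print.ci_state <- function(x, ...) {
  cat(sprintf("<ci_state '%s': %d electrons, %d determinant terms, |c|^2 = %.6f>\n",
              x$label, x$n_electrons, length(x$dets), sum(x$coefs^2)))
  if (length(x$diagnostics)) cat("  diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}

#' Decompose a CSF-basis CI vector into a determinant-basis CI state
#'
#' CSF terms whose coefficient magnitude does not exceed `csf_threshold` are
#' dropped before expansion; determinant terms whose combined coefficient
#' magnitude does not exceed `keep_threshold` are dropped afterwards. Both
#' comparisons are strict (`> threshold` survives) and the surviving
#' expansion is *not* renormalised, so the squared norm of the result may be
#' below the squared norm of the input.
#'
#' @param csfs list of [csf()] objects.
#' @param coefs numeric CI coefficients in the CSF basis.
#' @param basis a [spin_orbital_basis()].
#' @param csf_threshold screening threshold applied to CSF coefficients
#'   (default `1e-4`).
#' @param keep_threshold screening threshold applied to the merged
#'   determinant coefficients (default `1e-4`).
#' @param screen `"abs"` (default) applies the thresholds to `|c|`;
#'   `"squared"` applies them to `c^2`.
#' @param energy,multiplicity,label passed to [ci_state()].
#' @return A [ci_state()]; if screening removes every term, the state is
#'   empty and carries a `"degenerate"` diagnostic instead of erroring.
#' @export
decompose_ci_state <- function(csfs, coefs, basis,
                               csf_threshold = 1e-4, keep_threshold = 1e-4,
                               screen = c("abs", "squared"),
                               energy = NA_real_, multiplicity = NA_integer_,
                               label = "") {
  screen <- match.arg(screen)
  stopifnot(length(csfs) == length(coefs), csf_threshold >= 0, keep_threshold >= 0)
  measure <- function(c) if (screen == "abs") abs(c) else c^2
  keep <- measure(coefs) > csf_threshold
  acc <- numeric(0)
  for (i in which(keep)) {
    ex <- expand_csf(csfs[[i]], basis)
    keys <- vapply(ex$dets, det_key, "")
    vals <- coefs[i] * ex$coefs
    for (j in seq_along(keys)) {
      k <- keys[j]
      acc[k] <- (if (k %in% names(acc)) acc[[k]] else 0) + vals[j]
    }
  }
  acc <- acc[measure(acc) > keep_threshold]
  diagnostics <- character(0)
  if (length(acc) == 0L && length(coefs) > 0L)
    diagnostics <- "degenerate: screening removed every determinant term"
  # deterministic ordering: lexicographic in the occupation vectors
  if (length(acc)) {
    dets <- lapply(names(acc), key_to_occ)
    ord <- order(vapply(dets, function(d) paste(sprintf("%04d", d), collapse = ","), ""))
    dets <- dets[ord]
    cc <- as.numeric(acc)[ord]
  } else {
    dets <- list(); cc <- numeric(0)
  }
  ci_state(basis, dets, cc, energy = energy, multiplicity = multiplicity,
           label = label, diagnostics = diagnostics)
}

#' Diagnose a CI state
#'
#' Pure diagnostics: electron-count consistency, squared norm, duplicate
#' determinant terms and basis range are reported; the state is never
#' modified and no error is thrown.
#'
#' @param state a [ci_state()].
#' @return A list with fields `ok` (logical), `checks` (named logical) and
#'   `messages` (character), plus the squared norm.
#' @export
validate_state <- function(state) {
  stopifnot(inherits(state, "ci_state"))
  msgs <- character(0)
  n_el_ok <- TRUE
  if (length(state$dets)) {
    lens <- vapply(state$dets, length, 0L)
    n_el_ok <- all(lens == state$n_electrons)
    if (!n_el_ok)
      msgs <- c(msgs, sprintf("electron-count mismatch: determinant lengths %s vs state %d",
                              paste(unique(lens), collapse = "/"), state$n_electrons))
  }
  keys <- vapply(state$dets, det_key, "")
  dup_ok <- !anyDuplicated(keys)
  if (!dup_ok) msgs <- c(msgs, "duplicate determinant terms present")
  rng_ok <- length(state$dets) == 0L ||
    all(unlist(state$dets) <= 2L * state$basis$n_spatial)
  if (!rng_ok) msgs <- c(msgs, "spin-orbital index outside the basis")
  nrm2 <- sum(state$coefs^2)
  nrm_ok <- nrm2 <= 1 + 1e-8
  if (!nrm_ok) msgs <- c(msgs, sprintf("squared norm %.8f exceeds 1", nrm2))
  checks <- c(electron_count = n_el_ok, no_duplicates = dup_ok,
              basis_range = rng_ok, norm = nrm_ok)
  list(ok = all(checks), checks = checks, messages = msgs, norm2 = nrm2)
}
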