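# Dyson orbitals and norms between an n-electron CI state and an
# (n-1)-electron CI state, with the two states allowed to use different,
# mutually non-orthogonal MO sets that share one AO basis.

#' Spatial-orbital overlap between two MO sets
#'
#' Builds the matrix of overlaps between the spatial orbitals of the source
#' (n-electron) MO set and the ion ((n-1)-electron) MO set over a common AO
#' basis: `t(C_source) %*% S_ao %*% C_ion`. Spin blocks are implicit: alpha
#' only overlaps alpha and beta only beta.
#'
#' @param c_source AO-by-MO coefficient matrix of the source set.
#' @param c_ion AO-by-MO coefficient matrix of the ion set.
#' @param s_ao symmetric positive semi-definite AO overlap matrix.
#' @param source_basis,ion_basis optional [spin_orbital_basis()] descriptors;
#'   defaults are created from the column counts.
#' @return An object of class `orbital_overlap` with fields `matrix`,
#'   `source_basis`, `ion_basis`.
#' @export
build_orbital_overlap <- function(c_source, c_ion, s_ao,
                                  source_basis = NULL, ion_basis = NULL) {
  c_source <- as.matrix(c_source); c_ion <- as.matrix(c_ion); s_ao <- as.matrix(s_ao)
  if (nrow(s_ao) != ncol(s_ao)) stop("AO overlap must be square")
  if (max(abs(s_ao - t(s_ao))) > 1e-10) stop("AO overlap must be symmetric")
  if (nrow(c_source) != nrow(s_ao) || nrow(c_ion) != nrow(s_ao))
    stop("dimension mismatch between MO coefficients and AO overlap")
  m <- crossprod(c_source, s_ao %*% c_ion)
  if (is.null(source_basis)) source_basis <- spin_orbital_basis(ncol(c_source), "source")
  if (is.null(ion_basis)) ion_basis <- spin_orbital_basis(ncol(c_ion), "ion")
  orbital_overlap(m, source_basis, ion_basis)
}

#' Construct an orbital-overlap object from a precomputed matrix
#' @param matrix spatial-orbital overlap matrix (source rows, ion columns).
#' @param source_basis,ion_basis [spin_orbital_basis()] descriptors.
#' @return An object of class `orbital_overlap`.
#' @export
orbital_overlap <- function(matrix, source_basis, ion_basis) {
  matrix <- as.matrix(matrix)
  stopifnot(inherits(source_basis, "so_basis"), inherits(ion_basis, "so_basis"))
  if (nrow(matrix) != source_basis$n_spatial || ncol(matrix) != ion_basis$n_spatial)
    stop("overlap matrix dimensions do not match the bases")
  if (!all(is.finite(matrix))) stop("overlap entries must be finite")
  structure(list(matrix = matrix, source_basis = source_basis, ion_basis = ion_basis),
            class = "orbital_overlap")
}

# determinant of a (possibly 0x0) square matrix
det0 <- function(m) if (length(m) == 0L) 1 else det(m)

#' Dyson contribution of one determinant pair
#'
#' For an n-electron source determinant and an (n-1)-electron ion
#' determinant, returns the vector of Dyson coefficients over the source
#' spin orbitals: coefficient(s) = (-1)^p(s) * det(M_s) for occupied s,
#' where p(s) counts the occupied spin orbitals preceding s in the ordering
#' convention and M_s is the spin-orbital overlap matrix between the source
#' determinant with s removed and the ion determinant. Because alpha and
#' beta orbitals never overlap, the determinant factorises into an
#' alpha-block and a beta-block determinant; a removal whose spin leaves the
#' per-spin electron counts unbalanced contributes zero.
#'
#' @param source_det,ion_det normal-form occupation vectors; the source must
#'   have exactly one electron more than the ion.
#' @param overlap an [orbital_overlap()].
#' @return Numeric vector of length `2 * n_spatial(source)`.
#' @export
determinant_pair_dyson <- function(source_det, ion_det, overlap) {
  stopifnot(inherits(overlap, "orbital_overlap"))
  src <- sort(as.integer(source_det)); ion <- sort(as.integer(ion_det))
  if (length(src) != length(ion) + 1L)
    stop("source determinant must have exactly one electron more than the ion")
  n_sp_s <- overlap$source_basis$n_spatial
  n_sp_i <- overlap$ion_basis$n_spatial
  s_mo <- overlap$matrix
  ion_a <- ion[ion <= n_sp_i]
  ion_b <- ion[ion > n_sp_i] - n_sp_i
  out <- numeric(2L * n_sp_s)
  src_a_n <- sum(src <= n_sp_s)
  src_b_n <- length(src) - src_a_n
  for (pos in seq_along(src)) {
    s <- src[pos]
    is_alpha <- s <= n_sp_s
    # spin balance after removal
    if (is_alpha) {
      if (src_a_n - 1L != length(ion_a) || src_b_n != length(ion_b)) next
    } else {
      if (src_a_n != length(ion_a) || src_b_n - 1L != length(ion_b)) next
    }
    rem <- src[-pos]
    rem_a <- rem[rem <= n_sp_s]
    rem_b <- rem[rem > n_sp_s] - n_sp_s
    da <- det0(s_mo[rem_a, ion_a, drop = FALSE])
    db <- det0(s_mo[rem_b, ion_b, drop = FALSE])
    sgn <- if ((pos - 1L) %% 2L == 0L) 1 else -1
    out[s] <- sgn * da * db
  }
  out
}

#' Dyson orbital and norm between two CI states
#'
#' Sums [determinant_pair_dyson()] contributions over all determinant pairs
#' (a, b) weighted by the product of their CI coefficients. Pairs with
#' `|c_a * d_b| <= pair_threshold` are skipped (strict `>` survives, per the
#' screening convention used throughout the package).
#'
#' @param source n-electron [ci_state()].
#' @param ion (n-1)-electron [ci_state()].
#' @param overlap an [orbital_overlap()] between the two MO sets.
#' @param pair_threshold screening threshold on the coefficient product
#'   (default `1e-4`; use 0 to disable screening).
#' @return An object of class `dyson_result`: list with `coefficients`
#'   (length `2 * n_spatial(source)`), `norm` (= sum of squared
#'   coefficients), `channel` (source and ion labels), `binding_energy`
#'   (eV, `V_ion - V_source` when both energies are known) and
#'   `pair_threshold`.
#' @export
#' @examples
#' b <- spin_orbital_basis(2)
#' src <- ci_state(b, list(c(1, 3)), 1, energy = 0, label = "S0")  # |1a 1b|
#' ion <- ci_state(b, list(1L), 1, energy = 9, label = "D0")       # |1a|
#' ov <- orbital_overlap(diag(2), b, b)
#' dyson_orbital(src, ion, ov)$norm  # Koopmans limit: 1
dyson_orbital <- function(source, ion, overlap, pair_threshold = 1e-4) {
  check_dyson_inputs(source, ion, overlap)
  n_so <- 2L * overlap$source_basis$n_spatial
  phi <- numeric(n_so)
  for (a in seq_along(source$dets)) {
    ca <- source$coefs[a]
    for (b in seq_along(ion$dets)) {
      w <- ca * ion$coefs[b]
      if (abs(w) <= pair_threshold) next
      phi <- phi + w * determinant_pair_dyson(source$dets[[a]], ion$dets[[b]], overlap)
    }
  }
  dyson_result(phi, source, ion, pair_threshold)
}

#' Brute-force Dyson orbital (test oracle)
#'
#' Same contract as [dyson_orbital()] with no screening, computed by a
#' route that shares no linear algebra with the main path: the annihilation
#' operator is applied in second quantisation and every determinant overlap
#' is evaluated as an explicit signed sum over permutations (no spin-block
#' factorisation, no LU determinants). Exponential cost; refuses systems
#' above `max_spin_orbitals`.
#'
#' @inheritParams dyson_orbital
#' @param max_spin_orbitals refusal bound on `2 * n_spatial(source)`
#'   (default 12).
#' @return A `dyson_result`, as for [dyson_orbital()].
#' @export
dyson_orbital_bruteforce <- function(source, ion, overlap, max_spin_orbitals = 12L) {
  check_dyson_inputs(source, ion, overlap)
  n_sp_s <- overlap$source_basis$n_spatial
  n_sp_i <- overlap$ion_basis$n_spatial
  if (2L * n_sp_s > max_spin_orbitals)
    stop(sprintf(paste0("system has %d spin orbitals, above the brute-force bound %d; ",
                        "use dyson_orbital() for production work"),
                 2L * n_sp_s, max_spin_orbitals))
  so_ov <- function(s_src, s_ion) {
    # spin-orbital overlap <source s_src | ion s_ion>
    a1 <- s_src <= n_sp_s; a2 <- s_ion <= n_sp_i
    if (a1 != a2) return(0)
    overlap$matrix[if (a1) s_src else s_src - n_sp_s,
                   if (a2) s_ion else s_ion - n_sp_i]
  }
  det_overlap <- function(bra, ket) {
    # <bra (ion) | ket (source, n-1 electrons)> by permutation expansion
    n <- length(bra)
    if (n != length(ket)) return(0)
    if (n == 0L) return(1)
    pp <- permutations(n)
    total <- 0
    for (r in seq_len(nrow(pp))) {
      p <- pp[r, ]
      term <- perm_sign(p)
      for (i in seq_len(n)) term <- term * so_ov(ket[p[i]], bra[i])
      total <- total + term
    }
    total
  }
  phi <- numeric(2L * n_sp_s)
  for (s in seq_len(2L * n_sp_s)) {
    acc <- 0
    for (a in seq_along(source$dets)) {
      ann <- annihilate_so(source$dets[[a]], s)
      if (is.null(ann)) next
      for (b in seq_along(ion$dets)) {
        acc <- acc + source$coefs[a] * ion$coefs[b] * ann$sign *
          det_overlap(ion$dets[[b]], ann$occ)
      }
    }
    phi[s] <- acc
  }
  dyson_result(phi, source, ion, pair_threshold = 0)
}

check_dyson_inputs <- function(source, ion, overlap) {
  stopifnot(inherits(source, "ci_state"), inherits(ion, "ci_state"),
            inherits(overlap, "orbital_overlap"))
  if (source$basis$n_spatial != overlap$source_basis$n_spatial ||
      ion$basis$n_spatial != overlap$ion_basis$n_spatial)
    stop("overlap matrix does not match the state bases")
  if (is.na(source$n_electrons) || is.na(ion$n_electrons) ||
      source$n_electrons != ion$n_electrons + 1L)
    stop("ionization channel requires n and n-1 electrons (source vs ion)")
  invisible(TRUE)
}

dyson_result <- function(coefficients, source, ion, pair_threshold) {
  structure(list(coefficients = coefficients,
                 norm = sum(coefficients^2),
                 channel = c(source = source$label, ion = ion$label),
                 binding_energy = ion$energy - source$energy,
                 pair_threshold = pair_threshold),
            class = "dyson_result")
}

#' @export
print.dyson_result <- function(x, ...) {
  cat(sprintf("<dyson_result %s -> %s: norm %.8f, dE %s eV>\n",
              x$channel[["source"]], x$channel[["ion"]], x$norm,
              if (is.na(x$binding_energy)) "NA" else sprintf("%.4f", x$binding_energy)))
  invisible(x)
}
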