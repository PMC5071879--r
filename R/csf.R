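# Configuration state functions (CSFs) and their Slater-determinant
# expansion. CSFs follow the genealogical (Yamanouchi-Kotani) coupling
# scheme: singly occupied orbitals, taken in ascending spatial order, are
# coupled one spin-1/2 at a time to intermediate total spins.

#' Configuration state function
#'
#' A spin-adapted configuration: spatial occupancies in \{0, 1, 2\} plus a
#' genealogical coupling vector with one entry per singly occupied orbital.
#' A coupling entry of `+1` raises the intermediate total spin by 1/2, `-1`
#' lowers it. The total spin S is `sum(coupling) / 2`.
#'
#' @param occupation integer vector of occupancies (0, 1 or 2) over the
#'   spatial orbitals of the basis, in ascending orbital order.
#' @param coupling integer vector of +1/-1 genealogical steps, one per
#'   singly occupied orbital. May be empty for closed shells.
#' @param m_s spin projection M_S; defaults to the total spin S.
#' @return An object of class `csf` with fields `occupation`, `coupling`,
#'   `S`, `M_S`, `n_electrons`.
#' @export
#' @examples
#' # open-shell singlet on orbitals 1 and 2
#' csf(c(1, 1), coupling = c(1, -1))
csf <- function(occupation, coupling = integer(0), m_s = NULL) {
  occupation <- as.integer(occupation)
  coupling <- as.integer(coupling)
  if (!all(occupation %in% 0:2)) stop("occupancies must be 0, 1 or 2")
  n_open <- sum(occupation == 1L)
  if (length(coupling) != n_open)
    stop("coupling vector length must equal the number of singly occupied orbitals")
  if (!all(coupling %in% c(-1L, 1L)))
    stop("coupling steps must be +1 or -1 (in units of spin 1/2)")
  two_s_path <- cumsum(coupling)
  if (any(two_s_path < 0L))
    stop("invalid genealogical coupling: intermediate spin below zero")
  S <- if (n_open) two_s_path[n_open] / 2 else 0
  if (is.null(m_s)) m_s <- S
  if (abs(m_s) > S + 1e-12 || abs(2 * m_s - round(2 * m_s)) > 1e-9 ||
      (n_open + round(2 * m_s)) %% 2L != 0L)
    stop(sprintf("M_S = %g is unreachable for this occupation/coupling", m_s))
  structure(list(occupation = occupation, coupling = coupling,
                 S = S, M_S = m_s, n_electrons = sum(occupation)),
            class = "csf")
}

#' @export
print.csf <- function(x, ...) {
  cat(sprintf("<csf: occ [%s], S=%g, M_S=%g>\n",
              paste(x$occupation, collapse = ""), x$S, x$M_S))
  invisible(x)
}

# Clebsch-Gordan coefficient for coupling an intermediate spin j1 with a
# single spin 1/2: <j1, M - m; 1/2, m | j, M>. Arguments in doubled-integer
# units to stay exact: two_j1, two_j = 2*j1, 2*j; two_m = +/-1; two_M = 2*M.
cg_couple_half <- function(two_j1, two_m, two_j, two_M) {
  j1 <- two_j1 / 2
  M <- two_M / 2
  den <- 2 * j1 + 1
  if (two_j == two_j1 + 1L) {
    if (two_m == 1L) sqrt((j1 + M + 0.5) / den) else sqrt((j1 - M + 0.5) / den)
  } else if (two_j == two_j1 - 1L) {
    if (two_m == 1L) -sqrt((j1 - M + 0.5) / den) else sqrt((j1 + M + 0.5) / den)
  } else stop("invalid coupling step")
}

#' Expand a CSF into Slater determinants
#'
#' Expands a genealogically coupled CSF into normal-form Slater determinants
#' with Clebsch-Gordan coefficients. The determinant phases follow the fixed
#' package convention: the CSF is defined as an ordered product of creation
#' operators over spatial orbitals ascending (alpha before beta within a
#' doubly occupied orbital), which is then reordered into the alpha-block /
#' beta-block normal form with the corresponding permutation sign.
#'
#' @param x a [csf()].
#' @param basis a [spin_orbital_basis()]; its `n_spatial` must cover the
#'   occupation vector.
#' @return A list with `dets` (list of normal-form occupation vectors) and
#'   `coefs` (numeric); `sum(coefs^2)` is 1 to machine precision.
#' @export
#' @examples
#' b <- spin_orbital_basis(2)
#' expand_csf(csf(c(1, 1), coupling = c(1, -1), m_s = 0), b)
expand_csf <- function(x, basis) {
  stopifnot(inherits(x, "csf"), inherits(basis, "so_basis"))
  n_sp <- basis$n_spatial
  if (length(x$occupation) != n_sp)
    stop("occupation vector length must equal n_spatial of the basis")
  open_orbs <- which(x$occupation == 1L)
  n_open <- length(open_orbs)
  two_M_target <- round(2 * x$M_S)

  # enumerate spin assignments m_k = +/-1/2 over the open shells
  if (n_open == 0L) {
    assignments <- matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    assignments <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n_open)))
    assignments <- assignments[rowSums(assignments) == two_M_target, , drop = FALSE]
  }
  two_s_path <- c(0L, cumsum(x$coupling))

  dets <- list()
  coefs <- numeric(0)
  for (r in seq_len(nrow(assignments))) {
    ms <- unname(assignments[r, ])
    coef <- 1
    two_M <- 0L
    for (k in seq_len(n_open)) {
      two_M <- two_M + ms[k]
      coef <- coef * cg_couple_half(two_s_path[k], ms[k], two_s_path[k + 1L], two_M)
      if (coef == 0) break
    }
    if (coef == 0) next
    # creation order: spatial orbitals ascending, alpha before beta
    order_list <- integer(0)
    for (p in seq_len(n_sp)) {
      if (x$occupation[p] == 2L) {
        order_list <- c(order_list, so_index(p, "alpha", n_sp), so_index(p, "beta", n_sp))
      } else if (x$occupation[p] == 1L) {
        k <- match(p, open_orbs)
        spin <- if (ms[k] == 1L) "alpha" else "beta"
        order_list <- c(order_list, so_index(p, spin, n_sp))
      }
    }
    dets[[length(dets) + 1L]] <- sort(order_list)
    coefs <- c(coefs, coef * perm_sign(order_list))
  }
  if (length(dets) == 0L)
    stop(sprintf("M_S = %g is unreachable for this occupation", x$M_S))
  # global phase convention: reordering the interleaved (alpha, beta) pairs
  # of the k doubly occupied orbitals into the block normal form costs
  # (-1)^C(k,2); cancel it so a closed shell comes out with coefficient +1.
  # (Only the overall sign of the CSF is affected; relative phases between
  # determinants are physical and untouched.)
  k2 <- sum(x$occupation == 2L)
  phase <- if ((k2 * (k2 - 1L) / 2L) %% 2L == 1L) -1 else 1
  list(dets = dets, coefs = phase * coefs)
}
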