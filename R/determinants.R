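# Spin-orbital bookkeeping and Slater determinants.
#
# Ordering convention (fixed package-wide): spin orbitals are indexed
# 1..2*n_spatial with the alpha block first (alpha of spatial orbital p has
# index p) followed by the beta block (beta of spatial orbital p has index
# n_spatial + p). A determinant in normal form lists its occupied spin
# orbitals strictly increasing; all annihilation/creation phases are counted
# in this ordering.

#' Spin-orbital basis descriptor
#'
#' Describes one set of `n_spatial` orthonormal spatial molecular orbitals
#' and fixes the spin-orbital ordering convention used by every determinant
#' that references it: alpha block ascending spatial index, then beta block
#' ascending spatial index.
#'
#' @param n_spatial number of spatial orbitals (>= 1).
#' @param mo_set_id identifier of the MO set (free text).
#' @return An object of class `so_basis`.
#' @export
#' @examples
#' b <- spin_orbital_basis(4, "cas-neutral")
#' so_index(2, "beta", b)  # 6
spin_orbital_basis <- function(n_spatial, mo_set_id = "mo") {
  n_spatial <- as.integer(n_spatial)
  stopifnot(length(n_spatial) == 1L, n_spatial >= 1L)
  structure(list(n_spatial = n_spatial, mo_set_id = as.character(mo_set_id)),
            class = "so_basis")
}

#' @export
print.so_basis <- function(x, ...) {
  cat(sprintf("<so_basis '%s': %d spatial / %d spin orbitals>\n",
              x$mo_set_id, x$n_spatial, 2L * x$n_spatial))
  invisible(x)
}

#' Spin-orbital index from spatial index and spin
#' @param spatial spatial orbital index (1-based).
#' @param spin `"alpha"` or `"beta"` (vectorised).
#' @param basis a [spin_orbital_basis()] (or its `n_spatial`).
#' @return Integer spin-orbital index in the package ordering convention.
#' @export
so_index <- function(spatial, spin, basis) {
  n_sp <- if (inherits(basis, "so_basis")) basis$n_spatial else as.integer(basis)
  spatial <- as.integer(spatial)
  stopifnot(all(spatial >= 1L), all(spatial <= n_sp), all(spin %in% c("alpha", "beta")))
  spatial + ifelse(spin == "beta", n_sp, 0L)
}

#' Spin of a spin-orbital index
#' @inheritParams so_index
#' @param so spin-orbital index.
#' @export
so_spin <- function(so, basis) {
  n_sp <- if (inherits(basis, "so_basis")) basis$n_spatial else as.integer(basis)
  ifelse(so <= n_sp, "alpha", "beta")
}

#' Spatial orbital of a spin-orbital index
#' @inheritParams so_spin
#' @export
so_spatial <- function(so, basis) {
  n_sp <- if (inherits(basis, "so_basis")) basis$n_spatial else as.integer(basis)
  ifelse(so <= n_sp, so, so - n_sp)
}

#' Normal-form Slater determinant
#'
#' @param occupied integer vector of occupied spin-orbital indices; must be
#'   distinct. Stored sorted strictly increasing (the phase normal form).
#' @return Integer vector of class `slater_det`.
#' @export
slater_det <- function(occupied) {
  occ <- as.integer(occupied)
  if (anyDuplicated(occ)) stop("determinant has a repeated spin-orbital index")
  structure(sort(occ), class = "slater_det")
}

det_key <- function(occ) paste(occ, collapse = ",")

# a_s |occ>: remove spin orbital s with phase (-1)^(number of occupied spin
# orbitals preceding s). Returns NULL when s is unoccupied.
annihilate_so <- function(occ, s) {
  pos <- match(s, occ)
  if (is.na(pos)) return(NULL)
  list(occ = occ[-pos], sign = if ((pos - 1L) %% 2L == 0L) 1 else -1)
}

# a_s^dagger |occ>: insert spin orbital s with the same phase convention.
create_so <- function(occ, s) {
  if (s %in% occ) return(NULL)
  pos <- sum(occ < s)
  list(occ = sort(c(occ, s)), sign = if (pos %% 2L == 0L) 1 else -1)
}

#' Enumerate all determinants of a spin sector
#'
#' All normal-form determinants with `n_alpha` alpha and `n_beta` beta
#' electrons in `n_spatial` spatial orbitals.
#'
#' @param n_spatial number of spatial orbitals.
#' @param n_alpha,n_beta electron counts per spin.
#' @return List of integer occupation vectors (normal form).
#' @export
all_determinants <- function(n_spatial, n_alpha, n_beta) {
  stopifnot(n_alpha <= n_spatial, n_beta <= n_spatial, n_alpha >= 0, n_beta >= 0)
  choose_occ <- function(k) {
    if (k == 0L) return(list(integer(0)))
    cmb <- utils::combn(n_spatial, k)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  av <- choose_occ(as.integer(n_alpha))
  bv <- choose_occ(as.integer(n_beta))
  out <- vector("list", length(av) * length(bv))
  i <- 0L
  for (a in av) for (b in bv) {
    i <- i + 1L
    out[[i]] <- as.integer(c(a, n_spatial + b))
  }
  out
}

# --- second-quantisation helpers on determinant expansions -----------------
# An expansion is a named numeric vector: names are det_key() strings of
# normal-form occupation vectors, values are coefficients. Used by the spin
# diagnostics and by the brute-force Dyson oracle; not performance critical.

expansion_from_terms <- function(dets, coefs) {
  v <- stats::setNames(as.numeric(coefs), vapply(dets, det_key, ""))
  tapply_sum(v)
}

tapply_sum <- function(v) {
  if (anyDuplicated(names(v))) {
    s <- tapply(v, names(v), sum)
    v <- stats::setNames(as.numeric(s), names(s))
  }
  v
}

key_to_occ <- function(key) {
  if (identical(key, "")) integer(0) else as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
}

# apply sum_p a^dagger_{p,to} a_{p,from} to an expansion (spin ladder step)
apply_spin_ladder <- function(expansion, n_spatial, from = "beta", to = "alpha") {
  out <- numeric(0)
  for (key in names(expansion)) {
    occ <- key_to_occ(key)
    c0 <- expansion[[key]]
    for (p in seq_len(n_spatial)) {
      s_from <- so_index(p, from, n_spatial)
      s_to <- so_index(p, to, n_spatial)
      a <- annihilate_so(occ, s_from)
      if (is.null(a)) next
      b <- create_so(a$occ, s_to)
      if (is.null(b)) next
      k <- det_key(b$occ)
      out[k] <- (if (k %in% names(out)) out[[k]] else 0) + c0 * a$sign * b$sign
    }
  }
  out[out != 0]
}

# <expansion| S^2 |expansion> assuming <expansion|expansion> = 1 not required;
# returns the full expansion of S^2 |psi> for comparison against S(S+1) psi.
apply_s2 <- function(expansion, n_spatial) {
  # S^2 = S_- S_+ + S_z (S_z + 1)
  up <- apply_spin_ladder(expansion, n_spatial, from = "beta", to = "alpha")
  down <- apply_spin_ladder(up, n_spatial, from = "alpha", to = "beta")
  out <- down
  for (key in names(expansion)) {
    occ <- key_to_occ(key)
    ms <- (sum(occ <= n_spatial) - sum(occ > n_spatial)) / 2
    val <- expansion[[key]] * ms * (ms + 1)
    out[key] <- (if (key %in% names(out)) out[[key]] else 0) + val
  }
  out[out != 0]
}
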