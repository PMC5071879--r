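# Dyson orbitals and norms: overlaps, pair contributions, screening,
# oracle agreement and the structural invariants

test_that("build_orbital_overlap reproduces the MO triple product", {
  b4 <- spin_orbital_basis(4)
  ov <- build_orbital_overlap(diag(4), diag(4), diag(4))
  expect_equal(ov$matrix, diag(4))

  swap <- diag(4)[, c(2, 1, 3, 4)]
  ov <- build_orbital_overlap(diag(4), swap, diag(4))
  expect_equal(ov$matrix, swap)

  set.seed(3)
  A <- matrix(rnorm(16), 4)
  s_ao <- crossprod(A) / 4 + diag(4) * 0.3
  cs <- dysonspec:::orthonormalize_against(matrix(rnorm(16), 4), s_ao)
  ci <- dysonspec:::orthonormalize_against(matrix(rnorm(16), 4), s_ao)
  ov <- build_orbital_overlap(cs, ci, s_ao)
  # element-wise independent triple product
  manual <- matrix(0, 4, 4)
  for (p in 1:4) for (q in 1:4)
    manual[p, q] <- sum(outer(cs[, p], ci[, q]) * s_ao)
  expect_equal(ov$matrix, manual, tolerance = 1e-12)
  # orthonormality of each set against the AO metric
  expect_equal(crossprod(cs, s_ao %*% cs), diag(4), tolerance = 1e-10)

  expect_error(build_orbital_overlap(diag(3), diag(4), diag(4)), "dimension")
})

test_that("determinant-pair contributions match Koopmans and hand-worked minors", {
  b2 <- spin_orbital_basis(2)
  id <- orbital_overlap(diag(2), b2, b2)

  # removing 2a from {1a, 2a, 1b} against ion {1a, 1b} leaves exactly spin
  # orbital 2a; the phase is (-1)^1 because 2a sits at position 2 of the
  # normal-form occupation list
  v <- determinant_pair_dyson(c(1L, 2L, 3L), c(1L, 3L), id)
  expect_equal(v, c(0, -1, 0, 0))
  expect_equal(sum(v^2), 1)

  # source |1a 1b|, ion |2a| orthogonal to everything occupied
  v <- determinant_pair_dyson(c(1L, 3L), 2L, id)
  expect_equal(v, rep(0, 4))

  # two alpha electrons, general overlap: signed 1x1 minors
  set.seed(7)
  s <- matrix(rnorm(4), 2)
  ov <- orbital_overlap(s, b2, b2)
  v <- determinant_pair_dyson(c(1L, 2L), 1L, ov)
  expect_equal(v, c(s[2, 1], -s[1, 1], 0, 0))

  expect_error(determinant_pair_dyson(c(1L, 2L, 3L), 1L, id), "exactly one electron")
})

test_that("dyson_orbital agrees with the brute-force oracle on random systems", {
  worst <- 0
  for (seed in 1:60) {
    toy <- make_toy_system(random_toy_spec(seed))
    for (ion in toy$ions) {
      a <- dyson_orbital(toy$source, ion, toy$overlap, pair_threshold = 0)
      b <- dyson_orbital_bruteforce(toy$source, ion, toy$overlap)
      worst <- max(worst, max(abs(a$coefficients - b$coefficients)),
                   abs(a$norm - b$norm))
      expect_equal(a$norm, sum(a$coefficients^2), tolerance = 1e-12)
      expect_gte(a$norm, 0)
      expect_lte(a$norm, toy$source$n_electrons + 1e-12)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("Koopmans limit gives norm 1 for every removable spin orbital", {
  b3 <- spin_orbital_basis(3)
  id <- orbital_overlap(diag(3), b3, b3)
  src_occ <- c(1L, 2L, 4L)  # 1a 2a 1b
  src <- ci_state(b3, list(src_occ), 1, energy = 0, label = "S")
  for (pos in seq_along(src_occ)) {
    ion <- ci_state(b3, list(src_occ[-pos]), 1, energy = 9, label = "D")
    res <- dyson_orbital(src, ion, id, pair_threshold = 0)
    expect_equal(res$norm, 1, tolerance = 1e-12)
    expect_equal(abs(res$coefficients[src_occ[pos]]), 1, tolerance = 1e-12)
  }
})

test_that("pair screening at 1e-4 vs 1e-7 changes norms by well under 1%", {
  for (seed in 1:20) {
    toy <- make_toy_system(random_toy_spec(seed + 100))
    for (ion in toy$ions) {
      loose <- dyson_orbital(toy$source, ion, toy$overlap, pair_threshold = 1e-4)$norm
      tight <- dyson_orbital(toy$source, ion, toy$overlap, pair_threshold = 1e-7)$norm
      if (tight > 1e-8)
        expect_lt(abs(loose - tight) / tight, 1e-2)
    }
  }
})

test_that("norms are invariant under occupied-space rotations and spin mirroring", {
  b3 <- spin_orbital_basis(3)
  # closed-shell determinant occupying spatial orbitals 1,2 in both spins,
  # so a rotation within the occupied spatial subspace leaves each spin
  # block invariant up to det(U) and the state up to det(U)^2 = 1
  src <- ci_state(b3, list(c(1L, 2L, 4L, 5L)), 1, energy = 0, label = "S")
  set.seed(21)
  ion <- local({
    dets <- all_determinants(3, 2, 1)
    cf <- rnorm(length(dets)); cf <- cf / sqrt(sum(cf^2))
    ci_state(b3, dets, cf, energy = 9, label = "D")
  })
  s_mo <- dysonspec:::random_orthogonal(3)
  ov <- orbital_overlap(s_mo, b3, b3)
  base <- dyson_orbital(src, ion, ov, 0)$norm

  # rotate the source MOs block-wise: occupied alpha-space {1,2} among
  # themselves, virtual {3} fixed; C' = C U implies S' = t(U) S
  th <- 0.7
  U <- diag(3); U[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ov_rot <- orbital_overlap(t(U) %*% s_mo, b3, b3)
  rot <- dyson_orbital(src, ion, ov_rot, 0)$norm
  expect_equal(rot, base, tolerance = 1e-10)

  # mirror all alpha <-> beta labels in both states: norms unchanged
  mirror <- function(occ, n_sp) sort(ifelse(occ <= n_sp, occ + n_sp, occ - n_sp))
  src_m <- ci_state(b3, lapply(src$dets, mirror, n_sp = 3), src$coefs,
                    energy = 0, label = "S")
  ion_m <- ci_state(b3, lapply(ion$dets, mirror, n_sp = 3), ion$coefs,
                    energy = 9, label = "D")
  mir <- dyson_orbital(src_m, ion_m, ov, 0)$norm
  expect_equal(mir, base, tolerance = 1e-10)

  # determinant occupation lists may come unsorted; the normal form fixes phases
  src_u <- ci_state(b3, list(c(4L, 1L, 5L, 2L)), 1, energy = 0, label = "S")
  expect_equal(dyson_orbital(src_u, ion, ov, 0)$norm, base, tolerance = 1e-12)
})

test_that("completeness sum rule holds for full-CI ion families", {
  for (n in 2:4) {
    spec <- toy_system_spec(n_spatial = 3, n_electrons = n, n_source_terms = 6,
                            complete_ion = TRUE, regime = "identical", seed = n)
    toy <- make_toy_system(spec)
    total <- sum(vapply(toy$ions, function(ion)
      dyson_orbital(toy$source, ion, toy$overlap, 0)$norm, 0))
    expect_equal(total, n, tolerance = 1e-8)
  }
})

test_that("the brute-force oracle refuses oversized systems", {
  b <- spin_orbital_basis(8)
  src <- ci_state(b, list(c(1L, 9L)), 1, label = "S")
  ion <- ci_state(b, list(1L), 1, label = "D")
  ov <- orbital_overlap(diag(8), b, b)
  expect_error(dyson_orbital_bruteforce(src, ion, ov), "brute-force bound")
})

test_that("electron-count and basis mismatches raise channel/shape errors", {
  b2 <- spin_orbital_basis(2)
  b3 <- spin_orbital_basis(3)
  src <- ci_state(b2, list(c(1L, 3L)), 1, label = "S")
  ion2 <- ci_state(b2, list(c(1L, 3L)), 1, label = "D")
  ov <- orbital_overlap(diag(2), b2, b2)
  expect_error(dyson_orbital(src, ion2, ov), "n and n-1")
  ion3 <- ci_state(b3, list(1L), 1, label = "D")
  expect_error(dyson_orbital(src, ion3, ov), "does not match")
})
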