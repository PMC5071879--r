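# Static spectra: amplitudes, sticks, broadening, mixing, classification,
# ensemble averaging

test_that("channel amplitudes are binding energy times Dyson norm", {
  expect_equal(as.numeric(channel_amplitude(0, 3)), 0)
  expect_equal(as.numeric(channel_amplitude(0.5, 2.0)), 1.0)
  w <- channel_amplitude(0.3, -1)
  expect_equal(as.numeric(w), 0)
  expect_true(attr(w, "closed"))
  set.seed(2)
  norms <- runif(20); dEs <- runif(20, -2, 10)
  w <- channel_amplitude(norms, dEs)
  expect_equal(as.numeric(w), ifelse(dEs < 0, 0, norms * dEs))
})

test_that("stick spectra place one stick per open channel", {
  b <- spin_orbital_basis(2)
  src <- ci_state(b, list(c(1L, 3L)), 1, energy = 0, label = "S0")
  mk_ion <- function(e, lbl) ci_state(b, list(1L), 1, energy = e, label = lbl)

  st <- stick_spectrum(src, list(mk_ion(8, "D0")), c(D0 = 0.8))
  expect_equal(st$energy, 8)
  expect_equal(st$height, 6.4)

  # ion below the source: closed, omitted
  st <- stick_spectrum(src, list(mk_ion(-1, "D0")), c(D0 = 0.8))
  expect_equal(nrow(st), 0)

  # composition against per-channel amplitudes
  set.seed(4)
  ions <- lapply(1:4, function(k) mk_ion(7 + k / 2, sprintf("D%d", k - 1)))
  norms <- runif(4)
  st <- stick_spectrum(src, ions, norms)
  dE <- sapply(ions, function(s) s$energy)
  expect_equal(st$height, as.numeric(channel_amplitude(norms, dE)))

  expect_error(stick_spectrum(src, ions, c(D0 = 1)), "missing Dyson norm")

  # global shift moves the axis only
  st2 <- stick_spectrum(src, ions, norms, shift = -0.8)
  expect_equal(st2$energy, st$energy - 0.8)
  expect_equal(st2$height, st$height)
})

test_that("broadening conserves stick weight and reproduces the stated FWHM", {
  g <- energy_grid(4, 12, 0.01)
  sp <- broaden(data.frame(energy = 8, height = 1), g, fwhm = 0.2)
  expect_equal(g[which.max(sp$intensity)], 8, tolerance = 1e-9)
  expect_equal(dysonspec:::measure_fwhm(sp$energy, sp$intensity), 0.2,
               tolerance = 0.01)
  expect_equal(dysonspec:::trapz(sp$energy, sp$intensity), 1, tolerance = 1e-6)

  # several sticks: integrated intensity equals summed heights
  set.seed(9)
  sticks <- data.frame(energy = runif(10, 6, 10), height = runif(10))
  sp <- broaden(sticks, g, fwhm = 0.2)
  expect_equal(dysonspec:::trapz(sp$energy, sp$intensity), sum(sticks$height),
               tolerance = 1e-6)

  # two sticks 0.1 eV apart with 0.2 eV FWHM merge into one local maximum
  sp <- broaden(data.frame(energy = c(8, 8.1), height = c(1, 1)), g, fwhm = 0.2)
  y <- sp$intensity
  n_max <- sum(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
               y[2:(length(y) - 1)] > y[3:length(y)])
  expect_equal(n_max, 1)

  # empty stick list: zero spectrum, no error
  sp <- broaden(data.frame(energy = numeric(0), height = numeric(0)), g, 0.2)
  expect_true(all(sp$intensity == 0))

  # sticks near the edge attach a coverage warning
  expect_warning(broaden(data.frame(energy = 4.05, height = 1), g, fwhm = 0.2),
                 "cover")
})

test_that("broadening is linear and positive", {
  g <- energy_grid(5, 11, 0.02)
  a <- data.frame(energy = c(7, 8), height = c(1, 0.5))
  b <- data.frame(energy = c(8.5, 9), height = c(0.3, 0.9))
  mixed <- rbind(transform(a, height = 2 * height),
                 transform(b, height = 3 * height))
  lhs <- broaden(mixed, g, 0.2)$intensity
  rhs <- 2 * broaden(a, g, 0.2)$intensity + 3 * broaden(b, g, 0.2)$intensity
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_true(all(lhs >= 0))
})

test_that("component mixing normalizes weights and honors provenance", {
  g <- energy_grid(6, 10, 0.02)
  mk <- function(e) broaden(data.frame(energy = e, height = 1), g, 0.2)
  sp <- list(keto = mk(7), syn = mk(7.5), anti = mk(8), imino = mk(8.5))
  w <- c(keto = 29, syn = 17, anti = 37, imino = 17)
  mixed <- mix_components(sp, w)
  expect_equal(unname(mixed$meta$fractions), c(0.29, 0.17, 0.37, 0.17))
  expect_equal(unname(mixed$meta$raw_weights), unname(w))

  # common rescaling of the weights changes nothing
  mixed10 <- mix_components(sp, 10 * w)
  expect_equal(mixed10$intensity, mixed$intensity, tolerance = 1e-14)

  # weight-1 component with zero-weight garbage is the identity
  garbage <- mk(9); garbage$intensity <- garbage$intensity * 100
  out <- mix_components(list(sp$keto, garbage), c(1, 0))
  expect_equal(out$intensity, sp$keto$intensity)

  bad <- mk(7); bad$energy <- bad$energy + 0.01
  expect_error(mix_components(list(sp$keto, bad), c(1, 1)), "different grids")
})

test_that("bright/dark classification follows the largest dipole norm", {
  expect_equal(as.character(classify_bright_dark(c(1.2, 0.1))), c("pipi*", "npi*"))
  lab <- classify_bright_dark(c(0.5, 0.5))
  expect_equal(as.character(lab), c("pipi*", "npi*"))  # tie: lower index bright
  expect_true(attr(lab, "mixed"))
  expect_error(classify_bright_dark(1.0), "at least two")

  set.seed(13)
  for (rep in 1:50) {
    norms <- runif(2 + rep %% 3, 0, 2)
    lab <- classify_bright_dark(norms, rel_tol = 0)
    expect_equal(which(lab == "pipi*"), which.max(norms))
  }
})

test_that("ensemble averaging equals the mean of broadened spectra", {
  g <- energy_grid(5, 11, 0.02)
  one <- data.frame(energy = c(7, 8), height = c(1, 2))
  same <- ensemble_spectrum(list(one, one, one), g, 0.2)
  expect_equal(same$intensity, broaden(one, g, 0.2)$intensity, tolerance = 1e-12)

  set.seed(17)
  lists <- lapply(1:50, function(i)
    data.frame(energy = runif(3, 6, 10), height = runif(3)))
  pooled <- ensemble_spectrum(lists, g, 0.2)
  mean_of <- Reduce(`+`, lapply(lists, function(s) broaden(s, g, 0.2)$intensity)) / 50
  expect_equal(pooled$intensity, mean_of, tolerance = 1e-12)
})

test_that("with equal norms the amplitude grows monotonically with binding energy", {
  b <- spin_orbital_basis(2)
  src <- ci_state(b, list(c(1L, 3L)), 1, energy = 0, label = "S0")
  ions <- lapply(1:4, function(k)
    ci_state(b, list(1L), 1, energy = 6 + k, label = sprintf("D%d", k - 1)))
  st <- stick_spectrum(src, ions, rep(0.5, 4))
  expect_true(all(diff(st$height[order(st$energy)]) > 0))
})
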