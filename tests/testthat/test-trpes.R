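# TRPES assembly, convolution, integration and decomposition

test_that("per-frame channel intensities follow the open-channel arithmetic", {
  tr <- toy_trajectory(times = seq(0, 50, 5), hop = 30,
                       dE = c(a = 6.0, b = 4.0, gs = 9.0),
                       norm = c(a = 0.5, b = 0.7, gs = 0.9))
  # frame 1: only state a populated, its channel (dE 6.0) is closed at 5.4 eV
  st <- step_channel_intensities(tr, 1, probe = 5.4, mode = "norm")
  expect_equal(nrow(st), 0)
  # frame 8 (t = 35): state b populated, dE 4.0 open -> E_kin 1.4, bare norm 0.7
  st <- step_channel_intensities(tr, 8, probe = 5.4, mode = "norm")
  expect_equal(st$ekin, 1.4)
  expect_equal(st$intensity, 0.7)
  expect_equal(st$state, "b")
  # amplitude mode multiplies by the binding energy
  st <- step_channel_intensities(tr, 8, probe = 5.4, mode = "amplitude")
  expect_equal(st$intensity, 4.0 * 0.7)
})

test_that("fractional weights produce hand-computed weighted intensities", {
  times <- seq(0, 20, 5); nt <- length(times)
  w <- matrix(0, nt, 2, dimnames = list(NULL, c("a", "b")))
  w[, "a"] <- 0.6; w[, "b"] <- 0.4
  en <- matrix(0, nt, 2, dimnames = list(NULL, c("a", "b")))
  channels <- list(list(source = "a", ion = "D0", energy_ion = 4.0, norm = 0.5),
                   list(source = "b", ion = "D0", energy_ion = 3.0, norm = 0.8))
  tr <- trajectory_record("x", "enol", "OOP", times, w, en, channels)
  st <- step_channel_intensities(tr, 2, probe = 5.4, mode = "norm")
  st <- st[order(st$state), ]
  expect_equal(st$intensity, c(0.6 * 0.5, 0.4 * 0.8))
  expect_equal(st$ekin, c(1.4, 2.4))
})

test_that("a constant single trajectory gives a time-constant broadened spectrum", {
  tr <- toy_trajectory(times = seq(0, 100, 5), hop = Inf)  # stays in state a
  g <- assemble_trpes(list(tr), probe = 5.4, efwhm = 0.2,
                      tautomer_weights = c(enol = 1))
  expect_equal(dim(g$intensity), c(21L, length(g$ekin)))
  for (i in 2:21) expect_equal(g$intensity[i, ], g$intensity[1, ], tolerance = 1e-12)
  # matches broadening the stick directly (dE 4.0, W = 4.0 * 0.8)
  ref <- broaden(data.frame(energy = 5.4 - 4.0, height = 4.0 * 0.8),
                 g$ekin, fwhm = 0.2)
  expect_equal(g$intensity[1, ], ref$intensity, tolerance = 1e-10)
})

test_that("decomposition slices sum to the total and match subset assembly", {
  set.seed(31)
  mk <- function(id, pathway, hop, stop_t)
    toy_trajectory(id, pathway, "enol", seq(0, 200, 5), hop = hop, stop_t = stop_t)
  ens <- list(mk("t1", "OOP", 40, 120), mk("t2", "OOP", 25, 180),
              mk("t3", "ISC", 60, 90), mk("t4", "ISC", 10, 150),
              mk("t5", "C6", 35, Inf))
  g <- assemble_trpes(ens, probe = 5.4, tautomer_weights = c(enol = 1))
  for (by in c("state", "pathway", "tautomer")) {
    sl <- trpes_decompose(g, by)
    expect_lt(max(abs(Reduce(`+`, sl) - g$intensity)), 1e-8)
  }
  # pathway slices equal assembling each subset alone, rescaled by the
  # subset's share of the ensemble
  for (p in c("OOP", "ISC", "C6")) {
    sub <- Filter(function(tr) tr$pathway == p, ens)
    gs <- assemble_trpes(sub, probe = 5.4, tautomer_weights = c(enol = 1))
    expect_equal(trpes_decompose(g, "pathway")[[p]],
                 gs$intensity * length(sub) / length(ens), tolerance = 1e-10)
  }
})

test_that("assembly is linear in sub-ensembles", {
  mk <- function(id, hop, stop_t)
    toy_trajectory(id, "OOP", "enol", seq(0, 100, 5), hop = hop, stop_t = stop_t)
  e1 <- list(mk("a1", 20, 60), mk("a2", 35, 80))
  e2 <- list(mk("b1", 50, 90), mk("b2", 15, 40))
  g12 <- assemble_trpes(c(e1, e2), 5.4, tautomer_weights = c(enol = 1))
  g1 <- assemble_trpes(e1, 5.4, tautomer_weights = c(enol = 1))
  g2 <- assemble_trpes(e2, 5.4, tautomer_weights = c(enol = 1))
  expect_equal(g12$intensity, (g1$intensity + g2$intensity) / 2, tolerance = 1e-12)
})

test_that("tautomer weights and contributing-count normalization are applied", {
  mk <- function(id, taut, t_end)
    toy_trajectory(id, "OOP", taut, seq(0, t_end, 5), hop = Inf, stop_t = Inf)
  ens <- list(mk("k1", "keto", 100), mk("e1", "enol", 100), mk("e2", "enol", 50))
  g <- assemble_trpes(ens, 5.4, tautomer_weights = c(keto = 35, enol = 65))
  sl <- trpes_decompose(g, "tautomer")
  # time-bin 1: both enol trajectories contribute, each with weight 0.65/2
  # time-bin 21 (t = 100): only e1 covers it, weight 0.65/1 -- the enol slice
  # is identical because the per-bin normalization compensates
  expect_equal(sl$enol[21, ], sl$enol[1, ], tolerance = 1e-12)
  # keto/enol ratio of the slice integrals at bin 1 is 35/65
  expect_equal(sum(sl$keto[1, ]) / sum(sl$enol[1, ]), 35 / 65, tolerance = 1e-10)
  # total-count normalization: once e2 has ended, the enol signal halves
  g_tot <- assemble_trpes(ens, 5.4, tautomer_weights = c(keto = 35, enol = 65),
                          normalization = "total")
  sl_tot <- trpes_decompose(g_tot, "tautomer")
  expect_equal(sl_tot$enol[21, ], sl_tot$enol[1, ] / 2, tolerance = 1e-12)
})

test_that("mixed strides and start times are refused", {
  t1 <- toy_trajectory("a", times = seq(0, 50, 5))
  t2 <- toy_trajectory("b", times = seq(0, 50, 10))
  expect_error(assemble_trpes(list(t1, t2), 5.4, tautomer_weights = c(enol = 1)),
               "mixed trajectory strides")
  t3 <- toy_trajectory("c", times = seq(5, 55, 5))
  expect_error(assemble_trpes(list(t1, t3), 5.4, tautomer_weights = c(enol = 1)),
               "start time")
})

test_that("raising the probe energy never closes an open channel", {
  tr <- toy_trajectory(times = seq(0, 50, 5), hop = 25,
                       dE = c(a = 4.0, b = 5.0, gs = 9.0))
  probes <- c(4.5, 5.4, 7.0, 10.0)
  n_open <- sapply(probes, function(p)
    nrow(step_channel_intensities(tr, 3, probe = p, mode = "norm")))
  expect_true(all(diff(n_open) >= 0))
})

test_that("time convolution reproduces the stated FWHM and conserves signal", {
  times <- seq(0, 2000, 5)
  mk_grid <- function(y) {
    structure(list(time = times, ekin = c(1, 1.02),
                   intensity = cbind(y, y), slices = list(),
                   meta = list(probe = 5.4, efwhm = 0.2)),
              class = "trpes_grid")
  }
  # impulse -> Gaussian with FWHM 160 fs
  imp <- rep(0, length(times)); imp[which(times == 1000)] <- 1
  gc <- convolve_time(mk_grid(imp), 160)
  expect_equal(dysonspec:::measure_fwhm(times, gc$intensity[, 1]), 160,
               tolerance = 5 / 160)
  # constant signal unchanged in the interior
  gc <- convolve_time(mk_grid(rep(2.5, length(times))), 160)
  interior <- times > 500 & times < 1500
  expect_lt(max(abs(gc$intensity[interior, 1] - 2.5)), 1e-8)
  # time-integrated signal conserved in the interior for a compact bump
  bump <- exp(-((times - 1000) / 80)^2)
  gc <- convolve_time(mk_grid(bump), 160)
  expect_equal(sum(gc$intensity[, 1]) * 5, sum(bump) * 5, tolerance = 1e-6)
})

test_that("Gaussian x exponential convolution matches the closed form", {
  dt <- 1
  times <- seq(0, 3000, dt)
  tau <- 500; fwhm <- 160
  sigma <- dysonspec:::fwhm_to_sigma(fwhm)
  y <- exp(-times / tau)
  conv <- convolve_trace(y, dt, fwhm, before = "zero", after = "edge")
  interior <- times >= 3 * fwhm & times <= max(times) - 3 * fwhm
  analytic <- emg_profile(times, tau, sigma)
  expect_lt(max(abs(conv[interior] - analytic[interior])), 1e-6)
})

test_that("energy integration matches quadrature and respects the window", {
  times <- seq(0, 50, 5)
  ekin <- seq(0, 5.4, 0.02)
  flat <- matrix(1, length(times), length(ekin))
  g <- structure(list(time = times, ekin = ekin, intensity = flat,
                      slices = list(), meta = list(probe = 5.4)),
                 class = "trpes_grid")
  tr <- integrate_energy(g, c(0, 4))
  expect_equal(tr$total, rep(4, length(times)), tolerance = 1e-12)

  # signal entirely above the window integrates to zero
  hi <- flat * 0; hi[, ekin > 4.5] <- 1
  g$intensity <- hi
  expect_equal(max(integrate_energy(g, c(0, 4))$total), 0)

  # random grid equals an independent fine-quadrature value
  set.seed(41)
  sticks <- data.frame(energy = runif(5, 0.5, 3.5), height = runif(5))
  coarse <- broaden(sticks, ekin, 0.2)$intensity
  g$intensity <- matrix(coarse, length(times), length(ekin), byrow = TRUE)
  got <- integrate_energy(g, c(0, 4))$total[1]
  fine_grid <- seq(0, 4, 2e-4)
  fine <- dysonspec:::trapz(fine_grid, broaden(sticks, fine_grid, 0.2)$intensity)
  expect_equal(got, fine, tolerance = 1e-5)

  expect_warning(integrate_energy(g, c(0, 10)), "clipped")
  suppressWarnings(expect_error(integrate_energy(g, c(10, 11)), "empty"))
})

test_that("missing attributions raise an instructive error", {
  g <- structure(list(time = 1:3, ekin = c(1, 2), intensity = matrix(0, 3, 2),
                      slices = list(), meta = list()),
                 class = "trpes_grid")
  expect_error(trpes_decompose(g, "pathway"), "re-assemble")
})
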