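# Time-resolved photoelectron spectra from surface-hopping trajectory
# ensembles: per-step channel intensities, (time, kinetic energy) gridding
# with Gaussian energy broadening, time-domain convolution with the
# instrument response, energy-window integration and decomposition by
# neutral state, mechanistic pathway or tautomer.

#' Trajectory record
#'
#' Per-trajectory time series consumed by [assemble_trpes()]: at every time
#' step the spin-mixed weights of the neutral states (summing to 1), their
#' potential energies, and one Dyson norm + ion potential per ionization
#' channel.
#'
#' @param id trajectory identifier.
#' @param tautomer tautomer tag (e.g. `"keto"`, `"enol"`).
#' @param pathway mechanistic pathway label (e.g. `"OOP"`, `"SP"`, `"C6"`,
#'   `"3st-CI"`, `"ISC"`, `"inactive"`).
#' @param times strictly increasing, uniformly strided times in fs.
#' @param weights n_times-by-n_states matrix of state weights w_j(t); rows
#'   must sum to 1 within 1e-6. Column names are the state labels.
#' @param energies n_times-by-n_states matrix of neutral potentials V_j(t)
#'   in eV (column order as `weights`).
#' @param channels list of channels; each channel is a list with fields
#'   `source` (neutral state label), `ion` (ion state label), `energy_ion`
#'   (V_alpha(t), eV; scalar recycled or length n_times) and `norm` (Dyson
#'   norm, scalar recycled or length n_times).
#' @return An object of class `trajectory_record`.
#' @export
trajectory_record <- function(id, tautomer, pathway, times, weights, energies,
                              channels) {
  times <- as.numeric(times)
  weights <- as.matrix(weights); energies <- as.matrix(energies)
  nt <- length(times)
  stopifnot(nt >= 1, nrow(weights) == nt, nrow(energies) == nt,
            ncol(weights) == ncol(energies))
  if (nt > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(abs(dt - dt[1L])) > 1e-9 * max(dt[1L], 1))
      stop("trajectory stride must be uniform")
  }
  if (is.null(colnames(weights))) stop("weights must carry state labels as column names")
  if (max(abs(rowSums(weights) - 1)) > 1e-6)
    stop("state weights must sum to 1 at every step (within 1e-6)")
  if (any(weights < -1e-12)) stop("state weights must be non-negative")
  channels <- lapply(channels, function(ch) {
    stopifnot(!is.null(ch$source), !is.null(ch$ion))
    if (!ch$source %in% colnames(weights))
      stop(sprintf("channel source state '%s' not among trajectory states", ch$source))
    ch$energy_ion <- rep_len(as.numeric(ch$energy_ion), nt)
    ch$norm <- rep_len(as.numeric(ch$norm), nt)
    ch
  })
  structure(list(id = id, tautomer = tautomer, pathway = pathway,
                 times = times, weights = weights, energies = energies,
                 channels = channels),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("<trajectory_record '%s' [%s/%s]: %d steps x %.0f fs, %d channels>\n",
              x$id, x$tautomer, x$pathway, length(x$times),
              if (length(x$times) > 1) diff(x$times)[1] else 0, length(x$channels)))
  invisible(x)
}

#' Channel intensities of one trajectory frame
#'
#' For every channel (j, alpha) with binding energy
#' `dE = V_alpha(t) - V_j(t)` not exceeding the probe photon energy, the
#' photoelectron appears at `E_kin = probe - dE` with intensity
#' `w_j * A_{j,alpha}`, where A is either the amplitude `dE * norm`
#' (default, consistent with the static spectra) or the bare Dyson norm.
#' Channels with `E_kin < 0` or `dE < 0` are omitted.
#'
#' @param record a [trajectory_record()].
#' @param time_index frame index into `record$times`.
#' @param probe probe photon energy in eV.
#' @param mode `"amplitude"` (default) uses `dE * norm`; `"norm"` uses the
#'   bare Dyson norm.
#' @return Data frame with columns `ekin`, `intensity`, `state`, `ion`.
#' @export
step_channel_intensities <- function(record, time_index, probe,
                                     mode = c("amplitude", "norm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "trajectory_record"), probe > 0,
            time_index >= 1, time_index <= length(record$times))
  out <- lapply(record$channels, function(ch) {
    vj <- record$energies[time_index, ch$source]
    dE <- ch$energy_ion[time_index] - vj
    if (dE < 0 || dE > probe) return(NULL)
    w <- record$weights[time_index, ch$source]
    if (w <= 0) return(NULL)
    a <- if (mode == "amplitude") dE * ch$norm[time_index] else ch$norm[time_index]
    data.frame(ekin = probe - dE, intensity = w * a,
               state = ch$source, ion = ch$ion, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(ekin = numeric(0), intensity = numeric(0),
                      state = character(0), ion = character(0))
  out
}

# vectorised stick table of a whole trajectory: one row per (frame, open channel)
traj_stick_table <- function(record, probe, mode) {
  nt <- length(record$times)
  pieces <- lapply(record$channels, function(ch) {
    dE <- ch$energy_ion - record$energies[, ch$source]
    w <- record$weights[, ch$source]
    open <- dE >= 0 & dE <= probe & w > 0
    if (!any(open)) return(NULL)
    a <- if (mode == "amplitude") dE * ch$norm else ch$norm
    data.frame(time = record$times[open], ekin = probe - dE[open],
               intensity = (w * a)[open], state = ch$source,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(time = numeric(0), ekin = numeric(0),
                      intensity = numeric(0), state = character(0))
  out
}

#' Assemble a time-resolved photoelectron spectrum from an ensemble
#'
#' Pools the per-frame channel sticks of all trajectories onto a common
#' (time, kinetic energy) grid and applies Gaussian broadening along the
#' energy axis only. Trajectories are weighted by tautomer abundance and,
#' within a tautomer, by 1/N where N is by default the number of
#' trajectories still covering the time bin (so shorter trajectories
#' contribute only to the bins they cover). Decomposition slices by neutral
#' state (fractional, via the state weights), by pathway and by tautomer
#' are attached.
#'
#' @param ensemble list of [trajectory_record()]; all trajectories must
#'   share one stride and start time.
#' @param probe probe photon energy in eV (e.g. 5.4).
#' @param ekin_grid uniform kinetic-energy grid in eV; default
#'   `seq(0, probe, 0.02)`.
#' @param efwhm energy-broadening FWHM in eV (default 0.2).
#' @param tautomer_weights named non-negative weights over tautomer tags
#'   (default `c(keto = 35, enol = 65)`); normalised over the tags present.
#' @param mode intensity mode passed to the stick builder: `"amplitude"`
#'   (default) or `"norm"`.
#' @param normalization `"contributing"` (default) divides by the number of
#'   trajectories covering each time bin; `"total"` divides by the total
#'   trajectory count of the tautomer.
#' @return An object of class `trpes_grid`: list with `time`, `ekin`,
#'   `intensity` (time-by-energy matrix), `slices` (lists of matrices keyed
#'   by state / pathway / tautomer) and `meta`.
#' @export
assemble_trpes <- function(ensemble, probe,
                           ekin_grid = NULL, efwhm = 0.2,
                           tautomer_weights = c(keto = 35, enol = 65),
                           mode = c("amplitude", "norm"),
                           normalization = c("contributing", "total")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  stopifnot(length(ensemble) >= 1, probe > 0, efwhm > 0)
  if (is.null(ekin_grid)) ekin_grid <- seq(0, probe, by = 0.02)
  strides <- vapply(ensemble, function(tr)
    if (length(tr$times) > 1) diff(tr$times)[1L] else NA_real_, 0)
  strides <- strides[!is.na(strides)]
  if (length(strides) && max(strides) - min(strides) > 1e-9)
    stop("mixed trajectory strides; resampling is refused -- align the inputs first")
  t0 <- vapply(ensemble, function(tr) tr$times[1L], 0)
  if (max(t0) - min(t0) > 1e-9) stop("trajectories must share a common start time")
  dt <- if (length(strides)) strides[1L] else 1
  t_end <- max(vapply(ensemble, function(tr) tr$times[length(tr$times)], 0))
  time_axis <- seq(t0[1L], t_end, by = dt)
  nt <- length(time_axis)

  tags <- unique(vapply(ensemble, function(tr) tr$tautomer, ""))
  if (!all(tags %in% names(tautomer_weights)))
    stop("tautomer_weights must name every tautomer present: missing ",
         paste(setdiff(tags, names(tautomer_weights)), collapse = ", "))
  wt <- tautomer_weights[tags]
  wt <- wt / sum(wt)

  bin_of <- function(t) as.integer(round((t - time_axis[1L]) / dt)) + 1L
  # coverage counts per tautomer per bin
  cover <- matrix(0, nt, length(tags), dimnames = list(NULL, tags))
  for (tr in ensemble) {
    idx <- bin_of(tr$times)
    cover[idx, tr$tautomer] <- cover[idx, tr$tautomer] + 1
  }
  total_count <- table(factor(vapply(ensemble, function(tr) tr$tautomer, ""),
                              levels = tags))

  sticks <- vector("list", length(ensemble))
  for (k in seq_along(ensemble)) {
    tr <- ensemble[[k]]
    st <- traj_stick_table(tr, probe, mode)
    if (nrow(st) == 0) next
    st$bin <- bin_of(st$time)
    denom <- if (normalization == "contributing") cover[st$bin, tr$tautomer]
             else as.numeric(total_count[[tr$tautomer]])
    st$weight <- st$intensity * wt[[tr$tautomer]] / denom
    st$pathway <- tr$pathway
    st$tautomer <- tr$tautomer
    sticks[[k]] <- st[, c("bin", "ekin", "weight", "state", "pathway", "tautomer")]
  }
  sticks <- do.call(rbind, sticks)

  sigma <- fwhm_to_sigma(efwhm)
  ne <- length(ekin_grid)
  total <- matrix(0, nt, ne)
  slice_names <- list(state = character(0), pathway = character(0),
                      tautomer = character(0))
  slices <- list(state = list(), pathway = list(), tautomer = list())
  if (!is.null(sticks) && nrow(sticks) > 0) {
    for (b in sort(unique(sticks$bin))) {
      sb <- sticks[sticks$bin == b, ]
      dens <- outer(sb$ekin, ekin_grid, function(e, g) stats::dnorm(g, e, sigma)) *
        sb$weight
      if (!is.matrix(dens)) dens <- matrix(dens, nrow = nrow(sb))
      total[b, ] <- colSums(dens)
      for (by in names(slices)) {
        grp <- rowsum(dens, sb[[by]])
        for (g in rownames(grp)) {
          if (is.null(slices[[by]][[g]])) slices[[by]][[g]] <- matrix(0, nt, ne)
          slices[[by]][[g]][b, ] <- slices[[by]][[g]][b, ] + grp[g, ]
        }
      }
    }
  }
  structure(list(time = time_axis, ekin = ekin_grid, intensity = total,
                 slices = slices,
                 meta = list(probe = probe, efwhm = efwhm, tfwhm = NULL,
                             mode = mode, normalization = normalization,
                             tautomer_fractions = wt)),
            class = "trpes_grid")
}

#' @export
print.trpes_grid <- function(x, ...) {
  cat(sprintf("<trpes_grid: %d time bins x %d energy bins, probe %.2f eV%s>\n",
              length(x$time), length(x$ekin), x$meta$probe,
              if (!is.null(x$meta$tfwhm)) sprintf(", time FWHM %.0f fs", x$meta$tfwhm) else ""))
  invisible(x)
}

#' Convolve a trace with a Gaussian instrument response
#'
#' Discrete unit-sum Gaussian kernel on the trace's own stride. The signal
#' is taken as zero before the first frame (no signal before the pump) and
#' continued by its edge value after the last frame; both policies are
#' configurable.
#'
#' @param y numeric trace sampled on a uniform grid.
#' @param dt grid stride (same time unit as `fwhm`).
#' @param fwhm Gaussian FWHM of the response.
#' @param before,after boundary policy, `"zero"` or `"edge"`.
#' @return Convolved trace, same length as `y`.
#' @export
convolve_trace <- function(y, dt, fwhm, before = "zero", after = "edge") {
  stopifnot(fwhm > 0, dt > 0)
  sigma <- fwhm_to_sigma(fwhm)
  half <- max(1L, ceiling(6 * sigma / dt))
  kern <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  kern <- kern / sum(kern)
  padL <- switch(match.arg(before, c("zero", "edge")),
                 zero = rep(0, half), edge = rep(y[1L], half))
  padR <- switch(match.arg(after, c("edge", "zero")),
                 zero = rep(0, half), edge = rep(y[length(y)], half))
  yy <- c(padL, y, padR)
  as.numeric(stats::filter(yy, kern, sides = 2))[(half + 1L):(half + length(y))]
}

#' Time-domain convolution of a TRPES grid
#'
#' Convolves every energy column (and every attached decomposition slice)
#' with a unit-area Gaussian of the given FWHM, emulating the pump-probe
#' cross-correlation.
#'
#' @param grid a `trpes_grid` from [assemble_trpes()].
#' @param fwhm temporal FWHM in fs (e.g. 160).
#' @param before,after boundary policies, see [convolve_trace()].
#' @return The convolved `trpes_grid`; `meta$tfwhm` records the width.
#' @export
convolve_time <- function(grid, fwhm, before = "zero", after = "edge") {
  stopifnot(inherits(grid, "trpes_grid"), fwhm > 0)
  dtv <- diff(grid$time)
  if (length(dtv) == 0L) stop("cannot convolve a single-frame grid")
  if (max(dtv) - min(dtv) > 1e-9) stop("time axis must be uniform")
  dt <- dtv[1L]
  conv_mat <- function(m) apply(m, 2L, convolve_trace, dt = dt, fwhm = fwhm,
                                before = before, after = after)
  grid$intensity <- conv_mat(grid$intensity)
  for (by in names(grid$slices))
    grid$slices[[by]] <- lapply(grid$slices[[by]], conv_mat)
  grid$meta$tfwhm <- fwhm
  grid
}

#' Energy-window integrated yield traces
#'
#' Trapezoidal integral of the intensity over a kinetic-energy window, per
#' time bin, for the total signal and for every attached decomposition
#' slice. A window reaching beyond the energy axis is clipped with a
#' warning; a window containing fewer than two grid points is an error.
#'
#' @param grid a `trpes_grid`.
#' @param window numeric length-2 kinetic-energy window in eV (default
#'   `c(0, 4)`).
#' @return An object of class `yield_trace`: list with `time`, `total` and
#'   `slices` (named lists of numeric traces by state/pathway/tautomer).
#' @export
integrate_energy <- function(grid, window = c(0, 4)) {
  stopifnot(inherits(grid, "trpes_grid"), length(window) == 2, window[2] > window[1])
  if (window[1] < min(grid$ekin) - 1e-9 || window[2] > max(grid$ekin) + 1e-9) {
    warning("integration window clipped to the energy axis", call. = FALSE)
    window <- c(max(window[1], min(grid$ekin)), min(window[2], max(grid$ekin)))
  }
  sel <- which(grid$ekin >= window[1] - 1e-12 & grid$ekin <= window[2] + 1e-12)
  if (length(sel) < 2L) stop("empty integration window")
  x <- grid$ekin[sel]
  integ <- function(m) apply(m[, sel, drop = FALSE], 1L, function(y) trapz(x, y))
  slices <- lapply(grid$slices, function(group) lapply(group, integ))
  structure(list(time = grid$time, total = integ(grid$intensity),
                 slices = slices, window = window),
            class = "yield_trace")
}

#' Decomposition slices of a TRPES grid
#'
#' Returns the slices recorded during [assemble_trpes()]: signal is
#' attributed to neutral states fractionally through the state weights, and
#' to pathways / tautomers exclusively through the trajectory labels. The
#' slices of each attribution sum to the total grid.
#'
#' @param grid a `trpes_grid`.
#' @param by one of `"state"`, `"pathway"`, `"tautomer"`.
#' @return Named list of time-by-energy intensity matrices.
#' @export
trpes_decompose <- function(grid, by = c("state", "pathway", "tautomer")) {
  by <- match.arg(by)
  stopifnot(inherits(grid, "trpes_grid"))
  sl <- grid$slices[[by]]
  if (is.null(sl) || length(sl) == 0L)
    stop(sprintf("no '%s' attribution recorded; re-assemble the grid with assemble_trpes()", by))
  sl
}
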