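# Plain-text containers: JSON wavefunction files, directory-of-TSV
# trajectory ensembles, and two-column spectrum output with JSON sidecars.

#' Write a wavefunction container (JSON)
#'
#' Schema `dysonspec-wf-1`: a `basis` block (`mo_set_id`, `n_spatial`) and a
#' `states` map keyed by label, each with `n_electrons`, `multiplicity`,
#' `energy` and determinant `terms` (`occ`, `coef`). A shipped example
#' lives at `system.file("extdata", "example_wavefunctions.json",
#' package = "dysonspec")`.
#'
#' @param states list of [ci_state()] sharing one basis.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wavefunction_json <- function(states, path) {
  stopifnot(length(states) >= 1)
  basis <- states[[1L]]$basis
  payload <- list(
    schema = "dysonspec-wf-1",
    basis = list(mo_set_id = basis$mo_set_id, n_spatial = basis$n_spatial),
    states = stats::setNames(lapply(states, function(s) list(
      n_electrons = s$n_electrons,
      multiplicity = s$multiplicity,
      energy = s$energy,
      terms = lapply(seq_along(s$dets), function(i)
        list(occ = s$dets[[i]], coef = s$coefs[i]))
    )), vapply(states, function(s) s$label, "")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a wavefunction container (JSON)
#'
#' @param path file written by [write_wavefunction_json()] (or conforming
#'   to the `dysonspec-wf-1` schema).
#' @return Named list of [ci_state()].
#' @export
read_wavefunction_json <- function(path) {
  j <- jsonlite::read_json(path)
  if (!identical(j$schema, "dysonspec-wf-1"))
    stop("unrecognised wavefunction schema: ", j$schema)
  basis <- spin_orbital_basis(j$basis$n_spatial, j$basis$mo_set_id)
  out <- lapply(names(j$states), function(lbl) {
    s <- j$states[[lbl]]
    dets <- lapply(s$terms, function(tm) as.integer(unlist(tm$occ)))
    coefs <- vapply(s$terms, function(tm) as.numeric(tm$coef), 0)
    ci_state(basis, dets, coefs,
             energy = if (is.null(s$energy)) NA_real_ else as.numeric(s$energy),
             multiplicity = if (is.null(s$multiplicity)) NA_integer_
                            else as.integer(s$multiplicity),
             label = lbl)
  })
  stats::setNames(out, names(j$states))
}

#' Write a trajectory ensemble to a directory of TSV + JSON files
#'
#' One subdirectory per trajectory containing `meta.json` (id, tautomer,
#' pathway, state labels, channel identities) and `series.tsv` (columns:
#' `time`, `w.<state>`, `V.<state>`, then per channel `Vion.<k>` and
#' `norm.<k>`).
#'
#' @param ensemble list of [trajectory_record()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble_dir <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in ensemble) {
    sub <- file.path(dir, tr$id)
    dir.create(sub, showWarnings = FALSE)
    meta <- list(id = tr$id, tautomer = tr$tautomer, pathway = tr$pathway,
                 states = colnames(tr$weights),
                 channels = lapply(tr$channels, function(ch)
                   list(source = ch$source, ion = ch$ion)))
    jsonlite::write_json(meta, file.path(sub, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    df <- data.frame(time = tr$times, check.names = FALSE)
    for (s in colnames(tr$weights)) df[[paste0("w.", s)]] <- tr$weights[, s]
    for (s in colnames(tr$energies)) df[[paste0("V.", s)]] <- tr$energies[, s]
    for (k in seq_along(tr$channels)) {
      df[[paste0("Vion.", k)]] <- tr$channels[[k]]$energy_ion
      df[[paste0("norm.", k)]] <- tr$channels[[k]]$norm
    }
    utils::write.table(df, file.path(sub, "series.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a trajectory ensemble from a directory
#'
#' @param dir directory written by [write_ensemble_dir()].
#' @return List of [trajectory_record()].
#' @export
read_ensemble_dir <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  if (length(subs) == 0L) stop("no trajectory subdirectories under ", dir)
  lapply(subs, function(sub) {
    meta <- jsonlite::read_json(file.path(sub, "meta.json"))
    df <- utils::read.table(file.path(sub, "series.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE)
    states <- unlist(meta$states)
    w <- as.matrix(df[paste0("w.", states)]); colnames(w) <- states
    v <- as.matrix(df[paste0("V.", states)]); colnames(v) <- states
    channels <- lapply(seq_along(meta$channels), function(k)
      list(source = meta$channels[[k]]$source, ion = meta$channels[[k]]$ion,
           energy_ion = df[[paste0("Vion.", k)]], norm = df[[paste0("norm.", k)]]))
    trajectory_record(meta$id, meta$tautomer, meta$pathway,
                      df$time, w, v, channels)
  })
}

#' Write a spectrum as two-column text with a JSON sidecar
#'
#' @param spectrum a `spectrum_grid`.
#' @param path output path for the two-column (energy, intensity) file; the
#'   metadata sidecar is written to `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum_grid"))
  utils::write.table(data.frame(energy = spectrum$energy,
                                intensity = spectrum$intensity),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(spectrum$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a TRPES grid as a text matrix with a JSON sidecar
#'
#' The matrix file has one header row of kinetic energies and one row per
#' time bin (first column the time in fs).
#'
#' @param grid a `trpes_grid`.
#' @param path output path; the sidecar goes to `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_trpes <- function(grid, path) {
  stopifnot(inherits(grid, "trpes_grid"))
  m <- cbind(time = grid$time, grid$intensity)
  colnames(m) <- c("time", sprintf("%.6g", grid$ekin))
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(grid$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
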