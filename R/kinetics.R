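# Lifetime extraction from energy-integrated yield traces: independent
# monoexponential fits per pathway and global multi-exponential fits with
# shared time constants. The least-squares engine is variable projection:
# for candidate time constants the amplitudes are solved linearly, and the
# profiled residual is minimised over the (log) time constants with a
# deterministic multi-start.

# model basis evaluated at times t for time constants taus;
# conv_fwhm (if not NULL) replaces each exponential by its Gaussian
# convolution (exponentially modified Gaussian with that FWHM).
decay_basis_fn <- function(t, tau, conv_fwhm = NULL) {
  if (is.null(conv_fwhm)) {
    ifelse(t < 0, 0, exp(-t / tau))
  } else {
    emg_profile(t, tau, fwhm_to_sigma(conv_fwhm))
  }
}

#' Exponentially modified Gaussian decay profile
#'
#' Closed form of `exp(-t/tau)` for `t >= 0` (zero before) convolved with a
#' unit-area Gaussian of standard deviation `sigma`:
#' `0.5 * exp(sigma^2/(2 tau^2) - t/tau) * erfc((sigma/tau - t/sigma)/sqrt(2))`,
#' evaluated in log space for numerical stability.
#'
#' @param t times.
#' @param tau decay constant (> 0).
#' @param sigma Gaussian standard deviation (> 0).
#' @return Profile values (the unconvolved peak amplitude is 1).
#' @export
emg_profile <- function(t, tau, sigma) {
  z <- (sigma / tau - t / sigma) / sqrt(2)
  # log(erfc(z)) = log(2) + pnorm(-z*sqrt(2), log.p = TRUE)
  log_erfc <- log(2) + stats::pnorm(-z * sqrt(2), log.p = TRUE)
  exp(sigma^2 / (2 * tau^2) - t / tau + log(0.5) + log_erfc)
}

# linear amplitude solve for a fixed basis; returns rss and amplitudes
varpro_solve <- function(B, y) {
  fit <- tryCatch(stats::lm.fit(B, y), error = function(e) NULL)
  if (is.null(fit)) return(list(rss = Inf, amps = rep(NA_real_, ncol(B))))
  amps <- fit$coefficients
  amps[is.na(amps)] <- 0
  res <- y - B %*% amps
  list(rss = sum(res^2), amps = as.numeric(amps))
}

#' Monoexponential decay fit
#'
#' Least-squares fit of `A * exp(-t/tau)` (optionally plus a constant
#' offset, off by default) to a yield trace. The time constant is profiled
#' by variable projection with 8 deterministic log-spaced initialisations
#' and refined with [stats::nlminb()]; a final [minpack.lm::nlsLM()] polish
#' supplies the standard error. When `conv_fwhm` is given the model is the
#' Gaussian-convolved exponential ([emg_profile()]) with that fixed width,
#' for traces that have passed through [convolve_time()].
#'
#' @param time times in fs.
#' @param y trace values.
#' @param t_start fit only `time >= t_start` (default 0).
#' @param t_end fit only `time <= t_end` (default `Inf`). When fitting a
#'   trace that passed through [convolve_time()], the last couple of
#'   response widths before the final frame are distorted by the
#'   edge-extension boundary and should be excluded
#'   (`t_end = max(time) - 2 * conv_fwhm` is a good choice).
#' @param offset include a constant offset term (default `FALSE`).
#' @param conv_fwhm optional Gaussian FWHM (fs) of a convolution already
#'   applied to the trace; `NULL` (default) fits a plain exponential.
#' @return An object of class `decay_fit`: fields `tau`, `tau_se`,
#'   `amplitude`, `offset`, `rss`, `converged`, `non_decaying`, `model`,
#'   `n`.
#' @export
fit_monoexponential <- function(time, y, t_start = 0, t_end = Inf,
                                offset = FALSE, conv_fwhm = NULL) {
  keep <- time >= t_start & time <= t_end & is.finite(y)
  t <- time[keep]; yy <- y[keep]
  if (length(t) < 5L) stop("need at least 5 points after t_start")
  span <- max(t) - min(t)
  make_B <- function(tau) {
    B <- cbind(decay_basis_fn(t, tau, conv_fwhm))
    if (offset) B <- cbind(B, 1)
    B
  }
  obj <- function(ltau) varpro_solve(make_B(exp(ltau)), yy)$rss
  dt <- if (length(t) > 1) min(diff(t)) else 1
  starts <- log(exp(seq(log(max(dt, span / 500)), log(10 * span), length.out = 8)))
  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, obj, lower = log(dt / 100), upper = log(1000 * span),
                         control = list(abs.tol = 0, rel.tol = 1e-14, x.tol = 1e-14))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  tau <- exp(best$par)
  sol <- varpro_solve(make_B(tau), yy)
  non_decaying <- tau > 100 * span
  tau_se <- NA_real_
  converged <- TRUE
  if (!non_decaying) {
    # polish + standard error via Levenberg-Marquardt
    dat <- list(t = t, yy = yy)
    form <- if (is.null(conv_fwhm)) {
      if (offset) yy ~ A * exp(-t / tau) + C else yy ~ A * exp(-t / tau)
    } else {
      sig <- fwhm_to_sigma(conv_fwhm)
      if (offset) yy ~ A * emg_profile(t, tau, sig) + C
      else yy ~ A * emg_profile(t, tau, sig)
    }
    start <- list(A = sol$amps[1L], tau = tau)
    if (offset) start$C <- sol$amps[2L]
    nl <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- summary(nl)$coefficients
      tau <- cf["tau", "Estimate"]
      tau_se <- cf["tau", "Std. Error"]
      sol$amps[1L] <- cf["A", "Estimate"]
      if (offset) sol$amps[2L] <- cf["C", "Estimate"]
      sol$rss <- sum(stats::residuals(nl)^2)
    } else converged <- FALSE
    if (tau > 100 * span) non_decaying <- TRUE
  }
  structure(list(tau = if (non_decaying) NA_real_ else tau,
                 tau_se = tau_se,
                 amplitude = sol$amps[1L],
                 offset = if (offset) sol$amps[2L] else 0,
                 rss = sol$rss, converged = converged,
                 non_decaying = non_decaying,
                 model = if (is.null(conv_fwhm)) "mono" else "mono-convolved",
                 conv_fwhm = conv_fwhm, n = length(t)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (isTRUE(x$non_decaying)) {
    cat("<decay_fit: non-decaying trace>\n")
  } else if (!is.null(x$taus)) {
    cat(sprintf("<decay_fit %s: tau = %s fs>\n", x$model,
                paste(sprintf("%.4g +/- %.2g", x$taus, x$tau_se), collapse = ", ")))
  } else {
    cat(sprintf("<decay_fit %s: tau = %.6g +/- %.2g fs (A = %.4g)>\n",
                x$model, x$tau, x$tau_se, x$amplitude))
  }
  invisible(x)
}

# build the per-trace basis matrix for a global model
global_basis <- function(t, taus, terms, conv_fwhm) {
  cols <- lapply(terms, function(tm) {
    if (tm$type == "decay") {
      decay_basis_fn(t, taus[tm$k], conv_fwhm)
    } else if (tm$type == "rise") {
      decay_basis_fn(t, taus[tm$to], conv_fwhm) -
        decay_basis_fn(t, taus[tm$from], conv_fwhm)
    } else stop("unknown term type: ", tm$type)
  })
  do.call(cbind, cols)
}

#' Global multi-exponential fit with shared time constants
#'
#' Simultaneous least squares over several traces that share time constants
#' `tau_k`. Each trace is a linear combination of exponential basis
#' functions: plain decays `exp(-t/tau_k)` and, for sequential (cascade)
#' kinetics, rise-decay terms `exp(-t/tau_to) - exp(-t/tau_from)`. The
#' shared constants are profiled by variable projection (per-trace
#' amplitudes solved linearly) and optimised by deterministic multi-start
#' [stats::nlminb()].
#'
#' @param traces named list; each element is a list with numeric `time` and
#'   `y`.
#' @param n_components number of shared time constants.
#' @param components optional named list mapping each trace name to a list
#'   of term specifications `list(type = "decay", k = )` or
#'   `list(type = "rise", from = , to = )`. Default: every trace gets every
#'   decay term (parallel kinetics).
#' @param conv_fwhm optional Gaussian FWHM (fs) for convolved-trace models,
#'   as in [fit_monoexponential()].
#' @param tau_init optional numeric vector of initial time constants.
#' @return An object of class `decay_fit` with fields `taus`, `tau_se`,
#'   `amplitudes` (named list per trace), `rss`, `identifiability_warning`.
#' @export
fit_global <- function(traces, n_components = 2, components = NULL,
                       conv_fwhm = NULL, tau_init = NULL) {
  stopifnot(length(traces) >= 1, n_components >= 1)
  if (is.null(names(traces)) || any(names(traces) == ""))
    names(traces) <- paste0("trace", seq_along(traces))
  if (is.null(components)) {
    components <- lapply(traces, function(.)
      lapply(seq_len(n_components), function(k) list(type = "decay", k = k)))
  }
  stopifnot(all(names(traces) %in% names(components)))
  span <- max(vapply(traces, function(tr) max(tr$time) - min(tr$time), 0))
  dt <- min(vapply(traces, function(tr) min(diff(tr$time)), 0))
  obj <- function(ltaus) {
    taus <- exp(ltaus)
    rss <- 0
    for (nm in names(traces)) {
      B <- global_basis(traces[[nm]]$time, taus, components[[nm]], conv_fwhm)
      rss <- rss + varpro_solve(B, traces[[nm]]$y)$rss
    }
    rss
  }
  k <- n_components
  start_sets <- if (!is.null(tau_init)) {
    list(log(tau_init))
  } else {
    shifts <- seq(-1, 1, length.out = 8)
    lapply(shifts, function(sh)
      log(span) + seq(-3, -0.3, length.out = k) + sh)
  }
  best <- NULL
  for (s in start_sets) {
    opt <- stats::nlminb(s, obj, lower = log(dt / 100), upper = log(1000 * span),
                         control = list(abs.tol = 0, rel.tol = 1e-14, x.tol = 1e-14))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  taus <- exp(best$par)
  all_decay <- all(vapply(unlist(components, recursive = FALSE),
                          function(tm) tm$type == "decay", TRUE))
  if (all_decay) taus <- sort(taus)  # parallel model: constants exchangeable
  amps <- list()
  n_tot <- 0L
  res_all <- list()
  for (nm in names(traces)) {
    B <- global_basis(traces[[nm]]$time, taus, components[[nm]], conv_fwhm)
    sol <- varpro_solve(B, traces[[nm]]$y)
    amps[[nm]] <- sol$amps
    res_all[[nm]] <- traces[[nm]]$y - B %*% sol$amps
    n_tot <- n_tot + length(traces[[nm]]$y)
  }
  rss <- sum(unlist(res_all)^2)
  # standard errors from the stacked Jacobian over (log taus, amplitudes)
  par <- c(log(taus), unlist(amps))
  n_amp <- length(unlist(amps))
  resid_vec <- function(p) {
    lt <- p[seq_len(k)]; av <- p[-seq_len(k)]
    out <- numeric(0); pos <- 0L
    for (nm in names(traces)) {
      B <- global_basis(traces[[nm]]$time, exp(lt), components[[nm]], conv_fwhm)
      na <- ncol(B)
      out <- c(out, traces[[nm]]$y - B %*% av[pos + seq_len(na)])
      pos <- pos + na
    }
    out
  }
  J <- numeric_jacobian(resid_vec, par)
  p_tot <- length(par)
  dof <- max(n_tot - p_tot, 1L)
  sigma2 <- rss / dof
  JtJ <- crossprod(J)
  ident_warn <- NULL
  tau_se <- rep(NA_real_, k)
  ev <- eigen(JtJ, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12) {
    ident_warn <- "model poorly identified: singular/near-singular normal equations"
  } else {
    covm <- sigma2 * solve(JtJ)
    tau_se <- sqrt(diag(covm))[seq_len(k)] * taus  # delta method from log tau
  }
  if (k > sum(lengths(components) > 0))
    ident_warn <- paste(c(ident_warn,
                          "more shared constants than informative traces"), collapse = "; ")
  structure(list(taus = taus, tau_se = tau_se, amplitudes = amps,
                 rss = rss, model = if (is.null(conv_fwhm)) "global" else "global-convolved",
                 conv_fwhm = conv_fwhm,
                 identifiability_warning = ident_warn,
                 converged = best$convergence == 0, n = n_tot,
                 non_decaying = FALSE),
            class = "decay_fit")
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
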