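# Empirical flash-kinetics parameters of a single-turnover trace: peak
# intensity I_max, integrated light yield Q* (area under the curve), and the
# first-order decay constant of the post-peak phase.

#' Peak intensity of a kinetic trace
#'
#' @param trace a [kinetic_trace()].
#' @return list with \code{I_max} (maximum sampled intensity) and
#'   \code{t_peak} (its time, earliest sample on ties).
#' @export
peak_intensity <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (all(trace$intensities < 0))
    stop("trace has no non-negative intensity: no peak")
  i <- which.max(trace$intensities)  # earliest maximum on ties
  list(I_max = trace$intensities[i], t_peak = trace$times[i])
}

#' Integrated light yield (area under the kinetic curve)
#'
#' Trapezoidal integral of intensity over time. Negative samples (detector
#' noise) are clipped to zero before integration only; fitting routines see
#' the raw values.
#'
#' @param trace a [kinetic_trace()].
#' @return the integrated light in intensity units times seconds.
#' @export
quantum_yield <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(trace$times) < 2) stop("need at least 2 samples to integrate")
  pracma::trapz(trace$times, pmax(trace$intensities, 0))
}

#' Fit the first-order decay constant of the luminescence decay phase
#'
#' Nonlinear least squares of I = B exp(-k t) on a window of the trace tail.
#' The default window starts at the first sample after the peak whose
#' intensity has fallen to 80% of the peak (excluding rise contamination) and
#' ends at the last sample still at or above 5% of the peak (excluding the
#' detector floor). Starting values come from a log-linear regression on the
#' window; the same regression is available as an independent cross-check via
#' \code{method = "log-linear"}.
#'
#' @param trace a [kinetic_trace()].
#' @param window optional integer index range (length-2 vector) overriding
#'   the default fit window.
#' @param upper_frac,lower_frac window bounds as fractions of the peak.
#' @param method "nls" (default, Levenberg-Marquardt) or "log-linear".
#' @return an object of class \code{flash_decay_fit} with components
#'   \code{k_decay} (1/s), \code{B}, \code{fit_r2}, \code{fit_window}
#'   (index range), and \code{method}.
#' @export
fit_flash_decay <- function(trace, window = NULL, upper_frac = 0.8,
                            lower_frac = 0.05,
                            method = c("nls", "log-linear")) {
  stopifnot(inherits(trace, "kinetic_trace"))
  method <- match.arg(method)
  pk <- peak_intensity(trace)
  if (pk$I_max <= 0) stop("non-positive peak: cannot fit a decay")
  if (is.null(window)) {
    ipk <- which.max(trace$intensities)
    after <- seq(ipk, length(trace$times))
    lo <- after[trace$intensities[after] <= upper_frac * pk$I_max][1]
    if (is.na(lo)) stop("trace never falls below the upper window bound")
    keep <- which(trace$intensities >= lower_frac * pk$I_max)
    hi <- max(keep[keep >= lo])
    window <- c(lo, hi)
  }
  idx <- seq(window[1], window[2])
  if (length(idx) < 5) stop("decay-fit window has fewer than 5 points")
  t <- trace$times[idx]; y <- trace$intensities[idx]
  pos <- y > 0
  if (!any(pos)) stop("no positive intensities in the fit window")
  # log-linear start (weights ~ y^2 approximate equal variance in I-space)
  ll <- stats::lm(log(y[pos]) ~ t[pos], weights = y[pos]^2)
  k0 <- unname(max(-stats::coef(ll)[2], 1e-8))
  B0 <- unname(exp(stats::coef(ll)[1]))
  if (method == "log-linear") {
    k <- k0; B <- B0
    yhat <- B * exp(-k * t)
  } else {
    fit <- minpack.lm::nlsLM(y ~ B * exp(-k * t),
                             start = list(B = B0, k = k0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    B <- unname(cf["B"]); k <- unname(cf["k"])
    yhat <- stats::fitted(fit)
  }
  if (k <= 0) stop("decay fit produced a non-positive rate")
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  structure(list(k_decay = k, B = B, fit_r2 = max(0, min(1, r2)),
                 fit_window = window, method = method, n = length(idx)),
            class = "flash_decay_fit")
}

#' @export
print.flash_decay_fit <- function(x, ...) {
  cat(sprintf("Luminescence decay fit (%s): k_decay = %.4g 1/s, r2 = %.4f (%d points)\n",
              x$method, x$k_decay, x$fit_r2, x$n))
  invisible(x)
}

#' @export
coef.flash_decay_fit <- function(object, ...) {
  c(B = object$B, k_decay = object$k_decay)
}

#' Extract all empirical flash parameters of a trace
#'
#' Convenience wrapper combining [peak_intensity()], [quantum_yield()] and
#' [fit_flash_decay()].
#'
#' @inheritParams fit_flash_decay
#' @return an object of class \code{flash_params}: list with \code{I_max},
#'   \code{t_peak}, \code{Q_star}, \code{k_decay}, \code{fit_r2},
#'   \code{fit_window}, plus trace metadata.
#' @export
flash_params <- function(trace, window = NULL, upper_frac = 0.8,
                         lower_frac = 0.05) {
  pk <- peak_intensity(trace)
  fit <- fit_flash_decay(trace, window = window, upper_frac = upper_frac,
                         lower_frac = lower_frac)
  structure(list(I_max = pk$I_max, t_peak = pk$t_peak,
                 Q_star = quantum_yield(trace), k_decay = fit$k_decay,
                 fit_r2 = fit$fit_r2, fit_window = fit$fit_window,
                 temperature = trace$temperature, solvent = trace$solvent),
            class = "flash_params")
}

#' @export
print.flash_params <- function(x, ...) {
  cat("Single-turnover flash parameters\n")
  cat(sprintf("  I_max   = %.4g a.u. at t = %.4g s\n", x$I_max, x$t_peak))
  cat(sprintf("  Q*      = %.4g a.u.*s\n", x$Q_star))
  cat(sprintf("  k_decay = %.4g 1/s (r2 = %.4f)\n", x$k_decay, x$fit_r2))
  invisible(x)
}

#' @export
as.data.frame.flash_params <- function(x, ...) {
  data.frame(temperature_C = x$temperature, solvent = x$solvent,
             I_max = x$I_max, t_peak_s = x$t_peak, Q_star = x$Q_star,
             k_decay_per_s = x$k_decay, fit_r2 = x$fit_r2)
}
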