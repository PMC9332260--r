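# Thermal-inactivation analysis: remaining activity, phase segmentation
# (induction lag, single-exponential phase, late slow/aggregation phase),
# first-order rate fitting and Arrhenius activation energy.

#' Remaining activity from integrated light yields
#'
#' R = 100 Q* / Q0*, the heat-treated enzyme's integrated light output as a
#' percentage of the untreated control's.
#'
#' @param q integrated light yield after heat treatment (>= 0).
#' @param q0 integrated light yield of the untreated enzyme (> 0).
#' @return remaining activity in percent.
#' @export
remaining_activity <- function(q, q0) {
  if (any(q0 <= 0)) stop("untreated yield q0 must be positive")
  if (any(q < 0)) stop("treated yield q must be non-negative")
  100 * q / q0
}

#' Segment an inactivation time course into induction, exponential and slow phases
#'
#' The induction phase is the maximal leading run of points whose remaining
#' activity is still within \code{induction_tol} percent of 100 (heated
#' molecules recover on cooling); an isolated noisy dip down to
#' \code{100 - 2 * induction_tol} does not end the run as long as a later
#' leading point returns above the threshold. A late slow phase — typically aggregation
#' at high temperature — is detected as the maximal trailing run of at least
#' 3 points whose log-residuals from a provisional exponential fit exceed
#' 3 times their robust scale (MAD, with a 0.05 absolute floor so that an
#' exact exponential is never flagged). Everything in between is the
#' single-exponential phase used for rate fitting.
#'
#' @param series an [activity_series()] with at least 4 points.
#' @param induction_tol induction tolerance in percent of initial activity.
#' @param slow_detect logical; disable to force an empty slow phase.
#' @return list with integer index vectors \code{induction_idx},
#'   \code{exp_idx}, \code{slow_idx} (disjoint, covering the series).
#' @export
segment_phases <- function(series, induction_tol = 5, slow_detect = TRUE) {
  stopifnot(inherits(series, "activity_series"))
  n <- length(series$times)
  if (n < 4) stop("need at least 4 points to segment")
  high <- series$R >= 100 - induction_tol
  ok <- series$R >= 100 - 2 * induction_tol  # dip tolerance inside the run
  lead_ok <- cumsum(!ok) == 0
  cand <- which(high & lead_ok)
  induction_idx <- if (length(cand) > 0) seq_len(max(cand)) else integer(0)
  rest <- setdiff(seq_len(n), induction_idx)
  slow_idx <- integer(0)
  if (slow_detect && length(rest) >= 7) {
    pos <- rest[series$R[rest] > 0]
    # trailing run of points whose log-residuals from an exponential fitted
    # on `fit_idx` exceed 3x the robust scale of that fit (0.05 floor)
    trailing_run <- function(fit_idx) {
      ll <- stats::lm(log(series$R[fit_idx]) ~ series$times[fit_idx])
      pred <- stats::coef(ll)[1] + stats::coef(ll)[2] * series$times[pos]
      res <- log(series$R[pos]) - pred
      thr <- max(3 * stats::mad(res[pos %in% fit_idx]), 0.05)
      run <- 0L
      for (j in rev(seq_along(pos))) {
        if (res[j] > thr) run <- run + 1L else break
      }
      if (run >= 3) pos[(length(pos) - run + 1):length(pos)] else integer(0)
    }
    if (length(pos) >= 7) {
      # provisional fit on the leading half (least plateau-contaminated),
      # then confirmation against a refit on the non-flagged points
      lead <- pos[seq_len(max(4L, ceiling(length(pos) / 2)))]
      slow_idx <- trailing_run(lead)
      if (length(slow_idx) > 0 && length(setdiff(pos, slow_idx)) >= 4)
        slow_idx <- trailing_run(setdiff(pos, slow_idx))
    }
  }
  exp_idx <- setdiff(rest, slow_idx)
  if (length(exp_idx) < 3)
    stop("no decaying phase: fewer than 3 exponential-phase points")
  list(induction_idx = induction_idx, exp_idx = exp_idx, slow_idx = slow_idx)
}

#' Fit the first-order thermal-inactivation rate constant
#'
#' Segments the series with [segment_phases()] and fits
#' R = A exp(-k t) by nonlinear least squares on the exponential phase only,
#' on the original time axis with the pre-factor A free (A absorbs the
#' induction lag). The coefficient of determination is reported on that
#' segment.
#'
#' @param series an [activity_series()].
#' @param induction_tol,slow_detect passed to [segment_phases()].
#' @return an object of class \code{inactivation_fit} with components
#'   \code{k} (1/min), \code{A} (percent), \code{r2}, the segmentation index
#'   sets, and the input series.
#' @export
fit_inactivation <- function(series, induction_tol = 5, slow_detect = TRUE) {
  seg <- segment_phases(series, induction_tol = induction_tol,
                        slow_detect = slow_detect)
  t <- series$times[seg$exp_idx]; y <- series$R[seg$exp_idx]
  pos <- y > 0
  if (sum(pos) < 3) stop("fewer than 3 positive exponential-phase points")
  ll <- stats::lm(log(y[pos]) ~ t[pos], weights = y[pos]^2)
  k0 <- unname(max(-stats::coef(ll)[2], 1e-8))
  A0 <- unname(exp(stats::coef(ll)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-k * t), start = list(A = A0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("inactivation fit diverged: ", conditionMessage(e),
                             sprintf(" (start A=%.3g, k=%.3g, %d points)",
                                     A0, k0, length(t))))
  cf <- stats::coef(fit)
  yhat <- stats::fitted(fit)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  structure(list(k = unname(cf["k"]), A = unname(cf["A"]),
                 r2 = max(0, min(1, r2)),
                 induction_idx = seg$induction_idx, exp_idx = seg$exp_idx,
                 slow_idx = seg$slow_idx, series = series),
            class = "inactivation_fit")
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat(sprintf("Thermal-inactivation fit: k = %.4g 1/min, A = %.4g%%, r2 = %.4f\n",
              x$k, x$A, x$r2))
  cat(sprintf("  phases: %d induction / %d exponential / %d slow point(s)\n",
              length(x$induction_idx), length(x$exp_idx), length(x$slow_idx)))
  invisible(x)
}

#' @export
summary.inactivation_fit <- function(object, ...) {
  print(object)
  halflife <- log(2) / object$k
  cat(sprintf("  inactivation half-life: %.3g min\n", halflife))
  if (!is.na(object$series$temperature))
    cat(sprintf("  incubation temperature: %g C\n", object$series$temperature))
  invisible(object)
}

#' @export
coef.inactivation_fit <- function(object, ...) c(A = object$A, k = object$k)

#' @export
predict.inactivation_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$times else newdata$time_min
  object$A * exp(-object$k * t)
}

#' @export
residuals.inactivation_fit <- function(object, ...) {
  i <- object$exp_idx
  object$series$R[i] - object$A * exp(-object$k * object$series$times[i])
}

#' @export
plot.inactivation_fit <- function(x, ...) {
  s <- x$series
  phase <- rep("exp", length(s$times))
  phase[x$induction_idx] <- "induction"; phase[x$slow_idx] <- "slow"
  graphics::plot(s$times, s$R, log = "y", xlab = "incubation time (min)",
                 ylab = "remaining activity (%)",
                 pch = c(exp = 19, induction = 1, slow = 2)[phase], ...)
  tt <- seq(min(s$times[x$exp_idx]), max(s$times[x$exp_idx]), length.out = 100)
  graphics::lines(tt, x$A * exp(-x$k * tt))
  invisible(x)
}

#' Arrhenius analysis of inactivation rate constants
#'
#' Ordinary least squares of ln k on 1/T (T in Kelvin); the activation
#' energy is E_a = -slope * R, reported in kJ/mol with the slope's standard
#' error propagated. Duplicate temperatures with different rates are allowed
#' (they enter as separate points); at least two distinct temperatures are
#' required.
#'
#' @param k inactivation rate constants, 1/min (> 0).
#' @param temp_C corresponding incubation temperatures in Celsius.
#' @return an object of class \code{arrhenius_fit} with \code{E_a} (kJ/mol),
#'   \code{lnA0} (intercept), \code{stderr_Ea} (kJ/mol; \code{NA} with only
#'   two points), and \code{n_points}.
#' @examples
#' arrhenius(c(0.15, 0.71, 1.36, 1.63, 2.69), c(45, 48, 50, 52, 55))
#' @export
arrhenius <- function(k, temp_C) {
  if (length(k) != length(temp_C)) stop("k and temp_C must have equal length")
  if (length(k) < 2) stop("need at least 2 (k, T) pairs")
  if (any(k <= 0)) stop("rate constants must be positive")
  if (length(unique(temp_C)) < 2) stop("need at least 2 distinct temperatures")
  invT <- 1 / celsius_to_kelvin(temp_C)
  fit <- stats::lm(log(k) ~ invT)
  sm <- suppressWarnings(summary(fit))$coefficients  # benign on perfect fits
  E_a <- -unname(stats::coef(fit)[2]) * .R_GAS / 1000
  se <- if (nrow(sm) == 2 && stats::df.residual(fit) > 0)
    sm[2, "Std. Error"] * .R_GAS / 1000 else NA_real_
  structure(list(E_a = E_a, lnA0 = unname(stats::coef(fit)[1]),
                 stderr_Ea = se, n_points = length(k), fit = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  se <- if (is.na(x$stderr_Ea)) "" else sprintf(" +/- %.3g", x$stderr_Ea)
  cat(sprintf("Arrhenius fit (%d points): E_a = %.4g%s kJ/mol\n",
              x$n_points, x$E_a, se))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(E_a = object$E_a, lnA0 = object$lnA0)
}

#' @export
predict.arrhenius_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(exp(stats::fitted(object$fit)))
  invT <- 1 / celsius_to_kelvin(newdata$temp_C)
  exp(object$lnA0 - object$E_a * 1000 / .R_GAS * invT)
}
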