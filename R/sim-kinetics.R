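# Synthetic instrument-output generators with known ground truth. Every
# generator takes an explicit integer seed and restores the caller's RNG
# state, so identical (seed, params) always yield identical output.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a single-turnover flash trace
#'
#' Noise-free model: I(t) = amplitude (e^(-k_decay t) - e^(-k_rise t)), the
#' classic rise-then-decay flash shape. Its peak sits at
#' t_peak = ln(k_rise/k_decay) / (k_rise - k_decay) and its integral is
#' amplitude (1/k_decay - 1/k_rise). Additive Gaussian noise with standard
#' deviation \code{noise_sd} times the noise-free peak intensity is applied.
#'
#' @param amplitude intensity scale (arbitrary units, >= 0).
#' @param k_rise rise rate in 1/s; must exceed \code{k_decay}.
#' @param k_decay first-order decay rate in 1/s (> 0). Printed single-turnover
#'   values for the two luciferases with decanal are 0.32 and 0.21 1/s.
#' @param noise_sd additive noise sd as a fraction of the peak intensity.
#' @param dt sampling step in s (> 0).
#' @param duration trace length in s; should span several 1/k_decay.
#' @param temperature,solvent metadata labels.
#' @param seed integer random seed (ignored when \code{noise_sd = 0}).
#' @return a [kinetic_trace()].
#' @examples
#' tr <- sim_flash_trace(1, k_rise = 10, k_decay = 0.5, noise_sd = 0,
#'                       dt = 0.001, duration = 20)
#' @export
sim_flash_trace <- function(amplitude, k_rise, k_decay, noise_sd = 0.02,
                            dt = 0.01, duration = 20,
                            temperature = NA_real_, solvent = NA_character_,
                            seed = 1L) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (k_decay <= 0) stop("k_decay must be positive")
  if (k_rise <= k_decay)
    stop("invalid parameters: k_rise must exceed k_decay (model degenerate)")
  if (dt <= 0) stop("dt must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  times <- seq(0, duration, by = dt)
  clean <- amplitude * (exp(-k_decay * times) - exp(-k_rise * times))
  t_pk <- log(k_rise / k_decay) / (k_rise - k_decay)
  pk <- amplitude * (exp(-k_decay * t_pk) - exp(-k_rise * t_pk))
  intens <- if (noise_sd > 0 && amplitude > 0) {
    .with_seed(seed, clean + stats::rnorm(length(clean), sd = noise_sd * pk))
  } else clean
  kinetic_trace(times, intens, temperature = temperature, solvent = solvent)
}

#' Simulate a remaining-activity time course
#'
#' Noise-free model: R(t) = 100 for t <= t_lag (the induction phase, during
#' which heat-treated enzyme still recovers full activity on cooling);
#' afterwards R(t) = (100 - plateau) exp(-k (t - t_lag)) + plateau, where
#' plateau = 100 * plateau_frac emulates the late slow inactivation phase
#' attributed to aggregation. Noise is multiplicative Gaussian (activity
#' ratios carry relative error), so R(0) stays at 100 in expectation.
#'
#' @param k first-order inactivation rate in 1/min (> 0).
#' @param t_lag induction-phase duration in min (>= 0). Observed lags span
#'   roughly 0.5 to 8 min depending on temperature.
#' @param plateau_frac late activity floor as a fraction of 100% (in [0, 1);
#'   0 disables the slow phase).
#' @param noise_sd relative (multiplicative) noise sd.
#' @param times sampling times in minutes, strictly increasing.
#' @param temperature,solvent metadata labels.
#' @param seed integer random seed.
#' @return an [activity_series()].
#' @examples
#' s <- sim_inactivation_series(k = 0.693, t_lag = 2, noise_sd = 0,
#'                              times = seq(0, 6, 0.5))
#' @export
sim_inactivation_series <- function(k, t_lag = 0, plateau_frac = 0,
                                    noise_sd = 0.02,
                                    times = seq(0, 10, 0.5),
                                    temperature = NA_real_,
                                    solvent = NA_character_, seed = 1L) {
  if (k <= 0) stop("k must be positive")
  if (t_lag < 0) stop("t_lag must be non-negative")
  if (plateau_frac < 0 || plateau_frac >= 1)
    stop("plateau_frac must lie in [0, 1)")
  if (length(times) == 0) stop("empty sampling-time vector")
  plateau <- 100 * plateau_frac
  R <- ifelse(times <= t_lag, 100,
              (100 - plateau) * exp(-k * (times - t_lag)) + plateau)
  if (noise_sd > 0) {
    R <- .with_seed(seed, R * (1 + stats::rnorm(length(R), sd = noise_sd)))
    R <- pmax(R, 0)
  }
  activity_series(times, R, temperature = temperature, solvent = solvent)
}

#' Two-state excess heat capacity curve
#'
#' Equilibrium two-state unfolding: K(T) = exp[(dH_vH/R)(1/T_m - 1/T)],
#' progress alpha = K/(1+K), and excess heat capacity
#' C_exc(T) = dH_cal * dalpha/dT = dH_cal dH_vH K / (R T^2 (1+K)^2),
#' so alpha(T_m) = 1/2 and the integral of C_exc over a grid spanning the
#' transition equals dH_cal. An optional \code{skew} makes the effective
#' van't Hoff enthalpy drift linearly with temperature,
#' dH_vH (1 + skew (T - T_m)), producing the asymmetric peaks
#' (heat-asymmetry ratio != 1) typical of irreversible denaturation;
#' the curve is still an exact derivative of its progress variable, so the
#' area stays dH_cal.
#'
#' @param T temperatures in Kelvin.
#' @param T_m transition temperature in Kelvin.
#' @param dH_cal calorimetric enthalpy in kJ/mol (peak area).
#' @param dH_vH van't Hoff enthalpy in kJ/mol (sets peak sharpness; the full
#'   width at half maximum is approximately 3.5255 R T_m^2 / dH_vH).
#' @param skew linear temperature coefficient of the effective van't Hoff
#'   enthalpy, in 1/K; 0 gives the symmetric two-state form.
#' @return list with components \code{Cp_exc} (kJ/(K mol)) and \code{alpha}.
#' @export
two_state_excess_cp <- function(T, T_m, dH_cal, dH_vH, skew = 0) {
  if (dH_cal <= 0 || dH_vH <= 0) stop("enthalpies must be positive")
  Rk <- .R_GAS / 1000  # kJ/(mol K)
  h <- dH_vH * (1 + skew * (T - T_m))           # effective dH_vH(T)
  lnK <- (h / Rk) * (1 / T_m - 1 / T)
  alpha <- stats::plogis(lnK)                    # K/(1+K), overflow-safe
  dlnK <- (dH_vH / Rk) * (skew * (1 / T_m - 1 / T) +
                            (1 + skew * (T - T_m)) / T^2)
  list(Cp_exc = dH_cal * alpha * (1 - alpha) * dlnK, alpha = alpha)
}

#' Height of the two-state excess heat capacity peak
#'
#' Closed form dH_cal dH_vH / (4 R T_m^2) for the symmetric two-state model.
#'
#' @inheritParams two_state_excess_cp
#' @return peak height in kJ/(K mol).
#' @export
two_state_peak_height <- function(T_m, dH_cal, dH_vH) {
  dH_cal * dH_vH / (4 * (.R_GAS / 1000) * T_m^2)
}

#' Simulate a DSC thermogram
#'
#' A two-state excess heat capacity peak ([two_state_excess_cp()]) is added
#' onto native and denatured instrument baselines blended by the unfolding
#' progress alpha: baseline(T) = (1 - alpha) B_N(T) + alpha B_D(T), with each
#' baseline linear, B(T) = intercept + slope (T - T_m). Additive Gaussian
#' noise of standard deviation \code{noise_sd} (kJ/(K mol)) is applied; for
#' "x% of peak" noise multiply [two_state_peak_height()] by x/100.
#'
#' @param T_m transition temperature, K.
#' @param dH_cal calorimetric enthalpy, kJ/mol.
#' @param dH_vH van't Hoff enthalpy, kJ/mol (generator-only sharpness knob).
#' @param native_baseline numeric length-2, c(intercept, slope) of the
#'   pre-transition heat capacity in kJ/(K mol) and kJ/(K^2 mol); the
#'   intercept is the value at T_m.
#' @param denatured_baseline same for the post-transition baseline.
#' @param noise_sd additive heat-capacity noise sd, kJ/(K mol).
#' @param T_grid temperature samples in K, strictly increasing; should
#'   bracket T_m (a truncated peak is flagged with a warning).
#' @param skew optional asymmetry coefficient, see [two_state_excess_cp()].
#' @param solvent metadata label.
#' @param seed integer random seed.
#' @return a molar-units [thermogram()].
#' @export
sim_thermogram <- function(T_m, dH_cal, dH_vH,
                           native_baseline = c(30, 0.05),
                           denatured_baseline = c(35, 0.02),
                           noise_sd = 0, T_grid = seq(290, 350, by = 0.05),
                           skew = 0, solvent = NA_character_, seed = 1L) {
  if (any(diff(T_grid) <= 0)) stop("T_grid must be strictly increasing")
  if (T_m < min(T_grid) || T_m > max(T_grid))
    warning("T_grid does not bracket T_m: generated peak is truncated")
  ts <- two_state_excess_cp(T_grid, T_m, dH_cal, dH_vH, skew = skew)
  bn <- native_baseline[1] + native_baseline[2] * (T_grid - T_m)
  bd <- denatured_baseline[1] + denatured_baseline[2] * (T_grid - T_m)
  Cp <- (1 - ts$alpha) * bn + ts$alpha * bd + ts$Cp_exc
  if (noise_sd > 0)
    Cp <- .with_seed(seed, Cp + stats::rnorm(length(Cp), sd = noise_sd))
  thermogram(T_grid, Cp, units = "molar", scan_rate = 1, mw = 80000,
             solvent = solvent)
}
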