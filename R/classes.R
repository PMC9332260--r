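#' Single-turnover bioluminescence trace
#'
#' A sampled light-emission time course from a single-turnover (flash) assay:
#' the enzyme performs one catalytic cycle, so intensity rises quickly and
#' then decays approximately exponentially.
#'
#' @param times sampling times in seconds, strictly increasing, length >= 10.
#' @param intensities light intensities (arbitrary units), same length.
#' @param temperature assay temperature in degrees Celsius (metadata).
#' @param solvent solvent label, e.g. "buffer" or "sucrose" (metadata).
#' @return an object of class \code{kinetic_trace}.
#' @export
kinetic_trace <- function(times, intensities, temperature = NA_real_,
                          solvent = NA_character_) {
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("times and intensities must have equal length")
  if (length(times) < 10) stop("a kinetic trace needs at least 10 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, intensities = intensities,
                 temperature = temperature, solvent = solvent),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Single-turnover kinetic trace: %d samples, %.3g-%.3g s\n",
              length(x$times), min(x$times), max(x$times)))
  if (!is.na(x$temperature)) cat(sprintf("  temperature: %g C\n", x$temperature))
  if (!is.na(x$solvent)) cat(sprintf("  solvent: %s\n", x$solvent))
  invisible(x)
}

#' Remaining-activity time course at one incubation temperature
#'
#' Remaining activity R (percent of the untreated enzyme's integrated light
#' output) versus incubation time at a single temperature and solvent.
#'
#' @param times incubation times in minutes, non-negative, strictly increasing.
#' @param R remaining activity in percent (>= 0; noise may exceed 100 slightly).
#' @param temperature incubation temperature in degrees Celsius.
#' @param solvent solvent label.
#' @return an object of class \code{activity_series}.
#' @export
activity_series <- function(times, R, temperature = NA_real_,
                            solvent = NA_character_) {
  times <- as.numeric(times); R <- as.numeric(R)
  if (length(times) != length(R)) stop("times and R must have equal length")
  if (length(times) == 0) stop("empty series")
  if (any(times < 0)) stop("times must be non-negative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(R < 0)) stop("remaining activity must be non-negative")
  structure(list(times = times, R = R, temperature = temperature,
                 solvent = solvent),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("Remaining-activity series: %d points, %.3g-%.3g min\n",
              length(x$times), min(x$times), max(x$times)))
  if (!is.na(x$temperature)) cat(sprintf("  temperature: %g C\n", x$temperature))
  if (!is.na(x$solvent)) cat(sprintf("  solvent: %s\n", x$solvent))
  invisible(x)
}

#' Differential scanning calorimetry thermogram
#'
#' Heat capacity versus temperature. Units are either molar, kJ/(K mol), or
#' specific, J/(K g); the \code{units} flag records which. Metadata carries
#' what a molar conversion needs.
#'
#' @param T temperatures in Kelvin, strictly increasing, length >= 50.
#' @param Cp heat capacities in the stated units.
#' @param units "molar" (kJ/(K mol)) or "specific" (J/(K g)).
#' @param scan_rate scan rate in K/min (metadata).
#' @param conc_mg_mL protein concentration in mg/mL (metadata).
#' @param mw molecular weight in Da (metadata; the heterodimer is ~80,000 Da).
#' @param psv partial specific volume in cm^3/g (metadata; carried, not used
#'   in the excess-heat-capacity computation).
#' @param solvent solvent label.
#' @return an object of class \code{thermogram}.
#' @export
thermogram <- function(T, Cp, units = c("molar", "specific"),
                       scan_rate = NA_real_, conc_mg_mL = NA_real_,
                       mw = NA_real_, psv = 0.73, solvent = NA_character_) {
  units <- match.arg(units)
  T <- as.numeric(T); Cp <- as.numeric(Cp)
  if (length(T) != length(Cp)) stop("T and Cp must have equal length")
  if (length(T) < 50) stop("a thermogram needs at least 50 samples")
  if (any(diff(T) <= 0)) stop("temperatures must be strictly increasing")
  structure(list(T = T, Cp = Cp, units = units, scan_rate = scan_rate,
                 conc_mg_mL = conc_mg_mL, mw = mw, psv = psv,
                 solvent = solvent),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("DSC thermogram: %d samples, %.2f-%.2f K (%s units)\n",
              length(x$T), min(x$T), max(x$T), x$units))
  invisible(x)
}
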