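# Delimited-text I/O. All instrument-like records share one layout:
# '#'-prefixed "key: value" metadata lines, a column-name header row, then
# whitespace- or tab-delimited numeric rows.

.read_delim_block <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (m in lines[is_meta]) {
    m <- sub("^\\s*#\\s*", "", m)
    kv <- regmatches(m, regexec("^([^:=]+)[:=]\\s*(.*)$", m))[[1]]
    if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  body <- lines[!is_meta]
  if (length(body) < 2) stop("no data rows in ", path)
  header <- strsplit(trimws(body[1]), "[,\t ]+")[[1]]
  rows <- body[-1]
  parsed <- strsplit(trimws(rows), "[,\t ]+")
  bad <- which(vapply(parsed, length, 1L) != length(header))
  if (length(bad) > 0)
    stop(sprintf("malformed row(s) in %s at data line(s): %s",
                 path, paste(bad, collapse = ", ")))
  mat <- do.call(rbind, lapply(parsed, function(p)
    suppressWarnings(as.numeric(p))))
  nn <- which(apply(is.na(mat), 1, any))
  if (length(nn) > 0)
    stop(sprintf("non-numeric value(s) in %s at data line(s): %s",
                 path, paste(nn, collapse = ", ")))
  colnames(mat) <- header
  list(meta = meta, data = as.data.frame(mat))
}

.meta_num <- function(meta, key) {
  if (is.null(meta[[key]])) return(NA_real_)
  suppressWarnings(as.numeric(meta[[key]]))
}

.write_delim_block <- function(path, meta, data, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    if (!is.na(meta[[k]]) && nzchar(as.character(meta[[k]])))
      writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  }
  writeLines(paste(colnames(data), collapse = "\t"), con)
  apply(data, 1, function(r)
    writeLines(paste(formatC(r, digits = digits, format = "g"),
                     collapse = "\t"), con))
  invisible(path)
}

#' Read a single-turnover kinetic trace from delimited text
#'
#' Expects columns \code{time_s} and \code{intensity}, with optional metadata
#' header lines \code{# temperature_C: ...} and \code{# solvent: ...}.
#'
#' @param path file path.
#' @return a [kinetic_trace()].
#' @export
read_trace <- function(path) {
  b <- .read_delim_block(path)
  if (!all(c("time_s", "intensity") %in% names(b$data)))
    stop("trace file must have columns time_s and intensity")
  kinetic_trace(b$data$time_s, b$data$intensity,
                temperature = .meta_num(b$meta, "temperature_C"),
                solvent = if (is.null(b$meta$solvent)) NA_character_
                          else b$meta$solvent)
}

#' Write a kinetic trace to delimited text
#' @param trace a [kinetic_trace()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path) {
  .write_delim_block(path,
    list(temperature_C = trace$temperature, solvent = trace$solvent),
    data.frame(time_s = trace$times, intensity = trace$intensities))
}

#' Read a remaining-activity series from delimited text
#'
#' Expects columns \code{time_min} and \code{R_percent}, with metadata
#' \code{temperature_C} and \code{solvent}.
#'
#' @param path file path.
#' @return an [activity_series()].
#' @export
read_series <- function(path) {
  b <- .read_delim_block(path)
  if (!all(c("time_min", "R_percent") %in% names(b$data)))
    stop("series file must have columns time_min and R_percent")
  activity_series(b$data$time_min, b$data$R_percent,
                  temperature = .meta_num(b$meta, "temperature_C"),
                  solvent = if (is.null(b$meta$solvent)) NA_character_
                            else b$meta$solvent)
}

#' Write a remaining-activity series to delimited text
#' @param series an [activity_series()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_series <- function(series, path) {
  .write_delim_block(path,
    list(temperature_C = series$temperature, solvent = series$solvent),
    data.frame(time_min = series$times, R_percent = series$R))
}

#' Read a DSC thermogram from delimited text
#'
#' Temperature may be given as column \code{T_K} (Kelvin) or \code{T_C}
#' (Celsius, converted by +273.15); exactly one must be present (a file with
#' both is rejected rather than guessed at). Heat capacity is \code{Cp_molar}
#' (kJ/(K mol)) or \code{Cp_specific} (J/(K g)); again exactly one.
#' Recognised metadata: \code{scan_rate_K_min}, \code{conc_mg_mL},
#' \code{mw_Da}, \code{psv_cm3_g}, \code{solvent}.
#'
#' @param path file path.
#' @return a [thermogram()].
#' @export
read_thermogram <- function(path) {
  b <- .read_delim_block(path)
  has_K <- "T_K" %in% names(b$data); has_C <- "T_C" %in% names(b$data)
  if (has_K && has_C) stop("ambiguous temperature units: both T_K and T_C present")
  if (!has_K && !has_C) stop("thermogram file must have a T_K or T_C column")
  TK <- if (has_K) b$data$T_K else celsius_to_kelvin(b$data$T_C)
  has_m <- "Cp_molar" %in% names(b$data); has_s <- "Cp_specific" %in% names(b$data)
  if (has_m && has_s) stop("ambiguous heat-capacity units: both Cp_molar and Cp_specific present")
  if (!has_m && !has_s) stop("thermogram file must have a Cp_molar or Cp_specific column")
  psv <- .meta_num(b$meta, "psv_cm3_g")
  thermogram(TK, if (has_m) b$data$Cp_molar else b$data$Cp_specific,
             units = if (has_m) "molar" else "specific",
             scan_rate = .meta_num(b$meta, "scan_rate_K_min"),
             conc_mg_mL = .meta_num(b$meta, "conc_mg_mL"),
             mw = .meta_num(b$meta, "mw_Da"),
             psv = if (is.na(psv)) 0.73 else psv,
             solvent = if (is.null(b$meta$solvent)) NA_character_
                       else b$meta$solvent)
}

#' Write a DSC thermogram to delimited text
#' @param tg a [thermogram()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_thermogram <- function(tg, path) {
  cpcol <- if (tg$units == "molar") "Cp_molar" else "Cp_specific"
  d <- data.frame(tg$T, tg$Cp)
  names(d) <- c("T_K", cpcol)
  .write_delim_block(path,
    list(scan_rate_K_min = tg$scan_rate, conc_mg_mL = tg$conc_mg_mL,
         mw_Da = tg$mw, psv_cm3_g = tg$psv, solvent = tg$solvent), d)
}
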