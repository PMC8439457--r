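#' Build an incubation-record table
#'
#' @param lake_id,bottle_id identifiers.
#' @param treatment `"dark"` or `"light"`.
#' @param o2_start,o2_end dissolved oxygen, mg L^-1.
#' @param duration_h incubation length, hours.
#' @return validated data frame.
#' @export
incubation_records <- function(lake_id, bottle_id, treatment, o2_start,
                               o2_end, duration_h) {
  stopifnot(all(treatment %in% c("dark", "light")), all(duration_h > 0),
            all(o2_start >= 0), all(o2_end >= 0))
  data.frame(lake_id = lake_id, bottle_id = bottle_id, treatment = treatment,
             o2_start = o2_start, o2_end = o2_end, duration_h = duration_h,
             stringsAsFactors = FALSE)
}

#' Total respiration rate from dark incubations
#'
#' Mean over dark bottles of the oxygen drawdown `(start - end) / duration`,
#' scaled to mg O2 L^-1 day^-1.  A respiratory quotient of 1 is assumed, so
#' oxygen consumption is reported as-is.  Net oxygen production in the dark
#' (all bottles gaining O2) yields a negative rate with a warning flag
#' rather than an error.
#'
#' @param records incubation records for one lake.
#' @return rate in mg O2 L^-1 day^-1, with attributes `unreplicated` (single
#'   bottle) and `negative` (net production).
#' @export
respiration_rate <- function(records) {
  dark <- records[records$treatment == "dark", , drop = FALSE]
  if (nrow(dark) == 0) stop("no dark bottles for this lake")
  rates <- (dark$o2_start - dark$o2_end) / dark$duration_h * 24
  out <- mean(rates)
  attr(out, "unreplicated") <- nrow(dark) < 2
  attr(out, "negative") <- out < 0
  if (out < 0)
    warning("net O2 production in dark bottles; negative respiration rate")
  out
}

#' Primary productivity from light incubations
#'
#' Mean over light bottles of the oxygen gain `(end - start) / duration` in
#' mg O2 L^-1 h^-1.  Note the sign convention is opposite to
#' [respiration_rate()]: production is positive here.
#'
#' @param records incubation records for one lake.
#' @return rate in mg O2 L^-1 h^-1 with the same flags as
#'   [respiration_rate()].
#' @export
primary_productivity <- function(records) {
  light <- records[records$treatment == "light", , drop = FALSE]
  if (nrow(light) == 0) stop("no light bottles for this lake")
  rates <- (light$o2_end - light$o2_start) / light$duration_h
  out <- mean(rates)
  attr(out, "unreplicated") <- nrow(light) < 2
  attr(out, "negative") <- out < 0
  out
}

#' CDOM spectral slope
#'
#' Exponent `S` of the single exponential decay `A(l) = A0 *
#' exp(-S * (l - l0))` of chromophoric dissolved organic matter absorbance,
#' estimated by ordinary least squares of `ln A` on wavelength over
#' `[lo, hi]` (default 275-295 nm).  `S` is reported positive for decaying
#' spectra.
#'
#' @param wavelength_nm strictly increasing wavelength grid.
#' @param absorbance matching absorbance values (1-cm path).
#' @param lo,hi fit window bounds in nm.
#' @return slope `S` in nm^-1.
#' @export
spectral_slope <- function(wavelength_nm, absorbance, lo = 275, hi = 295) {
  stopifnot(length(wavelength_nm) == length(absorbance))
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  in_win <- wavelength_nm >= lo & wavelength_nm <= hi
  keep <- in_win & absorbance > 0
  if (sum(keep) < 3)
    stop("fewer than 3 positive absorbance values in [", lo, ", ", hi, "] nm")
  fit <- stats::lm.fit(cbind(1, wavelength_nm[keep]),
                       log(absorbance[keep]))
  -unname(fit$coefficients[2])
}

#' Standardise a predictor to mean 0, SD 1
#'
#' Uses the sample (n-1) standard deviation; the centring constants are kept
#' so model coefficients can be back-transformed to natural units.
#'
#' @param x numeric vector with positive SD.
#' @return standardised vector with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardise a constant vector")
  structure((x - m) / s, center = m, scale = s)
}

#' Invert [standardize()]
#'
#' @param z standardised vector carrying `center`/`scale` attributes (or
#'   supply them explicitly).
#' @param center,scale standardisation constants.
#' @return vector on the original scale.
#' @export
unstandardize <- function(z, center = attr(z, "center"),
                          scale = attr(z, "scale")) {
  as.numeric(z) * scale + center
}
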