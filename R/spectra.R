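#' Construct an FTIR spectrum
#'
#' @param wavenumber strictly monotone grid, cm^-1 (conventionally
#'   400-4,000).
#' @param intensity finite intensities.
#' @param label optional class label (e.g., polymer name).
#' @return data frame of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumber, intensity, label = NA_character_) {
  stopifnot(length(wavenumber) == length(intensity),
            all(is.finite(intensity)))
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber grid must be strictly monotone")
  if (all(d < 0)) { wavenumber <- rev(wavenumber); intensity <- rev(intensity) }
  structure(data.frame(wavenumber = wavenumber, intensity = intensity),
            label = label, class = c("ftir_spectrum", "data.frame"))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing over a fixed wavenumber window
#' (default: third-order polynomial over 20 cm^-1, the common denoising
#' setting for 4 cm^-1 resolution ATR spectra).  Polynomials of degree at
#' most `poly_order` pass through unchanged.  Window edges are handled by
#' refitting the polynomial in the truncated window.
#'
#' @param spectrum an [ftir_spectrum()].
#' @param window_cm full window width in cm^-1.
#' @param poly_order polynomial degree.
#' @return smoothed [ftir_spectrum()].
#' @export
savgol_smooth <- function(spectrum, window_cm = 20, poly_order = 3) {
  w <- spectrum$wavenumber; y <- spectrum$intensity
  spacing <- stats::median(diff(w))
  half <- max(1L, round(window_cm / (2 * spacing)))
  if (2 * half + 1 < poly_order + 1)
    stop("window covers ", 2 * half + 1, " points; need at least ",
         poly_order + 1)
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    idx <- lo:hi
    deg <- min(poly_order, length(idx) - 1L)
    x <- w[idx] - w[i]
    X <- outer(x, 0:deg, `^`)
    out[i] <- stats::lm.fit(X, y[idx])$coefficients[1]
  }
  ftir_spectrum(w, out, label = attr(spectrum, "label"))
}

rolling_stat <- function(y, half, fun) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- fun(y[max(1L, i - half):min(n, i + half)])
  out
}

#' Baseline correction and peak normalisation
#'
#' Approximates the "15% adaptive baseline" of common FTIR software (the
#' exact procedure is proprietary) by a rolling-minimum baseline with a
#' window spanning `baseline_frac` of the spectral range, smoothed by a
#' rolling mean of the same window, subtracted from the signal; the result
#' is then scaled so the maximum intensity is 1.
#'
#' @param spectrum an [ftir_spectrum()].
#' @param baseline_frac window size as a fraction of the spectral span
#'   (default 0.15).
#' @return corrected, normalised [ftir_spectrum()].
#' @export
baseline_and_normalize <- function(spectrum, baseline_frac = 0.15) {
  w <- spectrum$wavenumber; y <- spectrum$intensity
  if (max(y) == min(y)) stop("constant spectrum has no peaks to normalise")
  spacing <- stats::median(diff(w))
  half <- max(1L, round(baseline_frac * diff(range(w)) / (2 * spacing)))
  base <- rolling_stat(rolling_stat(y, half, min), half, mean)
  corrected <- y - base
  m <- max(corrected)
  if (m <= 0) stop("spectrum is all-zero after baseline subtraction")
  ftir_spectrum(w, corrected / m, label = attr(spectrum, "label"))
}

#' Match a spectrum against a reference library
#'
#' Resamples query and library entries to a common grid (linear
#' interpolation at `grid_cm` spacing) over the fingerprint `region` and
#' scores each entry by the Pearson correlation coefficient.  The best match
#' is returned only when its `r` reaches `threshold`; otherwise the label is
#' `NA`.  Pearson correlation makes the match invariant to positive affine
#' transforms of either spectrum.
#'
#' @param query an [ftir_spectrum()].
#' @param library a list of labelled [ftir_spectrum()]s.
#' @param region wavenumber window, cm^-1 (default 700-1,850, the
#'   fingerprint region).
#' @param threshold minimum acceptable correlation (default 0.90).
#' @param grid_cm resampling interval, cm^-1.
#' @return list with `label` (`NA` if no match), `r` (best correlation) and
#'   `scores` (named vector of all correlations).
#' @export
library_match <- function(query, library, region = c(700, 1850),
                          threshold = 0.90, grid_cm = 4) {
  if (length(library) == 0) stop("reference library is empty")
  grid <- seq(region[1], region[2], by = grid_cm)
  resamp <- function(sp) stats::approx(sp$wavenumber, sp$intensity,
                                       xout = grid, rule = 2)$y
  q <- resamp(query)
  labels <- unname(vapply(library, function(sp)
    as.character(attr(sp, "label") %||% NA_character_), character(1)))
  labels[is.na(labels)] <- paste0("entry_", which(is.na(labels)))
  scores <- vapply(library, function(sp) {
    v <- resamp(sp)
    if (stats::sd(v) == 0 || stats::sd(q) == 0) return(NA_real_)
    stats::cor(q, v)
  }, numeric(1))
  names(scores) <- labels
  best <- which.max(scores)
  r <- scores[best]
  list(label = if (!is.na(r) && r >= threshold) labels[best] else NA_character_,
       r = unname(r), scores = scores)
}

#' Full preprocessing-and-match pipeline
#'
#' Enforces the processing order smooth -> baseline -> normalise -> match.
#'
#' @inheritParams library_match
#' @inheritParams savgol_smooth
#' @param baseline_frac see [baseline_and_normalize()].
#' @return as [library_match()].
#' @export
match_pipeline <- function(query, library, window_cm = 20, poly_order = 3,
                           baseline_frac = 0.15, region = c(700, 1850),
                           threshold = 0.90) {
  q <- baseline_and_normalize(savgol_smooth(query, window_cm, poly_order),
                              baseline_frac)
  library_match(q, library, region = region, threshold = threshold)
}

#' Read a two-column spectrum file
#'
#' @param path delimited text with columns wavenumber (or wavelength) and
#'   intensity; a header row is auto-detected.
#' @param label optional label to attach.
#' @return an [ftir_spectrum()].
#' @export
read_spectrum <- function(path, label = NA_character_) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, sep)[[1]][1])))
  d <- utils::read.table(path, header = has_header, sep = sep)
  ftir_spectrum(d[[1]], d[[2]], label = label)
}
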