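#' Emission-model parameters
#'
#' The catchment emission model is `E_m = a * (sum_i MPW_i * area_i *
#' g(R_i) * days)^b` for month `m`, where `MPW_i` is mismanaged plastic
#' waste generation (tonnes km^-2 day^-1) in cell `i`, `area_i` the cell
#' area in km^2, and `g` couples emission to runoff `R_i` (mm day^-1).  The
#' published calibration behind the original study is not reprinted there,
#' so the coefficients are pluggable with linear defaults (`a = 1`, `b = 1`,
#' `g(R) = R / runoff_ref`); users with the calibrated formula supply its
#' values.
#'
#' @param a positive scale coefficient.
#' @param b positive exponent.
#' @param runoff_coupling `"linear"` (only built-in family) or a function of
#'   the runoff vector.
#' @param runoff_ref reference runoff rate (mm day^-1) normalising the
#'   linear coupling.
#' @return list of class `emission_params`.
#' @export
emission_params <- function(a = 1, b = 1, runoff_coupling = "linear",
                            runoff_ref = 1) {
  stopifnot(a > 0, b > 0, runoff_ref > 0)
  g <- if (is.function(runoff_coupling)) runoff_coupling
  else if (identical(runoff_coupling, "linear"))
    function(R) R / runoff_ref
  else stop("unknown runoff coupling: ", runoff_coupling)
  structure(list(a = a, b = b, g = g), class = "emission_params")
}

#' Correct an MPW grid for subnational GDP
#'
#' Cellwise multiplicative scaling of mismanaged-plastic-waste generation by
#' a subnational/national GDP-per-capita ratio raster.
#'
#' @param mpw MPW raster (tonnes km^-2 day^-1, values >= 0).
#' @param gdp_ratio aligned ratio raster (dimensionless, >= 0).
#' @return corrected MPW raster.
#' @export
gdp_correct_mpw <- function(mpw, gdp_ratio) {
  raster_check_aligned(mpw, gdp_ratio)
  out <- mpw
  out$values <- mpw$values * gdp_ratio$values
  out
}

#' MPW generation from population density
#'
#' `MPW = population_density * per-capita waste * mismanaged fraction`; all
#' three are inputs, none is a built-in constant.
#'
#' @param population raster of people per cell.
#' @param waste_pc_tonnes_day per-capita solid waste generation, tonnes
#'   day^-1.
#' @param mismanaged_frac fraction of waste mismanaged, in `[0, 1]`.
#' @return MPW raster in tonnes km^-2 day^-1.
#' @export
mpw_from_population <- function(population, waste_pc_tonnes_day,
                                mismanaged_frac) {
  stopifnot(waste_pc_tonnes_day >= 0, mismanaged_frac >= 0,
            mismanaged_frac <= 1)
  area_km2 <- (population$cell_size_m / 1000)^2
  out <- population
  out$values <- population$values * waste_pc_tonnes_day * mismanaged_frac /
    area_km2
  out
}

#' Monthly plastic emission from a catchment
#'
#' @param mpw MPW raster, tonnes km^-2 day^-1, already masked to the
#'   catchment (cells outside set `NA` or 0) or accompanied by `mask`.
#' @param runoff_mm_day runoff for the month: a scalar or an aligned raster,
#'   mm day^-1.
#' @param params an [emission_params()].
#' @param days_in_month number of days (28-31).
#' @param mask optional raster; nonzero cells define the catchment.
#' @return emitted plastic mass, tonnes for the month.
#' @export
monthly_emission <- function(mpw, runoff_mm_day, params = emission_params(),
                             days_in_month = 30, mask = NULL) {
  stopifnot(inherits(params, "emission_params"),
            days_in_month >= 28, days_in_month <= 31)
  vals <- mpw$values
  if (!is.null(mask)) {
    raster_check_aligned(mpw, mask)
    vals[is.na(mask$values) | mask$values == 0] <- NA
  }
  R <- if (inherits(runoff_mm_day, "mp_raster")) {
    raster_check_aligned(mpw, runoff_mm_day)
    runoff_mm_day$values
  } else {
    matrix(runoff_mm_day, nrow(vals), ncol(vals))
  }
  if (any(R < 0, na.rm = TRUE)) stop("negative runoff")
  area_km2 <- (mpw$cell_size_m / 1000)^2
  load <- sum(vals * area_km2 * params$g(R) * days_in_month, na.rm = TRUE)
  params$a * load^params$b
}

#' Integrate emissions over the lake retention time
#'
#' Sums monthly emissions over a window of `retention_months` ending at (and
#' including) the sampling month; a fractional oldest month is weighted
#' proportionally.
#'
#' @param monthly_emissions numeric vector of emissions, oldest first.
#' @param retention_months positive, possibly fractional, retention time.
#' @param sampling_month index into `monthly_emissions` of the sampling
#'   month (default: last).
#' @return total emitted mass (tonnes).
#' @export
integrate_retention <- function(monthly_emissions, retention_months,
                                sampling_month = length(monthly_emissions)) {
  stopifnot(retention_months > 0, sampling_month >= 1,
            sampling_month <= length(monthly_emissions))
  n_full <- floor(retention_months)
  frac <- retention_months - n_full
  frac_month <- sampling_month - n_full
  if (sampling_month - ceiling(retention_months) + 1L < 1L)
    stop("retention window extends before the start of the emission series")
  total <- if (n_full > 0)
    sum(monthly_emissions[seq.int(sampling_month - n_full + 1L,
                                  sampling_month)]) else 0
  if (frac > 0) total <- total + frac * monthly_emissions[frac_month]
  total
}

#' Cube root of non-negative values
#'
#' The transformation applied to respiration and plastic-mass-input
#' predictors before standardisation (it tolerates exact zeros, unlike a log
#' transform).
#'
#' @param x non-negative numeric vector.
#' @return `x^(1/3)` with `cube_root(0) == 0`.
#' @export
cube_root <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("cube_root requires non-negative input")
  x^(1 / 3)
}
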