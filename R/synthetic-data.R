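#' Configuration for the synthetic global tow database
#'
#' Generative twin of the censored log-normal mixed model: each study has a
#' habitat, a mesh size and a random intercept; each tow adds residual noise
#' on the log scale.  Defaults give a database of roughly the published
#' scale (about 2,160 tows) with habitat contrasts of the order reported for
#' lakes, rivers and marine/estuarine waters.
#'
#' @param n_studies number of studies.
#' @param tows_per_study tows per study.
#' @param habitat_log_means named log-scale mean concentrations (particles
#'   m^-3) per habitat.
#' @param mesh_effect slope per standardised mesh unit (log scale).
#' @param study_sd SD of study random intercepts (log scale, >= 0).
#' @param resid_sd residual SD (log scale, > 0).
#' @param volume_range_m3 tow volumes are drawn log-uniformly on this
#'   interval (lower bound > 0).
#' @param mesh_range_um mesh sizes drawn uniformly on this interval.
#' @param seed integer seed.
#' @return list of class `towdb_sim_config`.
#' @export
towdb_sim_config <- function(n_studies = 90, tows_per_study = 24,
                             habitat_log_means = c(lake = log(0.30),
                                                   river = log(0.90),
                                                   marine_estuarine = log(0.35)),
                             mesh_effect = -0.5, study_sd = 1.0,
                             resid_sd = 0.8, volume_range_m3 = c(1, 1000),
                             mesh_range_um = c(45, 780), seed = 1L) {
  stopifnot(n_studies >= 1, tows_per_study >= 1, study_sd >= 0, resid_sd > 0,
            volume_range_m3[1] > 0, diff(volume_range_m3) >= 0)
  if (is.null(names(habitat_log_means)) ||
      !all(names(habitat_log_means) %in% TOW_HABITATS))
    stop("habitat_log_means must be named with habitats from: ",
         paste(TOW_HABITATS, collapse = ", "))
  structure(list(n_studies = n_studies, tows_per_study = tows_per_study,
                 habitat_log_means = habitat_log_means,
                 mesh_effect = mesh_effect, study_sd = study_sd,
                 resid_sd = resid_sd, volume_range_m3 = volume_range_m3,
                 mesh_range_um = mesh_range_um, seed = as.integer(seed)),
            class = "towdb_sim_config")
}

#' Generate a synthetic net-tow database
#'
#' Latent log concentration for tow `i` of study `s` in habitat `h` is
#' `alpha_h + beta_mesh * mesh_std + u_s + eps`; a concentration implying
#' fewer than one particle in the tow's filtered volume is recorded as 0
#' (censored), and every record carries its detection limit `1 / volume`.
#'
#' @param config a [towdb_sim_config()].
#' @return data frame of tow records (see [read_towdb()] for columns) plus
#'   the latent truth columns `latent_log_conc` and `censored`.
#' @export
gen_towdb <- function(config = towdb_sim_config()) {
  stopifnot(inherits(config, "towdb_sim_config"))
  set.seed(config$seed)
  habitats <- names(config$habitat_log_means)
  study_habitat <- habitats[(seq_len(config$n_studies) - 1L) %%
                              length(habitats) + 1L]
  u <- if (config$study_sd > 0)
    stats::rnorm(config$n_studies, 0, config$study_sd) else
      numeric(config$n_studies)
  mesh_um <- stats::runif(config$n_studies, config$mesh_range_um[1],
                          config$mesh_range_um[2])
  # standardised against the generating uniform distribution so the mesh
  # effect has a fixed meaning independent of the realised sample
  mesh_mu <- mean(config$mesh_range_um)
  mesh_sd <- diff(config$mesh_range_um) / sqrt(12)
  mesh_std <- (mesh_um - mesh_mu) / mesh_sd

  n <- config$n_studies * config$tows_per_study
  s <- rep(seq_len(config$n_studies), each = config$tows_per_study)
  vol <- exp(stats::runif(n, log(config$volume_range_m3[1]),
                          log(config$volume_range_m3[2])))
  eps <- stats::rnorm(n, 0, config$resid_sd)
  latent <- config$habitat_log_means[study_habitat[s]] +
    config$mesh_effect * mesh_std[s] + u[s] + eps
  conc <- exp(latent)
  dl <- 1 / vol
  censored <- conc < dl
  conc[censored] <- 0

  out <- data.frame(study_id = sprintf("study_%03d", s),
                    habitat = study_habitat[s],
                    mesh_size_um = mesh_um[s],
                    net_mouth_diameter_m = NA_real_,
                    tow_distance_m = NA_real_,
                    volume_m3 = vol,
                    concentration_per_m3 = conc,
                    detection_limit_per_m3 = dl,
                    lake_area_km2 = NA_real_,
                    latitude_deg = NA_real_,
                    latent_log_conc = unname(latent),
                    censored = censored,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(alpha = config$habitat_log_means,
                             beta_mesh = config$mesh_effect, u = u,
                             study_sd = config$study_sd,
                             resid_sd = config$resid_sd)
  out
}

#' Configuration for the synthetic lake survey
#'
#' Generative twin of the Poisson hurdle model for the 67-lake survey.
#' Defaults encode the surveyed world: 67 lakes, 7.1 m^3 tows, detection
#' probability 56/67 (11 zero-count lakes), a median count near 2 (0.28
#' particles m^-3), and true standardised coefficients at the midpoints of
#' the reported effect intervals for (cube-root plastic input, wastewater
#' load, forest cover, urban cover, cube-root respiration, log spectral
#' slope).
#'
#' @param n_lakes number of lakes.
#' @param beta named length-6 coefficient vector on the standardised scale.
#' @param intercept log mean count at the predictor means.
#' @param detect_prob probability a lake yields a nonzero count.
#' @param volume_m3 tow volume (constant across lakes).
#' @param predictor_dists list of parameter lists for the raw predictor
#'   distributions (see Details in the package vignette).
#' @param seed integer seed.
#' @return list of class `lake_sim_config`.
#' @export
lake_sim_config <- function(n_lakes = 67,
                            beta = c(plastic_input = 0.29, wwtw_load = 0.225,
                                     forest = -0.205, urban = -0.01,
                                     respiration = -0.32,
                                     spectral_slope = 0.01),
                            intercept = log(2), detect_prob = 56 / 67,
                            volume_m3 = 7.1,
                            predictor_dists = list(
                              plastic_input = list(meanlog = 0, sdlog = 1.5),
                              wwtw_load = list(meanlog = 8, sdlog = 2,
                                               p_zero = 0.25),
                              forest = list(shape1 = 2, shape2 = 2),
                              urban = list(shape1 = 1, shape2 = 9),
                              respiration = list(sd = 1),
                              spectral_slope = list(meanlog = log(0.02),
                                                    sdlog = 0.3)),
                            seed = 1L) {
  stopifnot(n_lakes >= 1, length(beta) == 6, detect_prob > 0,
            detect_prob <= 1, volume_m3 > 0)
  structure(list(n_lakes = n_lakes, beta = beta, intercept = intercept,
                 detect_prob = detect_prob, volume_m3 = volume_m3,
                 predictor_dists = predictor_dists, seed = as.integer(seed)),
            class = "lake_sim_config")
}

#' Zero-truncated Poisson sampler (inversion)
#'
#' @param n number of draws.
#' @param lambda rate(s), > 0.
#' @return integer draws, all >= 1.
#' @export
rztpois <- function(n, lambda) {
  stopifnot(all(lambda > 0))
  p0 <- stats::dpois(0, lambda)
  u <- stats::runif(n, p0, 1)
  out <- stats::qpois(u, lambda)
  pmax(out, 1L)
}

#' Generate a synthetic lake survey
#'
#' Raw predictors are drawn from skewed distributions mimicking field data
#' (lognormal plastic input and spectral slope, lognormal wastewater load
#' with a point mass at zero, Beta land-cover proportions, half-normal
#' respiration), transformed as in the analysis (cube roots for plastic
#' input and respiration, log for spectral slope) and standardised; counts
#' are zero with probability `1 - detect_prob` and otherwise zero-truncated
#' Poisson with log mean `intercept + X beta`.
#'
#' @param config a [lake_sim_config()].
#' @return data frame with raw predictors, `count` and `concentration_per_m3`;
#'   the standardised design matrix is attached as `attr(, "X")` and the
#'   generating parameters as `attr(, "truth")`.
#' @export
gen_lake_survey <- function(config = lake_sim_config()) {
  stopifnot(inherits(config, "lake_sim_config"))
  set.seed(config$seed)
  n <- config$n_lakes
  pd <- config$predictor_dists
  wwtw <- ifelse(stats::runif(n) < pd$wwtw_load$p_zero, 0,
                 stats::rlnorm(n, pd$wwtw_load$meanlog, pd$wwtw_load$sdlog))
  raw <- data.frame(
    plastic_input = stats::rlnorm(n, pd$plastic_input$meanlog,
                                  pd$plastic_input$sdlog),
    wwtw_load = wwtw,
    forest = stats::rbeta(n, pd$forest$shape1, pd$forest$shape2),
    urban = stats::rbeta(n, pd$urban$shape1, pd$urban$shape2),
    respiration = abs(stats::rnorm(n, 0, pd$respiration$sd)),
    spectral_slope = stats::rlnorm(n, pd$spectral_slope$meanlog,
                                   pd$spectral_slope$sdlog))
  if (!all(vapply(raw, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite predictor draws")
  X <- lake_design_matrix(raw)
  eta <- config$intercept + drop(X %*% config$beta)
  detected <- stats::runif(n) < config$detect_prob
  count <- integer(n)
  if (any(detected)) count[detected] <- rztpois(sum(detected),
                                                exp(eta[detected]))
  out <- cbind(raw, count = count,
               concentration_per_m3 = count / config$volume_m3)
  attr(out, "X") <- X
  attr(out, "truth") <- list(beta = config$beta,
                             intercept = config$intercept,
                             detect_prob = config$detect_prob,
                             volume_m3 = config$volume_m3)
  out
}

#' Standardised design matrix for the lake hurdle model
#'
#' Applies the analysis transforms (cube root for plastic input and
#' respiration, log for spectral slope, identity otherwise) and standardises
#' each column to mean 0, SD 1.
#'
#' @param survey data frame with the six raw predictor columns.
#' @return numeric matrix with 6 standardised columns.
#' @export
lake_design_matrix <- function(survey) {
  X <- cbind(plastic_input = as.numeric(standardize(cube_root(survey$plastic_input))),
             wwtw_load = as.numeric(standardize(survey$wwtw_load)),
             forest = as.numeric(standardize(survey$forest)),
             urban = as.numeric(standardize(survey$urban)),
             respiration = as.numeric(standardize(cube_root(survey$respiration))),
             spectral_slope = as.numeric(standardize(log(survey$spectral_slope))))
  X
}

#' Generate a toy landscape
#'
#' A deterministic (given `seed`) raster world: a terrain sloping towards a
#' single outlet on the bottom edge, a small flat-ish lake ringed by a
#' raised shoreline with one spill channel carved down to the outlet, a
#' coded land-cover grid (1 forest, 2 urban, 3 other, 4 water), a population
#' grid concentrated on urban cells, a 12-month runoff series (mm day^-1)
#' and two wastewater treatment plants.
#'
#' @param size_px grid edge length in cells (>= 5).
#' @param seed integer seed.
#' @param cell_size_m cell size (default 25 m).
#' @return list with `dem`, `lake_mask`, `landcover`, `population`
#'   ([mp_raster]s), `runoff` (length-12 numeric) and `wwtw_points` (data
#'   frame `x`, `y`, `load_pe`).
#' @export
gen_toy_landscape <- function(size_px = 21, seed = 1L, cell_size_m = 25) {
  stopifnot(size_px >= 5)
  set.seed(seed)
  n <- size_px
  out_rc <- c(n, (n + 1L) %/% 2L)  # outlet: bottom edge, centre column
  cheb <- outer(seq_len(n), seq_len(n),
                function(r, c) pmax(abs(r - out_rc[1]), abs(c - out_rc[2])))
  slope <- 0.2
  dem <- slope * cheb + matrix(stats::runif(n * n, -0.04, 0.04), n, n)
  dem[out_rc[1], out_rc[2]] <- 0

  # lake: a disc between grid centre and outlet, gently sloping to its exit
  lake_r <- max(1L, n %/% 8L)
  centre <- c(max(lake_r + 2L, n %/% 2L), out_rc[2])
  lk <- outer(seq_len(n), seq_len(n), function(r, c)
    pmax(abs(r - centre[1]), abs(c - centre[2]))) <= lake_r
  lk[n, ] <- FALSE  # keep the lake off the outlet edge
  # teardrop shape: the downstream-most row is the single exit cell, so all
  # lake flow leaves through one cell and the lake sits in its watershed
  q_row <- max(which(apply(lk, 1, any)))
  lk[q_row, setdiff(seq_len(n), centre[2])] <- FALSE
  q_rc <- c(q_row, centre[2])  # lake exit cell
  lake_lvl <- 0.02
  lk_idx <- which(lk, arr.ind = TRUE)
  dem[lk] <- lake_lvl + 0.01 * pmax(abs(lk_idx[, 1] - q_rc[1]),
                                    abs(lk_idx[, 2] - q_rc[2]))
  # raised shoreline rim except where the spill channel leaves
  rim <- dilate8(lk) & !lk
  rim[q_rc[1] + 1L, q_rc[2]] <- FALSE
  dem[rim] <- pmax(dem[rim], max(dem[lk]) + 0.5)
  # channel from the lake exit straight down to the outlet, strictly falling
  ch_rows <- seq.int(q_rc[1] + 1L, n)
  dem[cbind(ch_rows, out_rc[2])] <-
    seq(lake_lvl - 0.005, 0.001, length.out = length(ch_rows))
  # graded bottom edge so border cells drain along the edge to the outlet
  dem[n, ] <- lake_lvl + 0.05 * abs(seq_len(n) - out_rc[2])
  dem[out_rc[1], out_rc[2]] <- 0

  mk <- function(v) mp_raster(v, cell_size_m = cell_size_m, origin = c(0, 0))
  lc <- matrix(3, n, n)
  lc[, seq_len(max(1L, n %/% 3L))] <- 1                     # western forest
  urb <- seq.int(max(1L, n - n %/% 4L), n)
  lc[seq_len(max(2L, n %/% 4L)), urb] <- 2                  # NE urban block
  lc[lk] <- 4

  pop <- matrix(stats::rpois(n * n, 2), n, n)
  pop[lc == 2] <- pop[lc == 2] + stats::rpois(sum(lc == 2), 50)
  pop[lk] <- 0

  runoff <- pmax(0.1, 1.5 + sin(2 * pi * (1:12) / 12) +
                   stats::rnorm(12, 0, 0.2))

  land <- which(lc != 4 & !rim, arr.ind = TRUE)
  pick <- land[sample.int(nrow(land), 2L), , drop = FALSE]
  wwtw <- data.frame(
    x = (pick[, 2] - 0.5) * cell_size_m,
    y = (n - pick[, 1] + 0.5) * cell_size_m,
    load_pe = round(stats::rlnorm(2, meanlog = 8, sdlog = 1)))

  list(dem = mk(dem), lake_mask = mk(lk + 0), landcover = mk(lc),
       population = mk(pop), runoff = runoff, wwtw_points = wwtw)
}

#' Generate a synthetic spectrum
#'
#' `kind = "cdom"`: exponential-decay absorbance `A0 * exp(-S * (l - l0))`
#' on a 200-700 nm grid with optional Gaussian noise.  `kind = "ftir"`: a
#' sum of Gaussian bands on a 400-4,000 cm^-1 grid (4 cm^-1 spacing) with
#' optional noise.
#'
#' @param kind `"cdom"` or `"ftir"`.
#' @param params for cdom: `A0`, `S` (nm^-1), `l0`, `noise_sd`; for ftir:
#'   `bands` (data frame with `center`, `width`, `height`), `noise_sd`.
#' @param seed integer seed.
#' @return data frame with `wavelength_nm`/`absorbance` (cdom) or an
#'   [ftir_spectrum()] (ftir).
#' @export
gen_spectra <- function(kind = c("cdom", "ftir"), params = list(),
                        seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "cdom") {
    p <- utils::modifyList(list(A0 = 2, S = 0.02, l0 = 200, noise_sd = 0),
                           params)
    wl <- seq(200, 700, by = 1)
    A <- p$A0 * exp(-p$S * (wl - p$l0))
    if (p$noise_sd > 0) A <- A + stats::rnorm(length(wl), 0, p$noise_sd)
    data.frame(wavelength_nm = wl, absorbance = A)
  } else {
    p <- list(bands = data.frame(center = c(1100, 1725), width = c(40, 30),
                                 height = c(1, 0.8)),
              noise_sd = 0, label = NA_character_)
    p[names(params)] <- params  # replace wholesale; no recursive merging
    wn <- seq(400, 4000, by = 4)
    y <- rep(0, length(wn))
    for (i in seq_len(nrow(p$bands)))
      y <- y + p$bands$height[i] *
        exp(-(wn - p$bands$center[i])^2 / (2 * p$bands$width[i]^2))
    if (p$noise_sd > 0) y <- y + stats::rnorm(length(wn), 0, p$noise_sd)
    ftir_spectrum(wn, y, label = p$label)
  }
}

#' Small synthetic FTIR reference library
#'
#' Four fabricated band patterns standing in for common polymer classes.
#' These are synthetic stand-ins, not measured reference spectra.
#'
#' @param seed integer seed (noise-free by default, so the seed only matters
#'   if `noise_sd > 0`).
#' @param noise_sd optional Gaussian noise.
#' @return named list of [ftir_spectrum()]s.
#' @export
synthetic_ftir_library <- function(seed = 1L, noise_sd = 0) {
  bands <- list(
    polyethylene_synth = data.frame(center = c(720, 1465, 2850, 2920),
                                    width = c(15, 20, 25, 25),
                                    height = c(0.4, 0.6, 0.9, 1)),
    polyester_synth = data.frame(center = c(725, 1095, 1240, 1715),
                                 width = c(15, 30, 30, 25),
                                 height = c(0.5, 0.8, 0.9, 1)),
    polyamide_synth = data.frame(center = c(690, 1540, 1635, 3300),
                                 width = c(25, 25, 25, 60),
                                 height = c(0.4, 0.8, 1, 0.6)),
    cellulose_synth = data.frame(center = c(1030, 1110, 1160, 3340),
                                 width = c(35, 25, 20, 80),
                                 height = c(1, 0.7, 0.5, 0.6)))
  out <- lapply(names(bands), function(nm)
    gen_spectra("ftir", params = list(bands = bands[[nm]],
                                      noise_sd = noise_sd, label = nm),
                seed = seed))
  names(out) <- names(bands)
  out
}
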