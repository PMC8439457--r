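test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_towdb(towdb_sim_config(seed = 8)),
                   gen_towdb(towdb_sim_config(seed = 8)))
  expect_identical(gen_lake_survey(lake_sim_config(seed = 8)),
                   gen_lake_survey(lake_sim_config(seed = 8)))
  l1 <- gen_toy_landscape(9, seed = 8)
  l2 <- gen_toy_landscape(9, seed = 8)
  expect_identical(l1$dem$values, l2$dem$values)
  expect_identical(l1$wwtw_points, l2$wwtw_points)
  expect_identical(gen_spectra("ftir", seed = 8),
                   gen_spectra("ftir", seed = 8))
  # different seeds differ
  expect_false(identical(l1$dem$values,
                         gen_toy_landscape(9, seed = 9)$dem$values))
})

test_that("tow generator collapses to habitat means in the zero-noise limit", {
  cfg <- towdb_sim_config(n_studies = 6, tows_per_study = 10, study_sd = 0,
                          resid_sd = 1e-12, mesh_effect = 0,
                          volume_range_m3 = c(100, 100), seed = 1)
  db <- gen_towdb(cfg)
  for (h in unique(db$habitat)) {
    conc <- db$concentration_per_m3[db$habitat == h]
    expect_equal(conc, rep(exp(cfg$habitat_log_means[h]), length(conc)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("log concentrations of positive tows centre on the habitat mean", {
  # large-volume tows so censoring is negligible, no mesh or study effects
  cfg <- towdb_sim_config(n_studies = 10, tows_per_study = 1000,
                          habitat_log_means = c(lake = log(0.3)),
                          mesh_effect = 0, study_sd = 0, resid_sd = 0.8,
                          volume_range_m3 = c(1e4, 1e4), seed = 33)
  db <- gen_towdb(cfg)
  pos <- db$concentration_per_m3 > 0
  expect_gt(mean(pos), 0.999)
  se <- cfg$resid_sd / sqrt(sum(pos))
  expect_lt(abs(mean(log(db$concentration_per_m3[pos])) - log(0.3)), 3 * se)
})

test_that("censoring responds to the habitat mean as expected", {
  # means far below the detection limit: all zeros
  low <- towdb_sim_config(n_studies = 4, tows_per_study = 25,
                          habitat_log_means = c(lake = -40),
                          volume_range_m3 = c(1, 10), seed = 2)
  expect_true(all(gen_towdb(low)$concentration_per_m3 == 0))
  # zero fraction is monotone non-increasing in the habitat means
  shifts <- c(-4, -2, 0, 2)
  zf <- vapply(shifts, function(s) {
    cfg <- towdb_sim_config(n_studies = 30, tows_per_study = 40,
                            habitat_log_means = c(lake = log(0.3) + s),
                            volume_range_m3 = c(1, 10), seed = 7)
    mean(gen_towdb(cfg)$concentration_per_m3 == 0)
  }, numeric(1))
  expect_true(all(diff(zf) <= 0))
  # recorded zeros are exactly the latent values below 1/volume
  db <- gen_towdb(towdb_sim_config(seed = 3))
  expect_true(all((db$concentration_per_m3 == 0) ==
                    (exp(db$latent_log_conc) < db$detection_limit_per_m3)))
})

test_that("lake survey counts follow the hurdle structure", {
  # detect_prob = 1, beta = 0: plain zero-truncated Poisson draws
  lam <- exp(log(2))
  cfg <- lake_sim_config(n_lakes = 4000, detect_prob = 1,
                         beta = setNames(rep(0, 6), names(lake_sim_config()$beta)),
                         seed = 21)
  survey <- gen_lake_survey(cfg)
  expect_true(all(survey$count >= 1))
  m_true <- lam / (1 - exp(-lam))
  se <- sd(survey$count) / sqrt(nrow(survey))
  expect_lt(abs(mean(survey$count) - m_true), 3 * se)

  # zero fraction matches 1 - detect_prob within binomial tolerance
  cfg2 <- lake_sim_config(n_lakes = 67, seed = 14)
  s2 <- gen_lake_survey(cfg2)
  p0 <- 1 - cfg2$detect_prob
  tol <- 3 * sqrt(p0 * (1 - p0) / 67)
  expect_lt(abs(mean(s2$count == 0) - p0), tol + 1e-9)
  # concentration is count over volume
  expect_equal(s2$concentration_per_m3, s2$count / cfg2$volume_m3)
  # design matrix is standardised
  X <- attr(s2, "X")
  expect_equal(unname(colMeans(X)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 6), tolerance = 1e-10)
})

test_that("toy landscape drains fully and honours its contracts", {
  land <- gen_toy_landscape(13, seed = 5)
  expect_length(land$runoff, 12)
  expect_true(all(land$runoff > 0))
  expect_true(all(land$landcover$values %in% 1:4))
  expect_true(all(land$population$values >= 0))
  expect_equal(nrow(land$wwtw_points), 2)
  # every cell has a monotone downhill path to the single outlet
  expect_monotone_path_to_edge(land$dem)
  dir <- d8_flow_direction(fill_depressions(land$dem))
  expect_equal(sum(dir$values == 0, na.rm = TRUE), 1)
  # the lake lies inside the watershed of its own pour point
  acc <- flow_accumulation(dir)
  pour <- find_pour_point(acc, land$lake_mask)
  ws <- delineate_watershed(dir, pour)
  expect_true(all(ws$values[land$lake_mask$values != 0] == 1))
  expect_error(gen_toy_landscape(4), "size_px")
})

test_that("synthetic spectra have the stated functional forms", {
  # noiseless cdom decay is recovered exactly by the slope estimator
  sp <- gen_spectra("cdom", params = list(S = 0.02), seed = 1)
  expect_equal(spectral_slope(sp$wavelength_nm, sp$absorbance), 0.02,
               tolerance = 1e-9)
  # ftir self-match at r = 1
  ft <- gen_spectra("ftir", seed = 1)
  m <- library_match(ft, list(ftir_spectrum(ft$wavenumber, ft$intensity,
                                            label = "self")))
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_equal(m$label, "self")
})

test_that("truncated Poisson sampler matches the analytic pmf", {
  set.seed(4)
  lam <- 1.3
  draws <- rztpois(20000, lam)
  expect_true(all(draws >= 1))
  for (k in 1:4) {
    p_hat <- mean(draws == k)
    p <- ztp_pmf_oracle(k, lam)
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 20000) + 1e-9)
  }
})
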