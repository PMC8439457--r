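test_that("zero-truncated Poisson log pmf normalises and has the right mean", {
  lam <- 3
  p <- exp(trunc_pois_logpmf(1:200, lam))
  expect_lt(abs(sum(p) - 1), 1e-10)
  # brute-force moment at lambda = 2
  p2 <- exp(trunc_pois_logpmf(1:300, 2))
  expect_equal(sum((1:300) * p2), trunc_pois_mean(2), tolerance = 1e-10)
  # matches the renormalised-Poisson oracle pointwise
  expect_equal(exp(trunc_pois_logpmf(1:20, 1.7)),
               ztp_pmf_oracle(1:20, 1.7), tolerance = 1e-12)
  # lambda -> 0: all mass on k = 1
  expect_equal(exp(trunc_pois_logpmf(1, 1e-8)), 1, tolerance = 1e-6)
  expect_error(trunc_pois_logpmf(0, 1), "k >= 1")
  expect_error(trunc_pois_logpmf(1, 0), "positive")
})

test_that("censored log-normal likelihood matches independent density code", {
  d <- cens_lnm_data(concentration = c(0.5, 0, 2.1),
                     habitat = c("lake", "lake", "river"),
                     mesh_size_um = c(100, 300, 500),
                     study = c("a", "a", "b"),
                     detection_limit = c(0.1, 0.2, 0.1))
  params <- list(alpha = c(lake = -1, river = 0.2), beta_mesh = -0.3,
                 u = c(0.1, -0.2), sigma_study = 0.5, sigma = 0.8)
  mesh_std <- as.numeric(standardize(c(100, 300, 500)))
  mu <- params$alpha[c("lake", "lake", "river")] +
    params$beta_mesh * mesh_std + params$u[c(1, 1, 2)]
  # independent implementation: hand-written log-normal density + normal cdf
  manual <- (-log(0.5) - log(0.8) - 0.5 * log(2 * pi) -
               (log(0.5) - mu[1])^2 / (2 * 0.8^2)) +
    pnorm((log(0.2) - mu[2]) / 0.8, log.p = TRUE) +
    (-log(2.1) - log(0.8) - 0.5 * log(2 * pi) -
       (log(2.1) - mu[3])^2 / (2 * 0.8^2)) +
    sum(dnorm(params$u, 0, 0.5, log = TRUE))
  expect_equal(cens_lnm_loglik(params, d), unname(manual), tolerance = 1e-12)
  expect_equal(cens_lnm_loglik(modifyList(params, list(sigma = -1)), d),
               -Inf)
  # censored term -> log(1) = 0 as the detection limit grows
  d_inf <- cens_lnm_data(0, "lake", 300, "a", detection_limit = 1e12)
  p0 <- list(alpha = c(lake = 0), beta_mesh = 0, u = 0, sigma_study = 0,
             sigma = 1)
  expect_equal(cens_lnm_loglik(p0, d_inf), 0, tolerance = 1e-10)
})

test_that("censored and observed probability mass sum to one by quadrature", {
  mu <- -0.7; sigma <- 0.9; L <- 0.25
  below <- pnorm((log(L) - mu) / sigma)
  above <- integrate(function(y) dlnorm(y, mu, sigma), L, Inf,
                     rel.tol = 1e-10)$value
  expect_lt(abs(below + above - 1), 1e-8)
  # the censored-term probability equals the quadrature of the density
  below_quad <- integrate(function(y) dlnorm(y, mu, sigma), 0, L,
                          rel.tol = 1e-10)$value
  expect_equal(below, below_quad, tolerance = 1e-8)
})

test_that("hurdle likelihood matches a brute-force product on a 5-lake toy", {
  X <- matrix(c(0.5, -1, 0, 1, -0.5,
                -0.2, 0.3, 1, -1, 0.1), 5, 2,
              dimnames = list(NULL, c("p1", "p2")))
  d <- suppressWarnings(hurdle_data(c(0, 2, 1, 0, 4), X))
  params <- list(pi = 0.7, beta0 = 0.4, beta = c(0.3, -0.2))
  lam <- exp(0.4 + X %*% c(0.3, -0.2))
  probs <- numeric(5)
  for (i in 1:5) {
    probs[i] <- if (d$k[i] == 0) 1 - 0.7
      else 0.7 * dpois(d$k[i], lam[i]) / (1 - dpois(0, lam[i]))
  }
  expect_equal(hurdle_loglik(params, d), sum(log(probs)), tolerance = 1e-10)
  expect_equal(hurdle_loglik(modifyList(params, list(pi = 1.2)), d), -Inf)
  # all positive counts: Bernoulli part contributes n log(pi)
  d_pos <- suppressWarnings(hurdle_data(c(1, 2, 1, 3, 4), X))
  ll1 <- hurdle_loglik(list(pi = 0.6, beta0 = 0.4, beta = c(0.3, -0.2)),
                       d_pos)
  ll2 <- hurdle_loglik(list(pi = 0.9, beta0 = 0.4, beta = c(0.3, -0.2)),
                       d_pos)
  expect_equal(ll1 - ll2, 5 * (log(0.6) - log(0.9)), tolerance = 1e-10)
})

test_that("with beta = 0 the likelihood-maximising pi is the positive fraction", {
  set.seed(6)
  X <- matrix(rnorm(40), 20, 2)
  X <- scale(X)[, ]
  k <- c(rep(0, 6), rpois(14, 2) + 1)
  d <- suppressWarnings(hurdle_data(k, X))
  pis <- seq(0.05, 0.95, by = 0.005)
  lls <- vapply(pis, function(p)
    hurdle_loglik(list(pi = p, beta0 = log(2), beta = c(0, 0)), d),
    numeric(1))
  expect_equal(pis[which.max(lls)], 14 / 20, tolerance = 0.005)
})

test_that("the hurdle fit recovers a known survey and reduces to Poisson GLM", {
  # strong-signal synthetic survey at n = 670
  cfg <- lake_sim_config(
    n_lakes = 670,
    beta = c(plastic_input = 0.3, wwtw_load = 0.2, forest = -0.2,
             urban = 0, respiration = -0.3, spectral_slope = 0),
    seed = 31)
  survey <- gen_lake_survey(cfg)
  d <- hurdle_data(survey$count, attr(survey, "X"))
  fit <- suppressWarnings(fit_hurdle(
    d, mcmc = list(chains = 2, iter = 500, warmup = 300, seed = 4)))
  s <- fit$summaries
  truth <- c(0.3, 0.2, -0.2, 0, -0.3, 0)
  b <- s[grepl("^beta\\[", s$param), ]
  # signs of nonzero coefficients recovered; joint coverage of all six 95%
  # intervals holds only ~74% of the time, so require at least 5 of 6
  expect_true(all(sign(b$mean[truth != 0]) == sign(truth[truth != 0])))
  expect_gte(sum(b$q2.5 <= truth & truth <= b$q97.5), 5)
  # detection probability recovered
  pi_mean <- mean(plogis(fit$flat[, "logit_pi"]))
  expect_lt(abs(pi_mean - cfg$detect_prob), 0.05)

  # with all counts positive and large (lambda >> 1) the truncation
  # correction vanishes and the fit reduces to an independent Poisson GLM
  cfg2 <- lake_sim_config(n_lakes = 300, intercept = log(20),
                          detect_prob = 1,
                          beta = c(plastic_input = 0.3, wwtw_load = 0.2,
                                   forest = -0.2, urban = 0,
                                   respiration = -0.3, spectral_slope = 0),
                          seed = 32)
  s2 <- gen_lake_survey(cfg2)
  d2 <- hurdle_data(s2$count, attr(s2, "X"))
  fit2 <- suppressWarnings(fit_hurdle(
    d2, mcmc = list(chains = 2, iter = 500, warmup = 300, seed = 5)))
  glm_fit <- glm(s2$count ~ attr(s2, "X"), family = poisson())
  b2 <- fit2$summaries[grepl("^beta\\[", fit2$summaries$param), ]
  expect_lt(max(abs(unname(coef(glm_fit)[-1]) - b2$mean)), 0.02)
  expect_lt(abs(unname(coef(glm_fit)[1]) -
                  fit2$summaries$mean[fit2$summaries$param == "beta0"]),
            0.02)
})

test_that("habitat contrasts are antisymmetric with zero self-contrast", {
  db <- gen_towdb(towdb_sim_config(n_studies = 9, tows_per_study = 8,
                                   seed = 12))
  fit <- suppressWarnings(fit_cens_lnm(
    towdb_to_censdata(db),
    mcmc = list(chains = 2, iter = 400, warmup = 300, seed = 5)))
  hc <- habitat_contrasts(fit)
  expect_equal(nrow(hc), 3)  # three habitat pairs
  # antisymmetry draw-by-draw: recompute with swapped habitats
  flat <- fit$flat
  a <- exp(flat[, "alpha[lake]"])
  b <- exp(flat[, "alpha[river]"])
  expect_equal(mean(a - b), hc$mean[hc$habitat_a == "lake" &
                                      hc$habitat_b == "river"])
  expect_equal(mean(b - a), -hc$mean[hc$habitat_a == "lake" &
                                       hc$habitat_b == "river"])
  # self-contrast is identically zero
  expect_equal(unname(quantile(a - a, c(0.025, 0.975))), c(0, 0))
})

test_that("bayes_r2 agrees with a straight-formula oracle on fixed draws", {
  cfg <- lake_sim_config(n_lakes = 67, seed = 17)
  survey <- gen_lake_survey(cfg)
  d <- hurdle_data(survey$count, attr(survey, "X"))
  fit <- suppressWarnings(fit_hurdle(
    d, mcmc = list(chains = 2, iter = 300, warmup = 200, seed = 6)))
  r2 <- bayes_r2(fit)
  expect_true(all(r2$draws >= 0 & r2$draws <= 1))
  # oracle: recompute for 10 fixed draws from first principles
  flat <- fit$flat
  for (s in c(1, 50, 100, 200, 300, 400, 500, 599, 600, 42)) {
    pi <- plogis(flat[s, "logit_pi"])
    beta <- flat[s, grepl("^beta\\[", colnames(flat))]
    lam <- exp(flat[s, "beta0"] + drop(d$X %*% beta))
    m <- pi * lam / (1 - exp(-lam))
    v <- pi * (lam + lam^2) / (1 - exp(-lam)) - m^2
    expect_equal(r2$draws[s], var(m) / (var(m) + mean(v)),
                 tolerance = 1e-10)
  }
})

test_that("marginal effects are flat for null predictors and exponential for
           strong ones", {
  # large intercept so the zero-truncation correction is negligible and the
  # closed form ratio = exp(beta_j * range) applies (pi cancels)
  cfg <- lake_sim_config(n_lakes = 670, intercept = log(20), seed = 23)
  survey <- gen_lake_survey(cfg)
  d <- hurdle_data(survey$count, attr(survey, "X"))
  fit <- suppressWarnings(fit_hurdle(
    d, mcmc = list(chains = 2, iter = 500, warmup = 300, seed = 7)))
  me <- marginal_effect(fit, "respiration")
  rng <- diff(range(d$X[, "respiration"]))
  b_hat <- fit$summaries$mean[fit$summaries$param == "beta[respiration]"]
  expect_equal(log(me$endpoint_ratio$mean), b_hat * rng, tolerance = 0.1)
  # monotone curve when the coefficient posterior is one-signed
  b_draws <- fit$flat[, "beta[respiration]"]
  if (all(b_draws < 0)) expect_true(all(diff(me$curve$mean) < 0))
  # out-of-range grid warns
  expect_warning(marginal_effect(fit, "forest", grid = c(-10, 10)),
                 "outside")
  expect_error(marginal_effect(fit, "nope"), "unknown predictor")
})
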