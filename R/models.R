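#' Data container for the censored log-normal mixed model
#'
#' @param concentration tow concentrations, particles m^-3 (0 = censored
#'   below the detection limit).
#' @param habitat habitat labels (`lake`, `river`, `marine_estuarine`).
#' @param mesh_size_um mesh sizes; standardised internally.
#' @param study study identifiers (random-intercept grouping).
#' @param detection_limit detection limits, particles m^-3 (> 0).
#' @return list of class `cens_lnm_data` with elements `y`, `habitat`
#'   (factor), `mesh` (standardised), `study` (factor), `L`, `censored`.
#' @export
cens_lnm_data <- function(concentration, habitat, mesh_size_um, study,
                          detection_limit) {
  stopifnot(all(concentration >= 0), all(detection_limit > 0),
            length(concentration) == length(habitat),
            length(concentration) == length(mesh_size_um),
            length(concentration) == length(study),
            length(concentration) == length(detection_limit))
  if (!all(habitat %in% TOW_HABITATS))
    stop("unknown habitat labels: ",
         paste(unique(setdiff(habitat, TOW_HABITATS)), collapse = ", "))
  mesh <- if (length(unique(mesh_size_um)) > 1)
    as.numeric(standardize(mesh_size_um)) else rep(0, length(mesh_size_um))
  structure(list(y = concentration,
                 habitat = factor(habitat, levels = intersect(TOW_HABITATS,
                                                              unique(habitat))),
                 mesh = mesh,
                 study = factor(study),
                 L = detection_limit,
                 # a value exactly at its detection limit counts as observed
                 censored = concentration < detection_limit &
                   concentration == 0),
            class = "cens_lnm_data")
}

#' Convert a tow database to model data
#'
#' @param db data frame from [read_towdb()] or [gen_towdb()].
#' @return a [cens_lnm_data()].
#' @export
towdb_to_censdata <- function(db) {
  cens_lnm_data(db$concentration_per_m3, db$habitat, db$mesh_size_um,
                db$study_id, db$detection_limit_per_m3)
}

#' Censored log-normal mixed-model log-likelihood
#'
#' Location for tow `i`: `mu_i = alpha[habitat_i] + beta_mesh * mesh_i +
#' u[study_i]`.  Uncensored tows contribute the log-normal log density at
#' `y_i`; censored tows (recorded zeros) contribute `log Phi((log L_i -
#' mu_i) / sigma)`, the probability of falling below the detection limit;
#' study intercepts contribute `sum log N(u_s; 0, sigma_study)`.
#'
#' @param params list with `alpha` (named by habitat level), `beta_mesh`,
#'   `u` (one per study level), `sigma_study` (>= 0), `sigma` (> 0).
#' @param data a [cens_lnm_data()].
#' @return log-likelihood; `-Inf` for invalid scale parameters.
#' @export
cens_lnm_loglik <- function(params, data) {
  if (params$sigma <= 0 || params$sigma_study < 0) return(-Inf)
  mu <- params$alpha[as.character(data$habitat)] +
    params$beta_mesh * data$mesh + params$u[as.integer(data$study)]
  ll <- 0
  obs <- !data$censored
  if (any(obs))
    ll <- ll + sum(stats::dlnorm(data$y[obs], mu[obs], params$sigma,
                                 log = TRUE))
  if (any(!obs))
    ll <- ll + sum(stats::pnorm((log(data$L[!obs]) - mu[!obs]) / params$sigma,
                                log.p = TRUE))
  if (params$sigma_study > 0) {
    ll <- ll + sum(stats::dnorm(params$u, 0, params$sigma_study, log = TRUE))
  } else if (any(params$u != 0)) {
    return(-Inf)
  }
  ll
}

#' Zero-truncated Poisson log pmf
#'
#' `log P(K = k) = k log(lambda) - lambda - log(1 - exp(-lambda)) - log k!`
#' for integer `k >= 1`.
#'
#' @param k positive integer counts.
#' @param lambda positive rate(s).
#' @return log probabilities.
#' @export
trunc_pois_logpmf <- function(k, lambda) {
  if (any(k < 1) || any(k != floor(k)))
    stop("zero-truncated Poisson requires integer k >= 1")
  if (any(lambda <= 0)) stop("lambda must be positive")
  k * log(lambda) - lambda - log1mexp(lambda) - lgamma(k + 1)
}

# log(1 - exp(-a)) computed stably for a > 0
log1mexp <- function(a) {
  ifelse(a > log(2), log1p(-exp(-a)), log(-expm1(-a)))
}

#' Mean of the zero-truncated Poisson
#'
#' @param lambda positive rate(s).
#' @return `lambda / (1 - exp(-lambda))`.
#' @export
trunc_pois_mean <- function(lambda) lambda / (1 - exp(-lambda))

#' Data container for the Poisson hurdle model
#'
#' @param count per-lake microparticle counts (>= 0).
#' @param X standardised predictor matrix (columns centred at ~0 with SD
#'   ~1).
#' @param volume_m3 tow volume, constant across lakes, used only to report
#'   concentrations.
#' @return list of class `hurdle_data`.
#' @export
hurdle_data <- function(count, X, volume_m3 = 7.1) {
  X <- as.matrix(X)
  stopifnot(all(count >= 0), all(count == floor(count)),
            nrow(X) == length(count), volume_m3 > 0)
  if (any(abs(colMeans(X)) > 0.2) ||
      any(abs(apply(X, 2, stats::sd) - 1) > 0.2))
    warning("design matrix columns are not standardised (mean 0, SD 1)")
  structure(list(k = as.integer(count), X = X, volume_m3 = volume_m3),
            class = "hurdle_data")
}

#' Poisson hurdle log-likelihood
#'
#' Zero counts contribute `log(1 - pi)`; positive counts contribute
#' `log(pi)` plus the zero-truncated Poisson log pmf with `log lambda_i =
#' beta0 + x_i' beta`.  The detection probability is intercept-only: the
#' model estimates one probability of detecting microparticles across all
#' samples.  Volume is constant across lakes, so no offset is needed; it
#' only rescales reported concentrations.
#'
#' @param params list with `pi` in (0, 1), `beta0`, `beta` (one per column
#'   of `X`).
#' @param data a [hurdle_data()].
#' @return log-likelihood; `-Inf` if `pi` is outside (0, 1).
#' @export
hurdle_loglik <- function(params, data) {
  if (params$pi <= 0 || params$pi >= 1) return(-Inf)
  pos <- data$k > 0
  ll <- sum(!pos) * log(1 - params$pi) + sum(pos) * log(params$pi)
  if (any(pos)) {
    lambda <- exp(params$beta0 + drop(data$X[pos, , drop = FALSE] %*%
                                        params$beta))
    ll <- ll + sum(trunc_pois_logpmf(data$k[pos], lambda))
  }
  ll
}

#' Default weakly informative priors
#'
#' Normal(0, 2.5) on standardised-scale coefficients, half-Normal(0, 2.5)
#' on standard deviations, Beta(1, 1) on the detection probability.
#'
#' @param coef_sd prior SD for location coefficients.
#' @param sd_sd prior SD for half-normal scale priors.
#' @param pi_shape1,pi_shape2 Beta prior shapes for the detection
#'   probability.
#' @return list of prior settings.
#' @export
default_priors <- function(coef_sd = 2.5, sd_sd = 2.5, pi_shape1 = 1,
                           pi_shape2 = 1) {
  list(coef_sd = coef_sd, sd_sd = sd_sd, pi_shape1 = pi_shape1,
       pi_shape2 = pi_shape2)
}

new_mp_fit <- function(draws, model, data, extra = list()) {
  dn <- dimnames(draws)[[3]]
  rh <- rhat(draws)
  es <- ess(draws)
  flat <- do.call(rbind, lapply(seq_len(dim(draws)[2]),
                                function(ch) matrix(draws[, ch, ],
                                                    ncol = dim(draws)[3])))
  colnames(flat) <- dn
  summaries <- data.frame(
    param = dn,
    mean = colMeans(flat),
    sd = apply(flat, 2, stats::sd),
    q2.5 = apply(flat, 2, stats::quantile, 0.025),
    q97.5 = apply(flat, 2, stats::quantile, 0.975),
    rhat = rh, ess = es, row.names = NULL)
  converged <- all(rh <= 1.01) && all(es >= 800)
  if (!converged)
    warning("fit did not meet the Rhat <= 1.01 / ESS >= 800 gates; ",
            "returned flagged, inspect diagnostics before use")
  structure(c(list(draws = draws, flat = flat, summaries = summaries,
                   converged = converged, model = model, data = data),
              extra),
            class = "mp_fit")
}

#' @export
print.mp_fit <- function(x, ...) {
  cat(sprintf("<mp_fit: %s> %d draws x %d chains, converged: %s\n",
              x$model, dim(x$draws)[1], dim(x$draws)[2], x$converged))
  print(x$summaries, digits = 3)
  invisible(x)
}

#' @export
summary.mp_fit <- function(object, ...) object$summaries

#' Fit the censored log-normal mixed model
#'
#' Habitat means, a standardised mesh-size effect, study random intercepts
#' with an estimated standard deviation, and a censored likelihood for
#' zero records.  Scale parameters are sampled on the log scale (with the
#' Jacobian correction) under half-normal priors.
#'
#' @param data a [cens_lnm_data()].
#' @param mcmc list with `chains`, `iter`, `warmup`, `seed`.
#' @param priors see [default_priors()].
#' @return an `mp_fit`; the fit is flagged (not rejected) if diagnostics
#'   miss the acceptance gates.
#' @export
fit_cens_lnm <- function(data,
                         mcmc = list(chains = 4, iter = 1000, warmup = 500,
                                     seed = 1),
                         priors = default_priors()) {
  stopifnot(inherits(data, "cens_lnm_data"))
  H <- nlevels(data$habitat)
  S <- nlevels(data$study)
  hlev <- levels(data$habitat)
  hidx <- as.integer(data$habitat)
  sidx <- as.integer(data$study)
  obs <- !data$censored
  logL <- log(data$L)
  logy <- ifelse(obs, log(pmax(data$y, 1e-300)), NA_real_)

  # Centred parameterisation on per-study means v_s: the tow likelihood
  # depends only on v_s (plus the within-study mesh deviation), and the
  # habitat level alpha/beta_mesh/sigma_study update through the S-row
  # hierarchical layer v_s ~ N(alpha_h + beta_mesh * mesh_bar_s,
  # sigma_study).  This decorrelates the coordinate-wise slice updates.
  mesh_bar <- as.numeric(tapply(data$mesh, sidx, mean))
  mesh_dev <- data$mesh - mesh_bar[sidx]
  study_h <- vapply(seq_len(S), function(s) hidx[match(s, sidx)], integer(1))

  logpost <- function(th) {
    alpha <- th[seq_len(H)]
    beta_mesh <- th[H + 1L]
    v <- th[H + 1L + seq_len(S)]
    sig_s <- exp(th[H + S + 2L])
    sig <- exp(th[H + S + 3L])
    mu <- v[sidx] + beta_mesh * mesh_dev
    ll <- sum(stats::dnorm(logy[obs], mu[obs], sig, log = TRUE)) -
      sum(logy[obs]) +
      sum(stats::pnorm((logL[!obs] - mu[!obs]) / sig, log.p = TRUE)) +
      sum(stats::dnorm(v, alpha[study_h] + beta_mesh * mesh_bar, sig_s,
                       log = TRUE))
    if (!is.finite(ll)) return(-Inf)
    ll +
      sum(stats::dnorm(c(alpha, beta_mesh), 0, priors$coef_sd, log = TRUE)) +
      stats::dnorm(sig_s, 0, priors$sd_sd, log = TRUE) + log(sig_s) +
      stats::dnorm(sig, 0, priors$sd_sd, log = TRUE) + log(sig)
  }

  init_v <- vapply(seq_len(S), function(s) {
    w <- logy[obs & sidx == s]
    if (length(w)) mean(w) else log(min(data$L[sidx == s])) - 1
  }, numeric(1))
  init_alpha <- vapply(seq_len(H), function(h) {
    w <- init_v[study_h == h]
    if (length(w)) mean(w) else 0
  }, numeric(1))
  init <- c(init_alpha, 0, init_v,
            log(max(stats::sd(init_v), 0.5)),
            log(max(stats::sd(logy[obs]), 0.5)))
  nm <- c(paste0("alpha[", hlev, "]"), "beta_mesh",
          paste0("v[", levels(data$study), "]"), "log_sigma_study",
          "log_sigma")
  draws <- run_mcmc(logpost, init, n_chains = mcmc$chains %||% 4,
                    iter = mcmc$iter %||% 1000,
                    warmup = mcmc$warmup %||% 500,
                    seed = mcmc$seed %||% 1, param_names = nm)
  fit <- suppressWarnings(
    new_mp_fit(draws, "cens_lnm", data,
               extra = list(habitats = hlev, n_study = S,
                            mesh_bar = mesh_bar)))
  if (!fit$converged)
    warning("cens_lnm fit flagged: diagnostics below acceptance gates")
  fit
}

#' Fit the Poisson hurdle model
#'
#' Intercept-only Bernoulli detection part plus a zero-truncated Poisson
#' count part with standardised predictors; the detection probability is
#' sampled on the logit scale under a Beta prior.
#'
#' @param data a [hurdle_data()].
#' @param mcmc list with `chains`, `iter`, `warmup`, `seed`.
#' @param priors see [default_priors()].
#' @return an `mp_fit`.
#' @export
fit_hurdle <- function(data,
                       mcmc = list(chains = 4, iter = 1000, warmup = 500,
                                   seed = 1),
                       priors = default_priors()) {
  stopifnot(inherits(data, "hurdle_data"))
  p <- ncol(data$X)
  pos <- data$k > 0
  n0 <- sum(!pos); n1 <- sum(pos)
  kpos <- data$k[pos]
  Xpos <- data$X[pos, , drop = FALSE]

  logpost <- function(th) {
    lpi <- th[1]
    pi <- stats::plogis(lpi)
    beta0 <- th[2]
    beta <- th[2 + seq_len(p)]
    eta <- beta0 + drop(Xpos %*% beta)
    if (any(eta > 30)) return(-Inf)
    lambda <- exp(eta)
    ll <- n0 * log(1 - pi) + n1 * log(pi) +
      sum(kpos * eta - lambda - log1mexp(lambda) - lgamma(kpos + 1))
    if (!is.finite(ll)) return(-Inf)
    ll +
      stats::dbeta(pi, priors$pi_shape1, priors$pi_shape2, log = TRUE) +
      log(pi) + log(1 - pi) +  # Jacobian of the logit transform
      sum(stats::dnorm(c(beta0, beta), 0, priors$coef_sd, log = TRUE))
  }

  init <- c(stats::qlogis(min(max(n1 / (n0 + n1), 0.05), 0.95)),
            log(max(mean(kpos), 0.5)), rep(0, p))
  nm <- c("logit_pi", "beta0",
          if (p > 0) paste0("beta[", colnames(data$X) %||% seq_len(p), "]"))
  draws <- run_mcmc(logpost, init, n_chains = mcmc$chains %||% 4,
                    iter = mcmc$iter %||% 1000,
                    warmup = mcmc$warmup %||% 500,
                    seed = mcmc$seed %||% 1, param_names = nm)
  fit <- suppressWarnings(new_mp_fit(draws, "hurdle", data))
  if (!fit$converged)
    warning("hurdle fit flagged: diagnostics below acceptance gates")
  fit
}

#' Pointwise log-likelihood matrix of a fit
#'
#' One row per posterior draw, one column per observation; input for
#' [loo_psis()].  For the censored model the contributions are conditional
#' on the study intercepts.
#'
#' @param fit an `mp_fit`.
#' @return numeric matrix, draws x observations.
#' @export
loglik_matrix <- function(fit) {
  flat <- fit$flat
  S <- nrow(flat)
  if (fit$model == "hurdle") {
    d <- fit$data
    n <- length(d$k)
    out <- matrix(NA_real_, S, n)
    pos <- d$k > 0
    pi <- stats::plogis(flat[, "logit_pi"])
    bidx <- grep("^beta\\[", colnames(flat))
    eta <- flat[, "beta0"] %*% t(rep(1, n)) +
      flat[, bidx, drop = FALSE] %*% t(d$X)
    lambda <- exp(eta)
    for (i in seq_len(n)) {
      out[, i] <- if (pos[i])
        log(pi) + d$k[i] * eta[, i] - lambda[, i] -
          log1mexp(lambda[, i]) - lgamma(d$k[i] + 1)
      else log(1 - pi)
    }
    out
  } else if (fit$model == "cens_lnm") {
    d <- fit$data
    n <- length(d$y)
    sidx <- as.integer(d$study)
    vidx <- match(paste0("v[", as.character(d$study), "]"), colnames(flat))
    sig <- exp(flat[, "log_sigma"])
    mesh_dev <- d$mesh - fit$mesh_bar[sidx]
    out <- matrix(NA_real_, S, n)
    for (i in seq_len(n)) {
      mu <- flat[, vidx[i]] + flat[, "beta_mesh"] * mesh_dev[i]
      out[, i] <- if (d$censored[i])
        stats::pnorm((log(d$L[i]) - mu) / sig, log.p = TRUE)
      else stats::dlnorm(d$y[i], mu, sig, log = TRUE)
    }
    out
  } else stop("unknown model: ", fit$model)
}

#' Bayesian R-squared
#'
#' Per posterior draw, the variance of the fitted means divided by itself
#' plus the mean model-implied residual variance (Gelman et al. 2019).
#'
#' @param fit an `mp_fit`.
#' @return list with `draws` (one R2 per posterior draw), `mean` and the
#'   95% credible interval `ci`.
#' @export
bayes_r2 <- function(fit) {
  flat <- fit$flat
  if (fit$model == "hurdle") {
    d <- fit$data
    pi <- stats::plogis(flat[, "logit_pi"])
    bidx <- grep("^beta\\[", colnames(flat))
    eta <- flat[, "beta0"] %*% t(rep(1, length(d$k))) +
      flat[, bidx, drop = FALSE] %*% t(d$X)
    lambda <- exp(eta)
    denom <- -expm1(-lambda)
    mu <- pi * lambda / denom
    ey2 <- pi * (lambda + lambda^2) / denom
    vres <- pmax(ey2 - mu^2, 0)
  } else if (fit$model == "cens_lnm") {
    d <- fit$data
    sidx <- as.integer(d$study)
    vidx <- match(paste0("v[", as.character(d$study), "]"), colnames(flat))
    sig <- exp(flat[, "log_sigma"])
    mesh_dev <- d$mesh - fit$mesh_bar[sidx]
    n <- length(d$y)
    mu <- matrix(NA_real_, nrow(flat), n)
    for (i in seq_len(n))
      mu[, i] <- flat[, vidx[i]] + flat[, "beta_mesh"] * mesh_dev[i]
    vres <- matrix(sig^2, nrow(flat), n)
  } else stop("unknown model: ", fit$model)
  vfit <- apply(mu, 1, stats::var)
  r2 <- vfit / (vfit + rowMeans(vres))
  list(draws = r2, mean = mean(r2),
       ci = unname(stats::quantile(r2, c(0.025, 0.975))))
}

#' Pairwise habitat contrasts on the response scale
#'
#' Per draw, the median-scale concentration per habitat at a reference mesh
#' size, `exp(alpha_h + beta_mesh * at_mesh)`, and all pairwise differences
#' summarised by posterior mean and 95% credible interval.
#'
#' @param fit a censored log-normal `mp_fit`.
#' @param at_mesh standardised mesh value at which to compare (default 0,
#'   the mean mesh size).
#' @return data frame with one row per ordered habitat pair.
#' @export
habitat_contrasts <- function(fit, at_mesh = 0) {
  stopifnot(fit$model == "cens_lnm")
  flat <- fit$flat
  hlev <- fit$habitats
  conc <- sapply(hlev, function(h)
    exp(flat[, paste0("alpha[", h, "]")] + flat[, "beta_mesh"] * at_mesh))
  pairs <- utils::combn(hlev, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    dif <- conc[, pairs[1, j]] - conc[, pairs[2, j]]
    data.frame(habitat_a = pairs[1, j], habitat_b = pairs[2, j],
               mean = mean(dif),
               q2.5 = unname(stats::quantile(dif, 0.025)),
               q97.5 = unname(stats::quantile(dif, 0.975)))
  }))
  out
}

#' Marginal effect curve of one predictor
#'
#' Expected concentration `pi * lambda / (1 - exp(-lambda)) / V` along a
#' grid of the focal standardised predictor with all others held at 0
#' (their mean).  The detection probability is marginalised (multiplied in)
#' by default; set `condition_on_detection = TRUE` to condition on a
#' detection instead.  Also returns the ratio of the curve endpoints, the
#' "concentrations increased x-fold over the observed range" statistic.
#'
#' @param fit a hurdle `mp_fit`.
#' @param predictor column name or index in the design matrix.
#' @param grid standardised values of the focal predictor (default: 25
#'   points across the observed range).
#' @param condition_on_detection if `TRUE`, drop the `pi` factor.
#' @return list with `curve` (data frame: grid value, mean, 95% CI) and
#'   `endpoint_ratio` (mean and 95% CI of last/first curve value per draw).
#' @export
marginal_effect <- function(fit, predictor, grid = NULL,
                            condition_on_detection = FALSE) {
  stopifnot(fit$model == "hurdle")
  d <- fit$data
  cn <- colnames(d$X)
  j <- if (is.character(predictor)) match(predictor, cn) else predictor
  if (is.na(j) || j < 1 || j > ncol(d$X)) stop("unknown predictor: ",
                                               predictor)
  obs_range <- range(d$X[, j])
  if (is.null(grid)) grid <- seq(obs_range[1], obs_range[2], length.out = 25)
  if (any(grid < obs_range[1] - 1e-9) || any(grid > obs_range[2] + 1e-9))
    warning("grid extends outside the observed range of the predictor")
  flat <- fit$flat
  pi <- if (condition_on_detection) 1 else stats::plogis(flat[, "logit_pi"])
  bcol <- grep("^beta\\[", colnames(flat))[j]
  lambda <- exp(outer(flat[, "beta0"], rep(1, length(grid))) +
                  outer(flat[, bcol], grid))
  conc <- pi * lambda / (-expm1(-lambda)) / d$volume_m3
  curve <- data.frame(
    x = grid,
    mean = colMeans(conc),
    q2.5 = apply(conc, 2, stats::quantile, 0.025),
    q97.5 = apply(conc, 2, stats::quantile, 0.975))
  ratio <- conc[, length(grid)] / conc[, 1]
  list(curve = curve,
       endpoint_ratio = list(mean = mean(ratio),
                             ci = unname(stats::quantile(ratio,
                                                         c(0.025, 0.975)))))
}

#' Extract posterior draws of the natural-scale hurdle parameters
#'
#' @param fit a hurdle `mp_fit`.
#' @return matrix with columns `pi`, `beta0` and one per predictor.
#' @export
hurdle_draws <- function(fit) {
  stopifnot(fit$model == "hurdle")
  flat <- fit$flat
  out <- cbind(pi = stats::plogis(flat[, "logit_pi"]),
               flat[, -1, drop = FALSE])
  out
}
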