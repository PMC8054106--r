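#' Hyperparameters of the spatio-temporal model
#'
#' Bundles the five hyperparameters of the logit-scale model
#' `logit(Q_ikt) = alpha + S_kt + Z_ikt`, where `S` is a mean-zero Gaussian
#' field with covariance `sigma2 * (R_S %x% R_T)` and `Z_ikt` is independent
#' noise with variance `tau2 / log(n_eff_ikt)`.
#'
#' @param alpha Intercept on the logit scale.
#' @param sigma2 Field variance (logit^2 units), > 0.
#' @param rho_s Spatial CAR dependence, in (0, 1).
#' @param phi Temporal AR(1) coefficient, |phi| < 1.
#' @param tau2 Noise scale (logit^2 units), > 0.
#' @return A `model_params` list.
#' @examples
#' model_params(alpha = -0.5, sigma2 = 1, rho_s = 0.9, phi = 0.8, tau2 = 1.5)
#' @export
model_params <- function(alpha = 0, sigma2 = 1, rho_s = 0.5, phi = 0.5,
                         tau2 = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha))
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  if (tau2 <= 0) abort("`tau2` must be positive.")
  if (rho_s <= 0 || rho_s >= 1) abort("`rho_s` must lie in (0, 1).")
  if (abs(phi) >= 1) abort("`phi` must satisfy |phi| < 1.")
  structure(
    list(alpha = alpha, sigma2 = sigma2, rho_s = rho_s, phi = phi,
         tau2 = tau2),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> alpha=%.3g sigma2=%.3g rho_s=%.3g phi=%.3g tau2=%.3g\n",
    x$alpha, x$sigma2, x$rho_s, x$phi, x$tau2))
  invisible(x)
}

#' Sample-size-driven observation noise variance
#'
#' The observation-level noise variance is `tau2 / log(n_eff)`: precision
#' grows with the log effective sample size, so sparse survey cells are
#' down-weighted and large censuses anchor the fit.
#'
#' @param n_eff Effective sample size(s), each > 1 so the log is positive.
#' @param tau2 Noise scale, > 0.
#' @return Noise variance(s), same length as `n_eff`.
#' @examples
#' noise_variance(exp(1), 1) # 1
#' @export
noise_variance <- function(n_eff, tau2) {
  if (any(n_eff <= 1)) {
    abort("`n_eff` must exceed 1 (log must be positive).")
  }
  if (tau2 <= 0) abort("`tau2` must be positive.")
  tau2 / log(n_eff)
}

#' Observation log-likelihood
#'
#' Sum over observations of the Gaussian log-density of the empirical logit
#' `y_logit` with mean `alpha + S_kt` and variance
#' `tau2 / log(n_eff)`. Observations sharing a (region, year) cell share the
#' latent value `S_kt`.
#'
#' @param params A [model_params()].
#' @param field K x T matrix of latent logit-scale values (region-major
#'   rows).
#' @param data A `factor_dataset` from [assemble_dataset()].
#' @return A single number (0 for an empty dataset).
#' @export
stgpr_log_likelihood <- function(params, field, data) {
  stopifnot(inherits(params, "model_params"), inherits(data, "factor_dataset"))
  field <- as.matrix(field)
  if (nrow(field) != data$n_regions || ncol(field) != data$n_years) {
    abort(sprintf("`field` must be %d x %d.", data$n_regions, data$n_years))
  }
  obs <- data$observations
  if (nrow(obs) == 0) return(0)
  mu <- params$alpha + field[cbind(obs$k, obs$t)]
  v <- noise_variance(obs$n_eff, params$tau2)
  sum(dnorm(obs$y_logit, mean = mu, sd = sqrt(v), log = TRUE))
}

# log-density of the mean-zero Gaussian field under sigma2 * (R_S %x% R_T),
# computed from the two small factors (never forming the KT x KT matrix):
# logdet = KT log sigma2 + T logdet R_S + K logdet R_T, and the quadratic
# form uses the T x K layout X = t(S) so that vec(X) follows the global
# region-major ordering.
field_log_density <- function(field, sigma2, R_s, R_t,
                              Rs_inv = solve(R_s), Rt_inv = solve(R_t),
                              logdet_Rs = determinant(R_s)$modulus,
                              logdet_Rt = determinant(R_t)$modulus) {
  K <- nrow(R_s)
  T <- nrow(R_t)
  X <- t(as.matrix(field)) # T x K
  qf <- sum(X * (Rt_inv %*% X %*% Rs_inv)) / sigma2
  logdet <- K * T * log(sigma2) + T * as.numeric(logdet_Rs) +
    K * as.numeric(logdet_Rt)
  -0.5 * (K * T * log(2 * pi) + logdet + qf)
}

#' Prior specification
#'
#' Weakly informative defaults on the logit scale: `alpha ~ N(0, 10^2)`;
#' half-Normal(0, 5^2) priors on the field and noise standard deviations
#' `sqrt(sigma2)` and `sqrt(tau2)`; `rho_s ~ Uniform(0, 1)`;
#' `phi ~ Uniform(-1, 1)`.
#'
#' @param alpha_sd Prior SD of the intercept.
#' @param sigma_scale Half-normal scale for the field SD.
#' @param tau_scale Half-normal scale for the noise SD.
#' @return A `stgpr_priors` list.
#' @export
stgpr_priors <- function(alpha_sd = 10, sigma_scale = 5, tau_scale = 5) {
  stopifnot(alpha_sd > 0, sigma_scale > 0, tau_scale > 0)
  structure(list(alpha_sd = alpha_sd, sigma_scale = sigma_scale,
                 tau_scale = tau_scale),
            class = "stgpr_priors")
}

# log prior density of a variance parameter whose SD has a half-normal prior;
# density expressed over the variance v (includes the d(sd)/d(v) factor)
log_halfnormal_var <- function(v, scale) {
  s <- sqrt(v)
  log(2) + dnorm(s, 0, scale, log = TRUE) - log(2 * s)
}

hyper_log_prior <- function(params, priors) {
  dnorm(params$alpha, 0, priors$alpha_sd, log = TRUE) +
    log_halfnormal_var(params$sigma2, priors$sigma_scale) +
    log_halfnormal_var(params$tau2, priors$tau_scale) +
    0 +          # rho_s ~ U(0,1)
    -log(2)      # phi ~ U(-1,1)
}

#' Joint log-prior of hyperparameters and latent field
#'
#' The field term is the mean-zero multivariate normal with covariance
#' `sigma2 * (R_S %x% R_T)`, evaluated through the two factor matrices (the
#' dense KT x KT covariance is never formed). Hyperparameter terms follow
#' [stgpr_priors()].
#'
#' @param params A [model_params()].
#' @param field K x T latent matrix.
#' @param graph A [region_graph()].
#' @param years Analysis years (only the length is used).
#' @param priors A [stgpr_priors()].
#' @return A single number.
#' @export
stgpr_log_prior <- function(params, field, graph, years,
                            priors = stgpr_priors()) {
  stopifnot(inherits(params, "model_params"), inherits(graph, "region_graph"))
  T <- length(years)
  field <- as.matrix(field)
  if (nrow(field) != graph$n_regions || ncol(field) != T) {
    abort(sprintf("`field` must be %d x %d.", graph$n_regions, T))
  }
  R_s <- car_correlation(graph, params$rho_s)
  R_t <- ar1_correlation(T, params$phi)
  field_log_density(field, params$sigma2, R_s, R_t) +
    hyper_log_prior(params, priors)
}
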