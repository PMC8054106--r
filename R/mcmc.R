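#' MCMC sampler configuration
#'
#' Defaults follow the production run: 110 000 iterations, 10 000 burn-in,
#' keep every 10th draw, so exactly 10 000 posterior samples are retained.
#' Scaled-down runs set smaller totals; `(n_iter - burn_in) / thin` must be
#' a positive integer.
#'
#' @param n_iter Total iterations.
#' @param burn_in Discarded initial iterations.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer RNG seed; fixing it makes the fit fully reproducible.
#' @param proposal_scales Named numeric: initial random-walk SDs on the
#'   transformed scales (`log sigma2`, `logit rho_s`, `atanh phi`,
#'   `log tau2`).
#' @param update Named logical: which hyperparameters to sample. Fixing a
#'   parameter (e.g. for conjugate checks) keeps it at its initial value.
#' @param adapt Adapt proposal scales during burn-in only (Robbins-Monro
#'   toward 0.44 acceptance), frozen afterwards so the post-burn-in chain is
#'   a valid Metropolis sampler.
#' @return A `stgpr_control` list with the retained draw count `n_draws`.
#' @examples
#' stgpr_control()$n_draws # 10000
#' @export
stgpr_control <- function(n_iter = 110000, burn_in = 10000, thin = 10,
                          seed = 1L,
                          proposal_scales = c(sigma2 = 0.4, rho_s = 0.8,
                                              phi = 0.4, tau2 = 0.4),
                          update = c(alpha = TRUE, sigma2 = TRUE,
                                     rho_s = TRUE, phi = TRUE, tau2 = TRUE),
                          adapt = TRUE) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  kept <- (n_iter - burn_in) / thin
  if (kept != round(kept) || kept < 1) {
    abort("(n_iter - burn_in) / thin must be a positive integer.")
  }
  upd <- c(alpha = TRUE, sigma2 = TRUE, rho_s = TRUE, phi = TRUE,
           tau2 = TRUE)
  upd[names(update)] <- update
  ps <- c(sigma2 = 0.4, rho_s = 0.8, phi = 0.4, tau2 = 0.4)
  ps[names(proposal_scales)] <- proposal_scales
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         thin = as.integer(thin), n_draws = as.integer(kept),
         seed = as.integer(seed), proposal_scales = ps, update = upd,
         adapt = isTRUE(adapt)),
    class = "stgpr_control"
  )
}

# spatial correlation pieces for a given rho, in the form the sampler needs
car_pieces <- function(graph, rho_s) {
  R <- car_correlation(graph, rho_s)
  list(R = R, inv = solve(R),
       logdet = as.numeric(determinant(R)$modulus))
}

ar1_pieces <- function(T, phi) {
  R <- ar1_correlation(T, phi)
  list(R = R, inv = solve(R),
       logdet = as.numeric(determinant(R)$modulus))
}

# field log-density up to the 2*pi constant, from a precomputed quadratic
# form at sigma2 = 1
field_lp_from_qf <- function(qf1, sigma2, KT, T_ld_Rs, K_ld_Rt) {
  -0.5 * (KT * log(sigma2) + T_ld_Rs + K_ld_Rt + qf1 / sigma2)
}

#' Fit the spatio-temporal Gaussian process model by MCMC
#'
#' Metropolis-within-Gibbs: the latent field `S` is refreshed in one joint
#' Gaussian draw from its full conditional (Gaussian prior plus Gaussian
#' heteroscedastic likelihood — the conditional precision is the Kronecker
#' prior precision plus a diagonal data precision); the intercept has a
#' conjugate Gibbs step; `sigma2`, `rho_s`, `phi` and `tau2` move by
#' random-walk Metropolis on unconstrained transforms (log, logit, atanh,
#' log) with the appropriate Jacobians. Proposal scales adapt during burn-in
#' only.
#'
#' @param data A `factor_dataset` from [assemble_dataset()].
#' @param control A [stgpr_control()].
#' @param priors A [stgpr_priors()].
#' @param init Optional [model_params()] giving starting values (and fixed
#'   values for any parameter excluded from `control$update`). Defaults to a
#'   crude data-based start.
#' @return An object of class `stgpr_fit` holding the retained draws of the
#'   hyperparameters and the latent field, acceptance rates, and the inputs.
#' @seealso [posterior_surface()], [tidy.stgpr_fit()], [glance.stgpr_fit()]
#' @export
stgpr <- function(data, control = stgpr_control(), priors = stgpr_priors(),
                  init = NULL) {
  stopifnot(inherits(data, "factor_dataset"),
            inherits(control, "stgpr_control"))
  graph <- data$graph
  K <- data$n_regions
  T <- data$n_years
  KT <- K * T
  obs <- data$observations
  N <- nrow(obs)

  set.seed(control$seed)

  # per-observation constants
  if (N > 0) {
    if (any(obs$n_eff <= 1)) {
      abort("All observations need n_eff > 1 for the noise model.")
    }
    cell <- (obs$k - 1L) * T + obs$t
    l <- log(obs$n_eff)
    y <- obs$y_logit
    Lcell <- numeric(KT)
    Lycell <- numeric(KT)
    for (i in seq_len(N)) {
      Lcell[cell[i]] <- Lcell[cell[i]] + l[i]
      Lycell[cell[i]] <- Lycell[cell[i]] + l[i] * y[i]
    }
    sum_l <- sum(l)
  } else {
    cell <- integer(0); l <- numeric(0); y <- numeric(0)
    Lcell <- numeric(KT); Lycell <- numeric(KT); sum_l <- 0
  }

  # initial state
  if (is.null(init)) {
    a0 <- if (N > 0) mean(y) else 0
    init <- model_params(alpha = a0, sigma2 = 1, rho_s = 0.5, phi = 0.5,
                         tau2 = 1)
  }
  alpha <- init$alpha; sigma2 <- init$sigma2; rho_s <- init$rho_s
  phi <- init$phi; tau2 <- init$tau2

  sp <- car_pieces(graph, rho_s)
  tp <- ar1_pieces(T, phi)

  upd <- control$update
  ls <- log(control$proposal_scales) # adapted log proposal SDs
  acc <- c(sigma2 = 0, rho_s = 0, phi = 0, tau2 = 0)  # post burn-in
  n_post <- control$n_iter - control$burn_in

  n_draws <- control$n_draws
  d_alpha <- numeric(n_draws); d_sigma2 <- numeric(n_draws)
  d_rho <- numeric(n_draws); d_phi <- numeric(n_draws)
  d_tau2 <- numeric(n_draws)
  d_field <- matrix(NA_real_, n_draws, KT)

  a_prec0 <- 1 / priors$alpha_sd^2
  S_vec <- numeric(KT)

  for (it in seq_len(control$n_iter)) {
    in_burn <- it <= control$burn_in

    ## (1) latent field: joint Gaussian conditional draw
    P <- kronecker(sp$inv, tp$inv) / sigma2
    diag(P) <- diag(P) + Lcell / tau2
    b <- (Lycell - alpha * Lcell) / tau2
    U <- tryCatch(chol(P), error = function(e) {
      abort(paste0("Latent-field conditional solve failed at iteration ",
                   it, ": ", conditionMessage(e)))
    })
    m <- backsolve(U, backsolve(U, b, transpose = TRUE))
    S_vec <- m + backsolve(U, rnorm(KT))
    X <- matrix(S_vec, nrow = T)           # T x K, col k is region k
    qf1 <- sum(X * (tp$inv %*% X %*% sp$inv))  # prior quad form at sigma2=1
    S_at_obs <- if (N > 0) S_vec[cell] else numeric(0)

    ## (2) intercept: conjugate Gibbs
    if (upd[["alpha"]]) {
      prec <- sum_l / tau2 + a_prec0
      mn <- if (N > 0) sum(l * (y - S_at_obs)) / tau2 / prec else 0
      alpha <- rnorm(1, mn, sqrt(1 / prec))
    }

    ## (3) field variance: RW Metropolis on log sigma2
    if (upd[["sigma2"]]) {
      prop <- sigma2 * exp(rnorm(1, 0, exp(ls[["sigma2"]])))
      logr <- field_lp_from_qf(qf1, prop, KT, T * sp$logdet, K * tp$logdet) -
        field_lp_from_qf(qf1, sigma2, KT, T * sp$logdet, K * tp$logdet) +
        log_halfnormal_var(prop, priors$sigma_scale) -
        log_halfnormal_var(sigma2, priors$sigma_scale) +
        log(prop) - log(sigma2)
      a_p <- min(1, exp(logr))
      if (runif(1) < a_p) {
        sigma2 <- prop
        if (!in_burn) acc[["sigma2"]] <- acc[["sigma2"]] + 1
      }
      if (in_burn && control$adapt) {
        ls[["sigma2"]] <- ls[["sigma2"]] + min(0.05, it^-0.5) * (a_p - 0.44)
      }
    }

    ## (4) spatial dependence: RW Metropolis on logit rho_s
    if (upd[["rho_s"]] && K > 1) {
      u <- qlogis(rho_s) + rnorm(1, 0, exp(ls[["rho_s"]]))
      prop <- plogis(u)
      sp_prop <- car_pieces(graph, prop)
      qf1_prop <- sum(X * (tp$inv %*% X %*% sp_prop$inv))
      logr <-
        field_lp_from_qf(qf1_prop, sigma2, KT, T * sp_prop$logdet,
                         K * tp$logdet) -
        field_lp_from_qf(qf1, sigma2, KT, T * sp$logdet, K * tp$logdet) +
        log(prop * (1 - prop)) - log(rho_s * (1 - rho_s))
      a_p <- min(1, exp(logr))
      if (runif(1) < a_p) {
        rho_s <- prop; sp <- sp_prop; qf1 <- qf1_prop
        if (!in_burn) acc[["rho_s"]] <- acc[["rho_s"]] + 1
      }
      if (in_burn && control$adapt) {
        ls[["rho_s"]] <- ls[["rho_s"]] + min(0.05, it^-0.5) * (a_p - 0.44)
      }
    }

    ## (5) temporal dependence: RW Metropolis on atanh phi
    if (upd[["phi"]] && T > 1) {
      u <- atanh(phi) + rnorm(1, 0, exp(ls[["phi"]]))
      prop <- tanh(u)
      tp_prop <- ar1_pieces(T, prop)
      qf1_prop <- sum(X * (tp_prop$inv %*% X %*% sp$inv))
      logr <-
        field_lp_from_qf(qf1_prop, sigma2, KT, T * sp$logdet,
                         K * tp_prop$logdet) -
        field_lp_from_qf(qf1, sigma2, KT, T * sp$logdet, K * tp$logdet) +
        log(1 - prop^2) - log(1 - phi^2)
      a_p <- min(1, exp(logr))
      if (runif(1) < a_p) {
        phi <- prop; tp <- tp_prop; qf1 <- qf1_prop
        if (!in_burn) acc[["phi"]] <- acc[["phi"]] + 1
      }
      if (in_burn && control$adapt) {
        ls[["phi"]] <- ls[["phi"]] + min(0.05, it^-0.5) * (a_p - 0.44)
      }
    }

    ## (6) noise scale: RW Metropolis on log tau2
    if (upd[["tau2"]]) {
      sse_w <- if (N > 0) sum(l * (y - alpha - S_at_obs)^2) else 0
      prop <- tau2 * exp(rnorm(1, 0, exp(ls[["tau2"]])))
      loglik <- function(t2) -0.5 * (N * log(t2) + sse_w / t2)
      logr <- loglik(prop) - loglik(tau2) +
        log_halfnormal_var(prop, priors$tau_scale) -
        log_halfnormal_var(tau2, priors$tau_scale) +
        log(prop) - log(tau2)
      a_p <- min(1, exp(logr))
      if (runif(1) < a_p) {
        tau2 <- prop
        if (!in_burn) acc[["tau2"]] <- acc[["tau2"]] + 1
      }
      if (in_burn && control$adapt) {
        ls[["tau2"]] <- ls[["tau2"]] + min(0.05, it^-0.5) * (a_p - 0.44)
      }
    }

    ## retain
    if (!in_burn) {
      j <- it - control$burn_in
      if (j %% control$thin == 0) {
        d <- j %/% control$thin
        d_alpha[d] <- alpha; d_sigma2[d] <- sigma2; d_rho[d] <- rho_s
        d_phi[d] <- phi; d_tau2[d] <- tau2
        d_field[d, ] <- S_vec
      }
    }
  }

  rates <- acc / n_post
  active <- names(rates)[upd[c("sigma2", "rho_s", "phi", "tau2")] &
                           c(TRUE, K > 1, T > 1, TRUE)]
  off <- active[rates[active] < 0.05 | rates[active] > 0.8]
  if (length(off) > 0) {
    warn(paste0("Post-burn-in Metropolis acceptance outside [0.05, 0.8] for: ",
                paste(sprintf("%s (%.2f)", off, rates[off]), collapse = ", ")))
  }

  structure(
    list(
      draws = list(alpha = d_alpha, sigma2 = d_sigma2, rho_s = d_rho,
                   phi = d_phi, tau2 = d_tau2, field = d_field),
      data = data, graph = graph, years = data$years,
      control = control, priors = priors,
      acceptance = rates, n_draws = n_draws
    ),
    class = "stgpr_fit"
  )
}

#' @export
print.stgpr_fit <- function(x, ...) {
  cat("<stgpr_fit> ", x$n_draws, " retained draws; ",
      x$data$n_obs, " observations over ", x$data$n_regions, " regions x ",
      x$data$n_years, " years\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy hyperparameter posterior summaries
#'
#' @param x A `stgpr_fit`.
#' @param ... Unused.
#' @return A tibble with one row per hyperparameter: posterior mean,
#'   SD and central 95% interval.
#' @exportS3Method generics::tidy
tidy.stgpr_fit <- function(x, ...) {
  pars <- c("alpha", "sigma2", "rho_s", "phi", "tau2")
  purrr::map_dfr(pars, function(p) {
    d <- x$draws[[p]]
    tibble::tibble(
      term = p, estimate = mean(d), std.error = sd(d),
      conf.low = unname(quantile(d, 0.025)),
      conf.high = unname(quantile(d, 0.975))
    )
  })
}

#' One-row fit summary
#'
#' @param x A `stgpr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: data dimensions, draw count and the mean
#'   post-burn-in Metropolis acceptance rate.
#' @exportS3Method generics::glance
glance.stgpr_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$data$n_obs, n_regions = x$data$n_regions,
    n_years = x$data$n_years, n_cells_observed = x$data$n_cells_observed,
    n_draws = x$n_draws,
    mean_acceptance = mean(x$acceptance[x$control$update[names(x$acceptance)]])
  )
}
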