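small_fit_dataset <- function() {
  g <- two_region_graph()
  obs <- dplyr::bind_rows(
    make_obs("A", 2010L, 0.4, 200),
    make_obs("A", 2011L, 0.45, 150),
    make_obs("B", 2010L, 0.2, 100),
    make_obs("B", 2012L, 0.3, 120)
  )
  assemble_dataset(obs, g, 2010:2012)
}

test_that("control enforces the retained-draw bookkeeping", {
  expect_equal(stgpr_control()$n_draws, 10000L)
  expect_equal(stgpr_control(n_iter = 2100, burn_in = 100, thin = 4)$n_draws,
               500L)
  expect_error(stgpr_control(n_iter = 105, burn_in = 10, thin = 10),
               "positive integer")
  expect_error(stgpr_control(n_iter = 100, burn_in = 100), "n_iter")
})

test_that("the sampler is reproducible given a seed and retains the
           configured number of draws", {
  ds <- small_fit_dataset()
  ctrl <- stgpr_control(n_iter = 400, burn_in = 100, thin = 3, seed = 7)
  f1 <- suppressWarnings(stgpr(ds, ctrl))
  f2 <- suppressWarnings(stgpr(ds, ctrl))
  expect_equal(f1$n_draws, 100L)
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(stgpr(ds, stgpr_control(n_iter = 400, burn_in = 100,
                                                 thin = 3, seed = 8)))
  expect_false(identical(f1$draws$alpha, f3$draws$alpha))
})

test_that("single-cell conjugate model: MCMC matches the closed-form normal
           posterior of alpha + S within Monte-Carlo error", {
  # one region, one year, one observation; hyperparameters held fixed, so
  # (alpha, S) is jointly Gaussian and mu = alpha + S has a conjugate
  # normal posterior
  g <- region_graph(data.frame(from = character(), to = character()),
                    region_ids = "A")
  truth <- model_params(alpha = 0, sigma2 = 0.7, rho_s = 0.5, phi = 0.5,
                        tau2 = 1.2)
  n_eff <- 150
  y <- 0.9
  obs <- make_obs("A", 2010L, plogis(y), n_eff)
  obs$y_logit <- y
  ds <- assemble_dataset(obs, g, 2010L)

  v_noise <- truth$tau2 / log(n_eff)
  v_prior <- 10^2 + truth$sigma2 # var(alpha) + var(S)
  post_var <- v_prior * v_noise / (v_prior + v_noise)
  post_mean <- y * v_prior / (v_prior + v_noise)

  ctrl <- stgpr_control(
    n_iter = 11000, burn_in = 1000, thin = 1, seed = 11,
    update = c(sigma2 = FALSE, rho_s = FALSE, phi = FALSE, tau2 = FALSE)
  )
  fit <- stgpr(ds, ctrl, init = truth)
  mu <- fit$draws$alpha + fit$draws$field[, 1]

  expect_lt(abs(mean(mu) - post_mean), 3 * mcse_batch(mu))
  expect_lt(abs(sd(mu) - sqrt(post_var)) / sqrt(post_var), 0.1)
})

test_that("posterior intervals widen when an isolated observation's
           effective sample size drops", {
  g <- two_region_graph()
  years <- 2010:2011
  fit_width <- function(n_eff) {
    obs <- dplyr::bind_rows(
      make_obs("A", 2010L, 0.4, n_eff),
      make_obs("B", 2011L, 0.3, 300)
    )
    ds <- assemble_dataset(obs, g, years)
    f <- suppressWarnings(
      stgpr(ds, stgpr_control(n_iter = 2500, burn_in = 500, thin = 2,
                              seed = 5))
    )
    s <- posterior_surface(f)
    i <- which(s$region_id == "A" & s$year == 2010)
    s$hi95[i] - s$lo95[i]
  }
  expect_lt(fit_width(500), fit_width(5))
})

test_that("prediction covers unobserved cells with finite intervals inside
           (0,1), and a degenerate draw store maps through the inverse
           logit", {
  ds <- small_fit_dataset() # cell (B, 2011) and (A, 2012) unobserved
  fit <- suppressWarnings(
    stgpr(ds, stgpr_control(n_iter = 1200, burn_in = 200, thin = 2,
                            seed = 3)))
  s <- posterior_surface(fit)
  expect_equal(nrow(s), 6)
  expect_true(all(s$lo95 > 0 & s$hi95 < 1))
  expect_true(all(s$lo95 <= s$mean & s$mean <= s$hi95))

  # flat draws (alpha = 0, S = 0) give a 0.5 surface everywhere
  flat <- fit
  flat$draws$alpha[] <- 0
  flat$draws$field[] <- 0
  s0 <- posterior_surface(flat)
  expect_true(all(s0$mean == 0.5))
  expect_true(all(s0$lo95 == 0.5 & s0$hi95 == 0.5))
})

test_that("with a large effective sample size the posterior mean approaches
           the pooled weighted estimate (shrinkage vanishes)", {
  g <- region_graph(data.frame(from = character(), to = character()),
                    region_ids = "A")
  q_obs <- 0.62
  obs <- make_obs("A", 2010L, q_obs, 5e5)
  ds <- assemble_dataset(obs, g, 2010L)
  # hyperparameters fixed: this is the conjugate limit where the noise
  # variance tau2/log(n_eff) -> 0 and the posterior collapses on the data
  ctrl <- stgpr_control(n_iter = 6000, burn_in = 1000, thin = 5, seed = 9,
                        update = c(sigma2 = FALSE, rho_s = FALSE,
                                   phi = FALSE, tau2 = FALSE))
  fit <- suppressWarnings(stgpr(ds, ctrl, init = model_params(tau2 = 1)))
  s <- posterior_surface(fit)
  expect_lt(abs(s$mean - q_obs), 0.01)
})

test_that("tidy and glance summarise the fit", {
  ds <- small_fit_dataset()
  fit <- suppressWarnings(
    stgpr(ds, stgpr_control(n_iter = 600, burn_in = 100, thin = 5, seed = 2)))
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "sigma2", "rho_s", "phi", "tau2"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 4L)
  expect_equal(gl$n_draws, 100L)
})
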