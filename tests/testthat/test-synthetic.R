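test_that("simulated graphs are connected, reproducible and planar-like", {
  g2 <- simulate_graph(2, seed = 1)
  expect_equal(g2$n_regions, 2)
  expect_equal(nrow(g2$edges), 1) # K = 2 must be a single edge

  g <- simulate_graph(47, seed = 9)
  g_again <- simulate_graph(47, seed = 9)
  expect_identical(g$W, g_again$W)
  expect_equal(g$n_regions, 47)

  for (seed in 1:5) {
    gk <- simulate_graph(sample(3:20, 1), seed = seed)
    ig <- igraph::graph_from_adjacency_matrix(gk$W, mode = "undirected")
    expect_true(igraph::is_connected(ig))
  }
})

test_that("simulated truth has the requested covariance structure", {
  g <- simulate_graph(4, seed = 2)
  years <- 2001:2003
  p <- model_params(alpha = -0.3, sigma2 = 1.2, rho_s = 0.8, phi = 0.6,
                    tau2 = 1)

  # near-degenerate field variance: surface flattens onto plogis(alpha)
  p0 <- model_params(alpha = -0.3, sigma2 = 1e-10, rho_s = 0.8, phi = 0.6)
  tr0 <- simulate_truth(g, years, p0, seed = 1)
  expect_lt(max(abs(tr0$surface - plogis(-0.3))), 1e-4)

  # moment matching against sigma2 * (R_S kron R_T) over replicates
  Sig <- kron_covariance(car_correlation(g, p$rho_s),
                         ar1_correlation(3, p$phi), p$sigma2)
  reps <- 400
  xs <- matrix(NA_real_, reps, 12)
  for (r in seq_len(reps)) {
    xs[r, ] <- as.vector(t(simulate_truth(g, years, p, seed = r)$field))
  }
  emp <- crossprod(xs) / reps
  # Monte-Carlo error of a covariance entry is O(sigma2/sqrt(reps))
  expect_lt(max(abs(emp - Sig)), 4 * p$sigma2 / sqrt(reps) * 3)

  # strong AR(1): lag-1 autocorrelation exceeds lag-3 on average
  p95 <- model_params(alpha = 0, sigma2 = 1, rho_s = 0.5, phi = 0.95)
  yrs <- 2001:2008
  lag_cor <- function(field, lag) {
    T <- ncol(field)
    cor(as.vector(field[, 1:(T - lag)]), as.vector(field[, (1 + lag):T]))
  }
  l1 <- mean(vapply(1:30, function(s) {
    lag_cor(simulate_truth(g, yrs, p95, seed = s)$field, 1)
  }, numeric(1)))
  l3 <- mean(vapply(1:30, function(s) {
    lag_cor(simulate_truth(g, yrs, p95, seed = s)$field, 3)
  }, numeric(1)))
  expect_gt(l1, l3)
})

test_that("microdata generator respects the plan and the surface", {
  g <- simulate_graph(3, seed = 3)
  years <- 2010:2012
  p <- model_params(alpha = 0, sigma2 = 1e-10, rho_s = 0.5, phi = 0.5)
  truth <- simulate_truth(g, years, p, seed = 1) # flat 0.5 surface

  sched <- tibble::tibble(
    survey_id = "s1", survey_family = "DHS-like", survey_year = 2012L,
    regions = list(g$region_ids[1:2]), n_per_region = list(2000L)
  )

  # zero weight dispersion: equal weights, so Kish n_eff equals raw n
  plan0 <- simulation_plan(sched, weight_dispersion = 0, seed = 5)
  md <- simulate_microdata(plan0, truth, g)
  est <- estimate_prevalence(md)
  expect_equal(est$n_eff, est$n)

  # at a flat 0.5 surface with n = 2000 the estimate concentrates near 0.5
  pooled <- sum(md$outcome) / nrow(md)
  expect_lt(abs(pooled - 0.5), 0.05)

  # empty schedule gives an empty record list
  plan_empty <- simulation_plan(sched[0, ], seed = 1)
  expect_equal(nrow(simulate_microdata(plan_empty, truth, g)), 0)

  # unknown regions are rejected
  sched_bad <- sched
  sched_bad$regions <- list(c("R01", "nope"))
  expect_error(
    simulate_microdata(simulation_plan(sched_bad, seed = 1), truth, g),
    "unknown regions")
})

test_that("direct observation simulator follows the heteroscedastic noise
           model", {
  g <- simulate_graph(5, seed = 4)
  years <- 2001:2004
  p <- model_params(alpha = -0.5, sigma2 = 0.8, rho_s = 0.7, phi = 0.6,
                    tau2 = 1.5)
  truth <- simulate_truth(g, years, p, seed = 2)
  obs <- simulate_observations(truth, g, n_eff_range = c(50, 500),
                               prop_observed = 0.8, seed = 3)
  expect_equal(nrow(obs), round(0.8 * 20))
  expect_true(all(obs$q > 0 & obs$q < 1))
  # the logit residuals standardised by the model SD are ~N(0,1)
  mu <- p$alpha + truth$field[cbind(match(obs$region_id, g$region_ids),
                                    match(obs$year, years))]
  z <- (obs$y_logit - mu) / sqrt(noise_variance(obs$n_eff, p$tau2))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) * 3)
  expect_lt(abs(sd(z) - 1), 0.5)
})

test_that("the reference scenario is reproducible and leaves enough cells
           unobserved to exercise prediction", {
  sc <- reference_scenario(seed = 1)
  sc2 <- reference_scenario(seed = 1)
  expect_identical(sc$microdata, sc2$microdata)
  expect_equal(sc$graph$n_regions, 12)
  expect_equal(length(sc$years), 10)
  expect_equal(nrow(sc$plan$schedule), 7)

  sy <- tibble::tibble(survey_id = sc$plan$schedule$survey_id,
                       survey_year = sc$plan$schedule$survey_year)
  obs <- estimate_prevalence(filter_recall_window(sc$microdata, sy))
  ds <- assemble_dataset(obs, sc$graph, sc$years)
  expect_gte(1 - ds$n_cells_observed / ds$n_cells, 0.10)
  expect_true(all(obs$n_eff > 1))

  # some (region, year) cells hold more than one survey
  multi <- obs |>
    dplyr::count(.data$region_id, .data$year) |>
    dplyr::filter(.data$n > 1)
  expect_gt(nrow(multi), 0)
})

test_that("study-scale plan matches the archive structure it emulates", {
  g <- simulate_graph(47, seed = 10)
  plan <- study_scale_plan(g, years = 1993:2014, seed = 10)
  sched <- plan$schedule
  expect_equal(nrow(sched), 20)
  expect_equal(sum(sched$survey_family == "census-like"), 2)
  expect_true(all(unlist(sched$n_per_region) >= 20 &
                    unlist(sched$n_per_region) <= 2000))
  expect_true(all(sched$survey_year >= 1993 & sched$survey_year <= 2014))
  # census-like waves enumerate every region
  cens <- sched[sched$survey_family == "census-like", ]
  expect_true(all(vapply(cens$regions, length, integer(1)) == 47))
})
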