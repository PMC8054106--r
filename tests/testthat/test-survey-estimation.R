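micro <- function(family, survey_id, event_year, outcome = 0, weight = 1,
                  region_id = "A") {
  tibble::tibble(survey_id = survey_id, survey_family = family,
                 region_id = region_id, event_year = event_year,
                 outcome = outcome, weight = weight, cluster_id = "c1")
}

test_that("recall window keeps <3 years for DHS-like and <2 for MICS-like", {
  events <- c(2010L, 2011L, 2012L, 2013L)
  dhs <- micro("DHS-like", "d1", events)
  expect_equal(
    sort(filter_recall_window(dhs, 2014)$event_year), c(2012L, 2013L))

  mics <- micro("MICS-like", "m1", c(events, 2014L))
  expect_equal(
    sort(filter_recall_window(mics, 2014)$event_year), c(2013L, 2014L))

  cens <- micro("census-like", "c1", events)
  expect_equal(nrow(filter_recall_window(cens, 2014)), 4)
})

test_that("recall filter is idempotent, handles empty input, and rejects
           unknown families and future events", {
  empty <- micro("DHS-like", "d1", 2013L)[0, ]
  expect_equal(nrow(filter_recall_window(empty, 2014)), 0)

  dhs <- micro("DHS-like", "d1", 2009:2013)
  once <- filter_recall_window(dhs, 2014)
  expect_identical(filter_recall_window(once, 2014), once)

  expect_error(filter_recall_window(micro("AIS", "x", 2013L), 2014),
               "Unknown survey_family")
  expect_error(filter_recall_window(micro("DHS-like", "d1", 2015L), 2014),
               "after the survey")
})

test_that("recall filter accepts a per-survey year mapping", {
  rec <- dplyr::bind_rows(micro("DHS-like", "d1", 2011L),
                          micro("MICS-like", "m1", 2011L))
  sy <- tibble::tibble(survey_id = c("d1", "m1"),
                       survey_year = c(2013L, 2013L))
  out <- filter_recall_window(rec, sy)
  expect_equal(out$survey_id, "d1") # lag 2: kept by DHS, dropped by MICS
})

test_that("weighted proportion, Kish effective size and empirical logit are
           computed as specified", {
  eq <- micro("DHS-like", "s1", 2013L, outcome = c(1, 1, 0, 0),
              weight = rep(1, 4))
  est <- estimate_prevalence(eq)
  expect_equal(est$q, 0.5)
  expect_equal(est$n_eff, 4)
  expect_equal(est$y_logit, 0)
  expect_false(est$v_floor)

  wt <- micro("DHS-like", "s1", 2013L, outcome = c(1, 0, 0),
              weight = c(2, 1, 1))
  est <- estimate_prevalence(wt)
  expect_equal(est$q, 0.5)
  expect_equal(est$n_eff, 16 / 6)

  # all-zero outcomes trigger the continuity correction on the n_eff scale
  zero <- micro("DHS-like", "s1", 2013L, outcome = rep(0, 10),
                weight = rep(1, 10))
  est <- estimate_prevalence(zero)
  expect_equal(est$q, 0)
  expect_true(est$v_floor)
  expect_equal(est$y_logit, log((0.5 / 11) / (1 - 0.5 / 11)))

  expect_error(estimate_prevalence(eq[0, ]), "No microdata")
  expect_error(
    estimate_prevalence(micro("DHS-like", "s1", 2013L, weight = -1)),
    "positive")
})

test_that("equal weights reproduce the unweighted mean and n_eff = n;
           Kish n_eff never exceeds n", {
  set.seed(403)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    y <- rbinom(n, 1, 0.3)
    eqw <- estimate_prevalence(
      micro("DHS-like", "s1", 2013L, outcome = y, weight = rep(2.5, n)))
    expect_equal(eqw$q, mean(y))
    expect_equal(eqw$n_eff, n)

    w <- rlnorm(n, 0, 0.8)
    est <- estimate_prevalence(
      micro("DHS-like", "s1", 2013L, outcome = y, weight = w))
    expect_lte(est$n_eff, n + 1e-12)
  }
})

test_that("assemble_dataset indexes observations and keeps multiplicity", {
  g <- region_graph(data.frame(from = "A", to = "B"))
  obs <- dplyr::bind_rows(
    make_obs("A", 2010L, 0.4, 100, survey_id = "s1"),
    make_obs("A", 2010L, 0.5, 50, survey_id = "s2"),
    make_obs("B", 2012L, 0.2, 80)
  )
  ds <- assemble_dataset(obs, g, 2010:2012)
  expect_equal(ds$n_obs, 3)
  expect_equal(ds$n_cells, 6)
  expect_equal(ds$n_cells_observed, 2) # (A,2010) holds two surveys
  expect_equal(sum(ds$observations$region_id == "A" &
                     ds$observations$year == 2010), 2)

  expect_error(assemble_dataset(make_obs("Z", 2010L, 0.4, 100), g, 2010:2012),
               "Z")
  expect_error(assemble_dataset(make_obs("A", 2009L, 0.4, 100), g, 2010:2012),
               "outside the analysis window")

  # empty observation set is a valid (prior-predictive) dataset
  empty <- assemble_dataset(make_obs("A", 2010L, .4, 10)[0, ], g, 2010:2012)
  expect_equal(empty$n_obs, 0)
  expect_equal(empty$n_cells_observed, 0)
})
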