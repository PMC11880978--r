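test_that("dilution fits recover the slope and flag saturated lanes", {
  fit <- fit_dilution_response(
    data.frame(dilution = c(0.1, 0.5, 1.0), intensity = c(10, 50, 100)))
  expect_equal(fit$slope, 100)
  expect_equal(fit$used_points, 3L)
  expect_equal(fit$excluded_points, 0L)

  # undiluted lane reads 60 < 0.8 * 100: saturated, dropped from the fit
  fit <- fit_dilution_response(
    data.frame(dilution = c(0.1, 0.5, 1.0), intensity = c(10, 50, 60)),
    saturation_tolerance = 0.20)
  expect_equal(fit$slope, 100)
  expect_equal(fit$used_points, 2L)
  expect_equal(fit$excluded_points, 1L)

  fit <- fit_dilution_response(data.frame(dilution = 0.5, intensity = 40))
  expect_equal(fit$slope, 80)

  expect_error(fit_dilution_response(
    data.frame(dilution = c(0.1, 1), intensity = c(0, 0))), "zero")
})

test_that("saturation flagging stops at the first on-line point", {
  # middle lane on the line, top lane saturated: only the top is dropped
  fit <- fit_dilution_response(
    data.frame(dilution = c(0.1, 0.5, 1.0), intensity = c(10, 48, 60)))
  expect_equal(fit$excluded_points, 1L)
  # both upper lanes saturated
  fit <- fit_dilution_response(
    data.frame(dilution = c(0.1, 0.5, 1.0), intensity = c(10, 30, 35)))
  expect_equal(fit$excluded_points, 2L)
  expect_equal(fit$slope, 100)
})

test_that("pairwise ratios are slope ratios with the antibody affinity cancelling", {
  expect_equal(pairwise_ratio(comp_with_slopes(200, 100)), 2.0)
  expect_equal(pairwise_ratio(comp_with_slopes(100, 100)), 1.0)
  # true amounts 3:1 seen through an arbitrary shared affinity of 7.3
  expect_equal(pairwise_ratio(comp_with_slopes(7.3 * 3, 7.3 * 1)), 3.0)
})

test_that("the chained ratio multiplies through the bridge", {
  exp1 <- bridge_experiment(
    "e1",
    comp_with_slopes(50, 100, "anti-AXIN1", "AXIN1", "GFP-AXIN1"),
    comp_with_slopes(70, 70, "anti-GFP", "GFP-AXIN1", "GFP-AXIN2"),
    comp_with_slopes(7.12, 1, "anti-AXIN2", "GFP-AXIN2", "AXIN2"))
  expect_equal(chained_ratio(exp1), 0.5 * 1.0 * 7.12)
  expect_equal(chained_ratio(noise_free_bridge(1, 1)), 1.0)
})

test_that("a disconnected chain errors naming the broken link", {
  c1 <- comp_with_slopes(1, 1, "anti-AXIN1", "AXIN1", "GFP-AXIN1")
  c2 <- comp_with_slopes(1, 1, "anti-GFP", "GFP-AXIN2", "GFP-AXIN1")
  c3 <- comp_with_slopes(1, 1, "anti-AXIN2", "GFP-AXIN2", "AXIN2")
  expect_error(bridge_experiment("e", c1, c2, c3), "comparison 1.*comparison 2")
})

test_that("antibody affinities cancel exactly for any positive values", {
  set.seed(99)
  for (i in 1:20) {
    aff <- c(a1 = runif(1, 0.01, 50), gfp = runif(1, 0.01, 50),
             a2 = runif(1, 0.01, 50))
    r <- chained_ratio(noise_free_bridge(3.56 * 8, 8, aff = aff))
    expect_equal(r, 3.56, tolerance = 1e-9)
  }
  # the worked-example affinities
  r <- chained_ratio(noise_free_bridge(3.56, 1,
                                       aff = c(a1 = 5, gfp = 0.2, a2 = 11)))
  expect_equal(r, 3.56, tolerance = 1e-12)
})

test_that("the GFP-construct amounts drop out of the chained ratio", {
  base <- chained_ratio(noise_free_bridge(35.6, 10, gfp1 = 7, gfp2 = 13))
  for (s in c(0.1, 0.5, 2, 10)) {
    r <- chained_ratio(noise_free_bridge(35.6, 10, gfp1 = 7 * s,
                                         gfp2 = 13 / s))
    expect_equal(r, base, tolerance = 1e-9)
  }
})

test_that("any single matched dilution gives the full-fit ratio when noise-free", {
  full <- pairwise_ratio(comp_with_slopes(120, 45))
  for (d in c(0.1, 0.5, 1.0)) {
    one <- pairwise_comparison("ab", "A", "B",
                               data.frame(dilution = d, intensity = 120 * d),
                               data.frame(dilution = d, intensity = 45 * d))
    expect_equal(pairwise_ratio(one), full, tolerance = 1e-12)
  }
})

test_that("aggregation reports mean, SEM and n on the ratio scale", {
  six <- lapply(1:6, function(i) noise_free_bridge(3.56, 1,
                                                   experiment_id = paste0("e", i)))
  est <- aggregate_ratio(six)
  expect_equal(est$mean, 3.56, tolerance = 1e-9)
  expect_equal(est$sem, 0, tolerance = 1e-9)
  expect_equal(est$n, 6L)

  two <- list(noise_free_bridge(3, 1, experiment_id = "e1"),
              noise_free_bridge(4, 1, experiment_id = "e2"))
  est <- aggregate_ratio(two)
  expect_equal(est$mean, 3.5, tolerance = 1e-9)
  expect_equal(est$sem, 0.5, tolerance = 1e-9)
  expect_error(aggregate_ratio(list()), "no bridge")
})

test_that("log-scale aggregation returns the geometric mean", {
  two <- list(noise_free_bridge(2, 1, experiment_id = "e1"),
              noise_free_bridge(8, 1, experiment_id = "e2"))
  est <- aggregate_ratio(two, log_scale = TRUE)
  expect_equal(est$mean, 4, tolerance = 1e-9)
})

test_that("detector saturation is excluded rather than biasing the ratio", {
  # cap so the undiluted endo-AXIN1 lane (5 x 35.6 = 178) clips deeply;
  # clips shallower than the 20% tolerance are undetectable by design
  tr <- bridge_truth(3.56, noise_sigma = 0, lane_loading_cv = 0,
                     saturation_cap = 120, seed = 21)
  exps <- simulate_bridge_study(3.56, 4, tr, construct_spread = 0)
  est <- aggregate_ratio(exps)
  expect_equal(est$mean, 3.56, tolerance = 1e-6)
  expect_gt(sum(est$qc$excluded_saturated), 0)
})

test_that("experiments assemble from band and design tables", {
  tr <- bridge_truth(3.56, noise_sigma = 0, lane_loading_cv = 0, seed = 5)
  exps <- simulate_bridge_study(3.56, 2, tr)
  tabs <- bridge_study_tables(exps)
  rebuilt <- assemble_bridge_experiments(tabs$bands, tabs$design)
  expect_equal(aggregate_ratio(rebuilt)$mean, 3.56, tolerance = 1e-9)
})
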