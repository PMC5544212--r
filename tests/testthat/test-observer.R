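test_that("the generative PSS mirrors across cue sides and is zero for bilateral cues", {
  obs <- observer_spec(shifts = c(near = 10, far = 4), beta = 0.05)
  expect_equal(true_alpha(obs, "left", "near"), 10)
  expect_equal(true_alpha(obs, "right", "near"), -10)
  expect_equal(true_alpha(obs, "left", "far"), 4)
  expect_equal(true_alpha(obs, "bilateral", "near"), 0)
  expect_equal(true_alpha(obs, "bilateral", "far"), 0)
  expect_error(true_alpha(obs, "left", "near", "congruent"), "unknown condition cell")
  obs2 <- observer_spec(shifts = c(near_congruent = 6), beta = 0.05)
  expect_equal(true_alpha(obs2, "right", "near", "congruent"), -6)
})

test_that("simulated reports follow the psychometric asymptotes and modality complement", {
  obs <- observer_spec(shifts = c(near = 0), beta = 5, lapse = 0)
  # left stimulus far earlier: 'which first' reports left, 'which second' right
  expect_equal(simulate_response(obs, -200, "left", "near", u = 0.5), "left")
  expect_equal(simulate_response(obs, -200, "left", "near",
                                 modality = "second", u = 0.5), "right")
  expect_equal(simulate_response(obs, 200, "left", "near", u = 0.5), "right")
  # same percept (same u), opposite label across modalities
  for (u in c(0.1, 0.5, 0.9)) {
    first <- simulate_response(obs, 10, "left", "near", u = u)
    second <- simulate_response(obs, 10, "left", "near",
                                modality = "second", u = u)
    expect_equal(second, setdiff(c("left", "right"), first))
  }
})

test_that("at the true PSS the two orders are reported equally often", {
  obs <- observer_spec(shifts = c(near = 15), beta = 0.05, lapse = 0)
  set.seed(501)
  draws <- replicate(10000,
                     simulate_response(obs, 15, "left", "near") == "right")
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("a session contains the full factorial trial count and is seed-reproducible", {
  cfg <- exp1_config()
  obs <- observer_spec(shifts = c(near = 10, far = 5), beta = 0.06,
                       lapse = 0.01)
  log1 <- simulate_session(obs, cfg, seed = 21)
  expect_equal(nrow(log1), 240)
  expect_true(all(log1$soa %in% cfg$soa_set))
  expect_true(all(log1$response %in% c("left", "right")))
  est <- attr(log1, "estimates")
  expect_equal(nrow(est), 12)  # 4 blocks x 3 cue conditions
  expect_true(all(est$n_trials == 20))
  log2 <- simulate_session(obs, cfg, seed = 21)
  expect_identical(as.data.frame(log1), as.data.frame(log2))
  log3 <- simulate_session(obs, cfg, seed = 22)
  expect_false(identical(log1$response, log3$response))
})

test_that("a nearly deterministic unbiased observer is recovered within one grid step", {
  cfg <- exp1_config()
  obs <- observer_spec(shifts = c(near = 0, far = 0), beta = 0.5, lapse = 0)
  log1 <- simulate_session(obs, cfg, seed = 31)
  est <- attr(log1, "estimates")
  expect_true(all(abs(est$pss) <= 10))
})

test_that("mirrored shift maps produce mirrored recovered effects", {
  cfg <- exp1_config()
  grid <- psi_grid()
  combined <- function(sign, seeds) {
    obs <- observer_spec(shifts = c(near = sign * 8, far = sign * 8),
                         beta = 0.1, lapse = 0)
    vapply(seeds, function(s) {
      log1 <- simulate_session(obs, cfg, s, grid)
      tr <- merge_modalities(as.data.frame(log1))
      near <- tr[tr$visual_position == "near", ]
      fL <- fit_condition(near[near$cue_condition == "left", ], grid)
      fR <- fit_condition(near[near$cue_condition == "right", ], grid)
      combine_unilateral(fL$pss, fR$pss)
    }, 0)
  }
  plus <- combined(1, 1:40)
  minus <- combined(-1, 101:140)
  expect_lt(abs(mean(plus) + mean(minus)), 3)
  expect_gt(mean(plus), 0)
  expect_lt(mean(minus), 0)
})

test_that("cohorts are reproducible and degenerate SDs give identical observers", {
  cfg <- exp1_config()
  spec <- cohort_spec(n = 3, shift_mean = c(near = 6, far = 2),
                      shift_sd = c(near = 0, far = 0), beta_log_sd = 0,
                      lapse = 0, seed = 5)
  logs <- simulate_cohort(spec, cfg)
  expect_length(logs, 3)
  truth <- attr(logs, "truth")
  expect_true(all(truth$near == 6))
  expect_true(all(truth$far == 2))
  expect_true(all(truth$beta == truth$beta[1]))
  expect_equal(vapply(logs, nrow, 0L), c(P01 = 240L, P02 = 240L, P03 = 240L))
  logs2 <- simulate_cohort(spec, cfg)
  expect_identical(as.data.frame(logs[[2]]), as.data.frame(logs2[[2]]))
})

test_that("equicorrelated shift draws respect means, SDs and correlation", {
  cfg <- exp1_config()
  spec <- cohort_spec(n = 60, shift_mean = c(near = 10, far = 5),
                      shift_sd = c(near = 6, far = 4), shift_cor = 0.8,
                      seed = 77)
  truth <- attr(simulate_cohort(spec, cfg), "truth")
  expect_equal(mean(truth$near), 10, tolerance = 2.5)
  expect_equal(sd(truth$near), 6, tolerance = 2)
  expect_equal(sd(truth$far), 4, tolerance = 1.5)
  expect_equal(cor(truth$near, truth$far), 0.8, tolerance = 0.2)
})
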