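test_that("initialization sets the posterior to the prior with a valid cache", {
  g <- psi_grid(alpha = c(-10, 10), beta = c(0.04, 0.08))
  st <- psi_init(g, c(-10, -5, 5, 10))
  expect_equal(st$posterior, rep(0.25, 4))
  expect_equal(st$trial_count, 0L)
  # marginal over alpha sums to 1
  pm <- matrix(st$posterior, 2, 2)
  expect_equal(sum(rowSums(pm)), 1)
  # cache at soa equal to a grid alpha is 0.5 for that alpha, any beta
  expect_equal(st$cache[c(1, 3), 1], c(0.5, 0.5))  # alpha = -10 rows, soa -10
  expect_true(all(st$cache > 0 & st$cache < 1))
  expect_equal(st$cache + st$cache0, matrix(1, 4, 4))
})

test_that("initialization rejects bad grids and SOA sets", {
  g <- psi_grid(alpha = c(-50, 0, 50), beta = c(0.04, 0.08))
  expect_error(psi_init(g, numeric(0)), "soa_set")
  expect_error(psi_init(g, c(-100, 100)), "span")
  expect_error(psi_grid(alpha = c(0, 0, 1)), "increasing")
  expect_error(psi_grid(beta = c(-0.1, 0.1)), "positive")
  expect_error(psi_grid(alpha = c(-1, 1), beta = c(0.1, 0.2),
                        prior = matrix(0, 2, 2)), "normalizable")
})

test_that("SOA selection matches exhaustive expected-entropy enumeration", {
  set.seed(401)
  for (i in 1:30) {
    st <- random_psi_state()
    expect_identical(psi_select_soa(st),
                     oracle_select_soa(st$posterior, st$cache, st$cache0,
                                       st$soa_set))
  }
})

test_that("selection tie-breaks deterministically and warns on point-mass posteriors", {
  g <- psi_grid(alpha = 0, beta = 0.05)
  st <- psi_init(g, c(-30, -10, 10, 30))
  # single-point grid: all expected entropies are 0 (entropy of a point mass)
  expect_warning(res <- psi_select_soa(st), "degenerate")
  expect_equal(res, -10)  # smallest |SOA|, negative preferred
  # mirrored symmetric state picks a smallest-|SOA| candidate
  # in a mirror-symmetric state the +/- expected entropies tie and the
  # negative member is returned
  g2 <- psi_grid(alpha = c(-20, 20), beta = c(0.05, 0.1))
  st2 <- psi_init(g2, c(-20, -10, 10, 20))
  eh <- psi_expected_entropy(st2)
  expect_equal(eh[1], eh[4], tolerance = 1e-12)
  expect_equal(eh[2], eh[3], tolerance = 1e-12)
  expect_lt(psi_select_soa(st2), 0)
})

test_that("posterior updates follow Bayes' rule and commute", {
  g <- psi_grid(alpha = c(-20, 20), beta = 0.05)
  st <- psi_init(g, c(-10, 10))
  lik <- st$cache[, 2]
  st1 <- psi_update(st, 10, 1)
  expect_equal(st1$posterior, lik * 0.5 / sum(lik * 0.5), tolerance = 1e-14)
  expect_equal(st1$trial_count, 1L)
  # response 1 then 0 at one SOA equals 0 then 1
  a <- psi_update(psi_update(st, 10, 1), 10, 0)
  b <- psi_update(psi_update(st, 10, 0), 10, 1)
  expect_equal(a$posterior, b$posterior, tolerance = 1e-14)
  expect_error(psi_update(st, 999, 1), "candidate set")
  expect_error(psi_update(st, 10, 2), "0/1")
})

test_that("sequential updating equals batch Bayes and stays normalized", {
  set.seed(402)
  for (i in 1:20) {
    st <- random_psi_state()
    prior <- st$posterior
    n_tr <- 20
    s_idx <- sample(seq_along(st$soa_set), n_tr, replace = TRUE)
    resp <- sample(0:1, n_tr, replace = TRUE)
    run <- st
    for (t in seq_len(n_tr)) {
      run <- psi_update(run, st$soa_set[s_idx[t]], resp[t])
      expect_equal(sum(run$posterior), 1, tolerance = 1e-12)
    }
    batch <- oracle_batch_posterior(prior, st$cache, st$cache0, s_idx, resp)
    expect_equal(run$posterior, batch, tolerance = 1e-12)
    expect_equal(run$trial_count, n_tr)
  }
})

test_that("posterior-mean estimates respect concentration and symmetry", {
  g <- psi_grid(alpha = c(-20, 0, 20), beta = c(0.02, 0.05, 0.1))
  st <- psi_init(g, c(-15, -5, 5, 15))
  st$trial_count <- 1L
  # point mass on (alpha = 20, beta = 0.05): flattened index alpha-fastest
  p <- rep(0, 9); p[3 + 3] <- 1
  st$posterior <- p
  est <- psi_estimate(st)
  expect_equal(est$alpha, 20)
  expect_equal(est$beta, 0.05)
  # posterior symmetric about alpha = 0 estimates alpha = 0
  st$posterior <- rep(1 / 9, 9)
  expect_equal(psi_estimate(st)$alpha, 0)
  expect_error(psi_estimate(psi_init(g, c(-10, 10))), "at least one")
})

test_that("the compiled series runner reproduces stepwise select/respond/update", {
  g <- psi_grid(alpha = seq(-100, 100, by = 20), beta = c(0.02, 0.05, 0.1))
  soas <- c(-90, -55, -30, -10, 10, 30, 55, 90)
  truth <- psychometric_params(12, 0.06)
  set.seed(403)
  u <- runif(40)
  fast <- run_psi_series(truth, 40, g, soas, u = u)
  st <- psi_init(g, soas)
  p_true <- response_probability(soas, truth)
  soa_seq <- numeric(40); resp_seq <- integer(40)
  for (t in 1:40) {
    soa <- psi_select_soa(st)
    r <- as.integer(u[t] < p_true[match(soa, soas)])
    st <- psi_update(st, soa, r)
    soa_seq[t] <- soa; resp_seq[t] <- r
  }
  expect_identical(fast$soa, soa_seq)
  expect_identical(fast$response, resp_seq)
  expect_equal(fast$posterior, st$posterior, tolerance = 1e-10)
  expect_equal(fast$estimate$alpha, psi_estimate(st)$alpha, tolerance = 1e-8)
})

test_that("identical seed and configuration give identical series", {
  truth <- psychometric_params(8, 0.05)
  soas <- exp1_config()$soa_set
  set.seed(7); a <- run_psi_series(truth, 30, psi_grid(), soas)
  set.seed(7); b <- run_psi_series(truth, 30, psi_grid(), soas)
  expect_identical(a$soa, b$soa)
  expect_identical(a$response, b$response)
  expect_identical(a$estimate$alpha, b$estimate$alpha)
})

test_that("a 200-trial series recovers a mid-grid observer to within the oracle tolerance", {
  set.seed(404)
  truth <- psychometric_params(8, 0.04)
  soas <- exp1_config()$soa_set
  err <- vapply(1:100, function(i)
    run_psi_series(truth, 200, psi_grid(), soas)$estimate$alpha - 8, 0)
  expect_lt(median(abs(err)), 4)
})

test_that("engine state round-trips through JSON", {
  g <- psi_grid(alpha = seq(-50, 50, by = 25), beta = c(0.02, 0.08))
  st <- psi_init(g, c(-30, -10, 10, 30))
  st <- psi_update(psi_update(st, -10, 0), 30, 1)
  txt <- psi_state_to_json(st)
  back <- psi_state_from_json(txt)
  expect_equal(back$posterior, st$posterior, tolerance = 1e-12)
  expect_equal(back$soa_set, st$soa_set)
  expect_equal(back$trial_count, st$trial_count)
  expect_equal(back$history$soa, st$history$soa)
  expect_equal(psi_estimate(back)$alpha, psi_estimate(st)$alpha)
})
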