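#' Parameter grid and prior for the PSI engine
#'
#' The PSI procedure maintains a posterior over a discrete (alpha, beta)
#' grid. Defaults: alpha uniform from -200 to 200 ms in 41 steps (the span
#' of the most extreme SOAs used by the designs), beta log-spaced from
#' 0.005 to 0.5 1/ms in 25 steps, and a uniform prior on alpha and on
#' log(beta). Slopes are scale parameters, hence the log spacing and the
#' log-scale posterior mean in [psi_estimate()].
#'
#' @param alpha Strictly increasing vector of candidate PSS values (ms).
#' @param beta Strictly increasing vector of candidate slopes (1/ms),
#'   all positive.
#' @param prior Optional non-negative matrix of prior weights,
#'   `length(alpha)` x `length(beta)`; normalized internally. Default
#'   uniform.
#' @return An object of class `psi_grid`.
#' @export
psi_grid <- function(alpha = seq(-200, 200, length.out = 41),
                     beta = exp(seq(log(0.005), log(0.5), length.out = 25)),
                     prior = NULL) {
  if (!is.numeric(alpha) || length(alpha) < 1L || any(!is.finite(alpha)) ||
      is.unsorted(alpha, strictly = TRUE))
    stop("`alpha` must be a strictly increasing finite vector", call. = FALSE)
  if (!is.numeric(beta) || length(beta) < 1L || any(!is.finite(beta)) ||
      any(beta <= 0) || is.unsorted(beta, strictly = TRUE))
    stop("`beta` must be a strictly increasing vector of positive slopes",
         call. = FALSE)
  if (is.null(prior)) {
    prior <- matrix(1 / (length(alpha) * length(beta)),
                    nrow = length(alpha), ncol = length(beta))
  } else {
    prior <- as.matrix(prior)
    if (!identical(dim(prior), c(length(alpha), length(beta))))
      stop("`prior` must be a length(alpha) x length(beta) matrix",
           call. = FALSE)
    if (any(!is.finite(prior)) || any(prior < 0) || sum(prior) <= 0)
      stop("`prior` must be non-negative and normalizable", call. = FALSE)
    prior <- prior / sum(prior)
  }
  structure(list(alpha = alpha, beta = beta, prior = prior),
            class = "psi_grid")
}

# Likelihood cache: psi(soa | alpha_i, beta_j) for every grid point and SOA.
# Rows index the flattened grid with alpha varying fastest (column-major
# order of the prior matrix); columns index soa_set. The complement
# p(r = 0) is computed from the mirrored logistic plogis(-z) rather than
# as 1 - p, so that extreme (slope x SOA) cells never cancel to exactly 0.
psi_cache_pair <- function(grid, soa_set, lapse = 0) {
  a <- rep(grid$alpha, times = length(grid$beta))
  b <- rep(grid$beta, each = length(grid$alpha))
  C1 <- vapply(soa_set,
               function(x) lapse + (1 - 2 * lapse) * stats::plogis(b * (x - a)),
               numeric(length(a)))
  C0 <- vapply(soa_set,
               function(x) lapse + (1 - 2 * lapse) * stats::plogis(b * (a - x)),
               numeric(length(a)))
  list(C1 = C1, C0 = C0)
}

psi_cache <- function(grid, soa_set, lapse = 0) {
  psi_cache_pair(grid, soa_set, lapse)$C1
}

# Precomputed pieces for fast expected-entropy evaluation:
# C1 = p(r = 1), C0 = p(r = 0), M1 = C1 log C1, M0 = C0 log C0.
psi_cache_parts <- function(grid, soa_set, lapse = 0) {
  pair <- psi_cache_pair(grid, soa_set, lapse)
  C1 <- pair$C1
  C0 <- pair$C0
  list(C1 = C1, C0 = C0, M1 = C1 * log(C1), M0 = C0 * log(C0),
       tie_order = order(abs(soa_set), soa_set))
}

#' Initialize a PSI adaptive state
#'
#' Builds the engine state for one series: posterior set to the prior, the
#' likelihood cache precomputed from [response_probability()] for every
#' (SOA, grid point) pair, and the trial counter at zero.
#'
#' @param grid A [psi_grid()].
#' @param soa_set The experiment's discrete candidate SOAs (ms), non-empty.
#' @param lapse Fixed lapse rate used by the engine's model (default 0,
#'   mirroring the two-parameter logistic used for fitting).
#' @return An object of class `psi_state`.
#' @export
psi_init <- function(grid, soa_set, lapse = 0) {
  if (!inherits(grid, "psi_grid"))
    stop("`grid` must be a psi_grid object", call. = FALSE)
  if (!is.numeric(soa_set) || length(soa_set) == 0L || any(!is.finite(soa_set)))
    stop("`soa_set` must be a non-empty finite vector (ms)", call. = FALSE)
  if (anyDuplicated(soa_set))
    stop("`soa_set` must not contain duplicates", call. = FALSE)
  if (length(grid$alpha) > 1L &&
      (min(soa_set) < min(grid$alpha) || max(soa_set) > max(grid$alpha)))
    stop("the alpha grid span must contain the SOA range", call. = FALSE)
  if (!is.numeric(lapse) || lapse < 0 || lapse >= 0.5)
    stop("`lapse` must lie in [0, 0.5)", call. = FALSE)
  pair <- psi_cache_pair(grid, soa_set, lapse)
  structure(list(
    grid = grid,
    soa_set = soa_set,
    lapse = lapse,
    posterior = as.vector(grid$prior),
    cache = pair$C1,
    cache0 = pair$C0,
    tie_order = order(abs(soa_set), soa_set),
    trial_count = 0L,
    history = data.frame(trial = integer(), soa = numeric(),
                         response = integer())
  ), class = "psi_state")
}

#' @export
print.psi_state <- function(x, ...) {
  cat(sprintf("psi_state: %d x %d grid, %d SOAs, %d trials observed\n",
              length(x$grid$alpha), length(x$grid$beta),
              length(x$soa_set), x$trial_count))
  invisible(x)
}

#' Expected posterior entropy of each candidate SOA
#'
#' For each SOA `x` in the state's candidate set, computes
#' \eqn{E[H](x) = \sum_r p(r|x) H(\mathrm{posterior} \mid x, r)} where
#' `p(r|x)` marginalizes the trial likelihood over the current posterior.
#' This is the quantity the PSI procedure minimizes when picking the next
#' trial's SOA.
#'
#' @param state A [psi_init()] state.
#' @return Numeric vector of expected entropies (nats), one per SOA.
#' @export
psi_expected_entropy <- function(state) {
  stopifnot(inherits(state, "psi_state"))
  post <- state$posterior
  C1 <- state$cache
  C0 <- state$cache0
  M1 <- C1 * log(C1)
  M0 <- C0 * log(C0)
  plp <- ifelse(post > 0, post * log(post), 0)
  w1 <- as.vector(crossprod(C1, post))
  w0 <- as.vector(crossprod(C0, post))
  s1 <- as.vector(crossprod(M1, post)) + as.vector(crossprod(C1, plp))
  s0 <- as.vector(crossprod(M0, post)) + as.vector(crossprod(C0, plp))
  ifelse(w1 > 0, w1 * log(w1), 0) - s1 +
    ifelse(w0 > 0, w0 * log(w0), 0) - s0
}

# Deterministic argmin with the documented tie-break: walk the SOAs in
# tie-break order (smallest |SOA| first, negative before positive) and only
# displace the incumbent when the improvement exceeds tol.
pick_min_entropy <- function(values, tie_order, tol = 1e-12) {
  best <- tie_order[1L]
  for (k in tie_order[-1L]) if (values[k] < values[best] - tol) best <- k
  best
}

#' Select the next SOA by expected-entropy minimization
#'
#' Returns the candidate SOA minimizing [psi_expected_entropy()].
#' Ties resolve deterministically: the smallest `|SOA|` wins and a
#' remaining +/- tie resolves to the negative SOA. A degenerate posterior
#' (all mass on one grid point) triggers a warning and returns the
#' tie-break default.
#'
#' @param state A [psi_init()] state.
#' @return One SOA value (ms) from the state's candidate set.
#' @export
psi_select_soa <- function(state) {
  stopifnot(inherits(state, "psi_state"))
  if (max(state$posterior) >= 1 - 1e-12) {
    warning("degenerate posterior (point mass); returning tie-break default SOA")
    return(state$soa_set[state$tie_order[1L]])
  }
  eh <- psi_expected_entropy(state)
  state$soa_set[pick_min_entropy(eh, state$tie_order)]
}

#' Bayesian update of the PSI posterior after one trial
#'
#' Multiplies the current posterior by the Bernoulli trial likelihood at
#' the presented SOA and renormalizes. Updates commute, so any trial order
#' yields the batch-Bayes posterior.
#'
#' @param state A [psi_init()] state.
#' @param soa The presented SOA; must belong to the state's candidate set.
#' @param response 0/1 response (1 = reference stimulus judged first).
#' @return The updated `psi_state`.
#' @export
psi_update <- function(state, soa, response) {
  stopifnot(inherits(state, "psi_state"))
  s <- match(soa, state$soa_set)
  if (is.na(s))
    stop("`soa` is not in the state's candidate set", call. = FALSE)
  if (length(response) != 1L || !(response %in% c(0, 1)))
    stop("`response` must be a single 0/1 value", call. = FALSE)
  lik <- if (response == 1) state$cache[, s] else state$cache0[, s]
  post <- state$posterior * lik
  z <- sum(post)
  if (!is.finite(z) || z <= 0)
    stop("posterior update failed: total likelihood is zero across the grid",
         call. = FALSE)
  state$posterior <- post / z
  state$trial_count <- state$trial_count + 1L
  state$history <- rbind(state$history,
                         data.frame(trial = state$trial_count, soa = soa,
                                    response = as.integer(response)))
  state
}

#' Posterior-mean parameter estimate
#'
#' `alpha` is the posterior marginal mean over the alpha grid; `beta` is
#' the exponential of the posterior marginal mean of `log(beta)` (slopes
#' are averaged on the log scale); the lapse is the engine's fixed value.
#'
#' @param state A `psi_state` with at least one observed trial.
#' @return A [psychometric_params()] object.
#' @export
psi_estimate <- function(state) {
  stopifnot(inherits(state, "psi_state"))
  if (state$trial_count < 1L)
    stop("estimate requires at least one observed trial", call. = FALSE)
  estimate_from_posterior(state$posterior, state$grid, state$lapse)
}

estimate_from_posterior <- function(posterior, grid, lapse = 0) {
  pm <- matrix(posterior, nrow = length(grid$alpha), ncol = length(grid$beta))
  alpha_hat <- sum(rowSums(pm) * grid$alpha)
  beta_hat <- exp(sum(colSums(pm) * log(grid$beta)))
  psychometric_params(alpha_hat, beta_hat, lapse)
}

#' Serialize / restore a PSI state as JSON
#'
#' The grid, prior, posterior, SOA set, lapse and trial history are written
#' at full precision; the likelihood cache is rebuilt on restore. Enables
#' session resumption.
#'
#' @param state A `psi_state`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `psi_state_to_json`: the JSON string (invisibly when written to
#'   a file). `psi_state_from_json`: the restored `psi_state`.
#' @export
psi_state_to_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "psi_state"))
  obj <- list(
    alpha = state$grid$alpha,
    beta = state$grid$beta,
    prior = as.vector(state$grid$prior),
    posterior = state$posterior,
    soa_set = state$soa_set,
    lapse = state$lapse,
    trial_count = state$trial_count,
    history = state$history
  )
  txt <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' @param x JSON string or path to a JSON file produced by
#'   `psi_state_to_json`.
#' @rdname psi_state_to_json
#' @export
psi_state_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  grid <- psi_grid(alpha = obj$alpha, beta = obj$beta,
                   prior = matrix(obj$prior, nrow = length(obj$alpha)))
  state <- psi_init(grid, obj$soa_set, obj$lapse)
  state$posterior <- obj$posterior
  state$trial_count <- as.integer(obj$trial_count)
  hist <- as.data.frame(obj$history)
  if (nrow(hist) > 0) state$history <- hist
  state
}

#' Run one adaptive PSI series against a simulated observer
#'
#' Repeats select-SOA, draw a Bernoulli response from the observer's true
#' psychometric function, update the posterior, for `n_trials` trials. The
#' trial loop runs in compiled code; it is numerically equivalent to
#' iterating [psi_select_soa()] and [psi_update()] (cross-checked in the
#' test suite).
#'
#' @param truth A [psychometric_params()] object: the generating observer.
#' @param n_trials Number of trials in the series.
#' @param grid A [psi_grid()].
#' @param soa_set Candidate SOAs (ms).
#' @param lapse_fit Lapse rate assumed by the engine (default 0).
#' @param u Optional vector of `n_trials` uniform draws; defaults to
#'   `runif(n_trials)` so the series is governed by R's RNG state.
#' @return A list with `soa` (presented SOAs), `response` (0/1),
#'   `posterior` (final posterior over the flattened grid) and `estimate`
#'   (a `psychometric_params`).
#' @export
run_psi_series <- function(truth, n_trials, grid = psi_grid(),
                           soa_set, lapse_fit = 0, u = NULL) {
  stopifnot(inherits(truth, "psychometric_params"))
  if (is.null(u)) u <- stats::runif(n_trials)
  if (length(u) != n_trials)
    stop("`u` must contain one uniform draw per trial", call. = FALSE)
  parts <- psi_cache_parts(grid, soa_set, lapse_fit)
  p_true <- response_probability(soa_set, truth)
  res <- run_psi_series_cpp(parts$C1, parts$M1, parts$C0, parts$M0,
                            as.vector(grid$prior), p_true, u,
                            as.integer(parts$tie_order))
  list(soa = soa_set[res$soa_idx],
       response = res$response,
       posterior = res$posterior,
       estimate = estimate_from_posterior(res$posterior, grid, lapse_fit))
}
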