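# Independent brute-force oracles for the adaptive engine, written as plain
# loops so they share no code path with the package implementation.

# Expected posterior entropy per candidate SOA by direct enumeration over
# (response, grid point).
oracle_expected_entropy <- function(post, C1, C0) {
  n_soa <- ncol(C1)
  eh <- numeric(n_soa)
  for (s in seq_len(n_soa)) {
    for (r in 0:1) {
      w <- post * (if (r == 1) C1[, s] else C0[, s])
      W <- sum(w)
      if (W > 0) {
        q <- w / W
        q <- q[q > 0]
        eh[s] <- eh[s] + W * (-sum(q * log(q)))
      }
    }
  }
  eh
}

# SOA choice by exhaustive minimization with the documented tie-break rule:
# walk candidates ordered by (|SOA|, negative first); a later candidate must
# improve by more than 1e-12 to win.
oracle_select_soa <- function(post, C1, C0, soa_set) {
  eh <- oracle_expected_entropy(post, C1, C0)
  ord <- order(abs(soa_set), soa_set)
  best <- ord[1]
  for (k in ord[-1]) if (eh[k] < eh[best] - 1e-12) best <- k
  soa_set[best]
}

# One-pass batch Bayes posterior from a trial stream.
oracle_batch_posterior <- function(prior, C1, C0, s_idx, resp) {
  post <- prior
  for (k in seq_along(post)) {
    for (t in seq_along(s_idx)) {
      lik <- if (resp[t] == 1) C1[k, s_idx[t]] else C0[k, s_idx[t]]
      post[k] <- post[k] * lik
    }
  }
  post / sum(post)
}

# Random small engine state (grid <= 5 x 5, <= 10 SOAs) with a random
# normalized posterior.
random_psi_state <- function() {
  n_a <- sample(2:5, 1)
  n_b <- sample(2:5, 1)
  n_s <- sample(3:10, 1)
  # alpha span always covers the SOA range (engine invariant)
  alpha <- sort(c(-100, 100, stats::runif(n_a - 2, -90, 90)))
  beta <- sort(stats::runif(n_b, 0.01, 0.3))
  soa <- sort(sample(setdiff(-100:100, 0), n_s))
  state <- psi_init(psi_grid(alpha = alpha, beta = beta), soa)
  p <- stats::rexp(n_a * n_b)
  state$posterior <- p / sum(p)
  state
}

# Small deterministic trial set spanning several SOAs, for fitting tests.
make_trials <- function(soas, responses, modality = "first") {
  data.frame(soa = soas, response = responses,
             response_modality = modality, stringsAsFactors = FALSE)
}

# Single-modality fixtures are expected in fitting tests; silence the
# missing-modality warning only.
merge_modalities_keep <- function(trials) {
  suppressWarnings(merge_modalities(trials))
}
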