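#' Condition cell labels of a configuration
#'
#' The analysis cells are the visual-position levels (first design) or the
#' position x hand-congruency crossing (second design). Labels are
#' `"near"`/`"far"` or `"near_congruent"`, ..., matching the names expected
#' in an observer's shift map.
#'
#' @param config A `toj_config`.
#' @return Character vector of cell labels.
#' @export
cell_labels <- function(config) {
  stopifnot(inherits(config, "toj_config"))
  if (is.null(config$congruency)) return(config$positions)
  as.vector(outer(config$positions, config$congruency, paste, sep = "_"))
}

cell_label <- function(position, congruency = "none") {
  ifelse(congruency %in% c(NA, "none"), position,
         paste(position, congruency, sep = "_"))
}

#' Ground-truth generative parameters of one simulated observer
#'
#' A simulated participant embodies prior entry: a nociceptive cue on one
#' hand shifts attention to that side, so the attended (cued-side) visual
#' stimulus is perceived earlier and the uncued stimulus must lead by the
#' cell's `shift` (ms) to be perceived as simultaneous. The shift magnitude
#' is defined per condition cell (position, or position x congruency);
#' bilateral cues shift nothing.
#'
#' @param shifts Named numeric vector of true per-cell PSS shifts in ms
#'   (names as in [cell_labels()]). Positive = prioritization of the cued
#'   side.
#' @param beta True slope of the observer's psychometric function (1/ms).
#' @param lapse Stimulus-independent error rate in `[0, 0.5)`.
#' @return An object of class `observer_spec`.
#' @examples
#' obs <- observer_spec(shifts = c(near = 10.95, far = 5.34), beta = 0.04)
#' true_alpha(obs, "left", "near")   #  +10.95
#' true_alpha(obs, "right", "near")  #  -10.95
#' true_alpha(obs, "bilateral", "near")  # 0
#' @export
observer_spec <- function(shifts, beta = 0.1, lapse = 0) {
  if (!is.numeric(shifts) || is.null(names(shifts)) ||
      any(!nzchar(names(shifts))) || any(!is.finite(shifts)))
    stop("`shifts` must be a named finite numeric vector (ms per cell)",
         call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a single positive slope (1/ms)", call. = FALSE)
  if (!is.numeric(lapse) || length(lapse) != 1L || lapse < 0 || lapse >= 0.5)
    stop("`lapse` must lie in [0, 0.5)", call. = FALSE)
  structure(list(shifts = shifts, beta = beta, lapse = lapse),
            class = "observer_spec")
}

#' Generative PSS of one trial context
#'
#' Maps a trial's cue condition and condition cell to the observer's true
#' `alpha` in the left/right SOA frame (negative SOA = left stimulus
#' first, response model = probability of "right first"). A left-hand cue
#' yields `+shift` (the right stimulus must lead by `shift` ms to be
#' perceived as simultaneous, i.e. the left side is prioritized), a
#' right-hand cue `-shift`, a bilateral cue 0.
#'
#' @param observer An [observer_spec()].
#' @param cue_condition `"left"`, `"right"` or `"bilateral"`.
#' @param position `"near"` or `"far"`.
#' @param congruency `"congruent"`, `"incongruent"` or `"none"`.
#' @return True alpha in ms.
#' @export
true_alpha <- function(observer, cue_condition, position,
                       congruency = "none") {
  stopifnot(inherits(observer, "observer_spec"))
  if (cue_condition == "bilateral") return(0)
  lab <- cell_label(position, congruency)
  if (!lab %in% names(observer$shifts))
    stop(sprintf("unknown condition cell '%s' in observer shift map", lab),
         call. = FALSE)
  s <- unname(observer$shifts[[lab]])
  switch(cue_condition,
         left = s,
         right = -s,
         stop(sprintf("unknown cue condition '%s'", cue_condition),
              call. = FALSE))
}

#' Draw one simulated TOJ response
#'
#' The perceived-first side is drawn from the observer's true psychometric
#' function at the presented SOA; in the "which second" response modality
#' the reported label is the complement of the perceived-first side.
#'
#' @inheritParams true_alpha
#' @param soa Presented SOA (ms, left/right frame).
#' @param modality `"first"` or `"second"`.
#' @param u Optional uniform draw in `[0, 1]`; defaults to `runif(1)`.
#' @return `"left"` or `"right"` -- the reported label.
#' @export
simulate_response <- function(observer, soa, cue_condition, position,
                              congruency = "none", modality = "first",
                              u = stats::runif(1)) {
  a <- true_alpha(observer, cue_condition, position, congruency)
  p_right_first <- response_probability(
    soa, psychometric_params(a, observer$beta, observer$lapse))
  perceived <- if (u < p_right_first) "right" else "left"
  if (modality == "second") other_side(perceived) else perceived
}

other_side <- function(x) unname(c(left = "right", right = "left")[x])

#' Simulate one full adaptive session
#'
#' Builds the seeded schedule, then runs one independent PSI series per
#' (block x cue condition): each trial's SOA is selected by
#' expected-entropy minimization, the response drawn from the observer's
#' true psychometric function (with report-label complementation in
#' "which second" blocks), and the posterior updated. Responses consume
#' one uniform draw per trial in schedule order, so a session is a pure
#' function of (observer, config, seed).
#'
#' @param observer An [observer_spec()] whose shift map covers the
#'   config's cells.
#' @param config A `toj_config`.
#' @param seed Integer seed for the schedule and the responses.
#' @param grid A [psi_grid()] used by the engine.
#' @return A `toj_session` data frame (the trial log, one row per trial
#'   with `soa` and `response` filled in) with attributes `estimates`
#'   (final per-series PSS/slope), `config`, `seed` and `grid`.
#' @export
simulate_session <- function(observer, config, seed, grid = psi_grid()) {
  stopifnot(inherits(observer, "observer_spec"), inherits(config, "toj_config"))
  sched <- schedule_session(config, seed)
  u <- stats::runif(nrow(sched))
  parts <- psi_cache_parts(grid, config$soa_set, lapse = 0)
  prior <- as.vector(grid$prior)
  blocks <- unique(sched[, c("block", "visual_position", "hand_congruency",
                             "response_modality")])
  est <- vector("list", nrow(blocks) * length(config$cue_conditions))
  k <- 0L
  for (b in seq_len(nrow(blocks))) {
    binfo <- blocks[b, ]
    for (cue in config$cue_conditions) {
      idx <- which(sched$block == binfo$block & sched$cue_condition == cue)
      a <- true_alpha(observer, cue, binfo$visual_position,
                      binfo$hand_congruency)
      p_true <- response_probability(
        config$soa_set,
        psychometric_params(a, observer$beta, observer$lapse))
      res <- run_psi_series_cpp(parts$C1, parts$M1, parts$C0, parts$M0,
                                prior, p_true, u[idx],
                                as.integer(parts$tie_order))
      sched$soa[idx] <- config$soa_set[res$soa_idx]
      perceived <- ifelse(res$response == 1L, "right", "left")
      sched$response[idx] <- if (binfo$response_modality == "second")
        other_side(perceived) else perceived
      fit <- estimate_from_posterior(res$posterior, grid)
      k <- k + 1L
      est[[k]] <- data.frame(
        block = binfo$block,
        visual_position = binfo$visual_position,
        hand_congruency = binfo$hand_congruency,
        response_modality = binfo$response_modality,
        cue_condition = cue,
        pss = fit$alpha, slope = fit$beta,
        n_trials = length(idx),
        stringsAsFactors = FALSE
      )
    }
  }
  attr(sched, "estimates") <- do.call(rbind, est)
  attr(sched, "grid") <- grid
  class(sched) <- c("toj_session", "data.frame")
  sched
}

#' Population-level specification for simulated cohorts
#'
#' The between-participant layer: per-cell mean shifts and standard
#' deviations (Gaussian on the ms scale), an equicorrelation `shift_cor`
#' between a participant's cell shifts (individual differences in overall
#' cueing susceptibility make shifts covary across cells), a log-normal
#' slope distribution (slopes are scale parameters), a shared lapse rate,
#' and a master seed from which every per-participant seed is derived.
#'
#' @param n Number of participants (>= 2).
#' @param shift_mean Named vector of cell-mean shifts (ms).
#' @param shift_sd Named vector (or scalar) of between-participant shift
#'   SDs (ms), `>= 0`.
#' @param shift_cor Common correlation between any two cells' shifts, in
#'   `[0, 1)`.
#' @param beta_mean Median true slope (1/ms).
#' @param beta_log_sd SD of `log(beta)` across participants.
#' @param lapse Shared lapse rate.
#' @param beta_floor Lower truncation for drawn slopes (1/ms).
#' @param seed Master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, shift_mean, shift_sd, shift_cor = 0,
                        beta_mean = 0.1, beta_log_sd = 0.2, lapse = 0.01,
                        beta_floor = 0.005, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be at least 2 participants", call. = FALSE)
  if (is.null(names(shift_mean)))
    stop("`shift_mean` must be named by condition cell", call. = FALSE)
  if (length(shift_sd) == 1L && is.null(names(shift_sd)))
    shift_sd <- stats::setNames(rep(shift_sd, length(shift_mean)),
                                names(shift_mean))
  if (!identical(sort(names(shift_mean)), sort(names(shift_sd))))
    stop("`shift_mean` and `shift_sd` must share cell names", call. = FALSE)
  if (any(shift_sd < 0)) stop("`shift_sd` must be >= 0", call. = FALSE)
  if (shift_cor < 0 || shift_cor >= 1)
    stop("`shift_cor` must lie in [0, 1)", call. = FALSE)
  if (beta_mean <= 0 || beta_log_sd < 0 || beta_floor <= 0)
    stop("slope distribution parameters must be positive", call. = FALSE)
  structure(list(n = as.integer(n), shift_mean = shift_mean,
                 shift_sd = shift_sd[names(shift_mean)],
                 shift_cor = shift_cor,
                 beta_mean = beta_mean, beta_log_sd = beta_log_sd,
                 lapse = lapse, beta_floor = beta_floor,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Cohort specifications at the reported group effects
#'
#' Convenience constructors of [cohort_spec()] objects calibrated to the
#' group-level PSS effects reported for each design. Cell means are the
#' reported means (first design: near 10.95 ms, far 5.34 ms, 17
#' participants; second design: congruent 10.94 ms, incongruent 7.85 ms
#' at both positions, 23 participants). The reported SDs describe
#' *estimated* PSS values and therefore include estimation noise from the
#' 40-trial adaptive fits; the generative SDs used here are deconvolved by
#' subtracting the simulator's own measured estimation-noise variance
#' (about 19 ms^2 for a combined unilateral cell at the default observer
#' parameters) from the squared reported SDs. The reported within-subject
#' near-vs-far contrast further implies strongly covarying cell shifts,
#' encoded as a shared correlation of 0.9. With `null = TRUE` all cell
#' means are set to zero while the between-participant structure is kept,
#' which is the generative null used for type-I-error calibration.
#'
#' @param config A `toj_config` from [exp1_config()] or [exp2_config()].
#' @param n Number of participants; defaults to the design's sample size.
#' @param null Zero out all cell means?
#' @param seed Master seed.
#' @return A `cohort_spec`.
#' @export
reference_cohort <- function(config, n = NULL, null = FALSE, seed = 1L) {
  stopifnot(inherits(config, "toj_config"))
  noise_var <- 19  # measured var of the combined-cell estimate, ms^2
  if (config$experiment == "exp1") {
    mu <- c(near = 10.95, far = 5.34)
    sdv <- sqrt(pmax(c(near = 7.29, far = 6.36)^2 - noise_var, 1))
    if (is.null(n)) n <- 17L
  } else {
    mu <- c(near_congruent = 10.94, far_congruent = 10.94,
            near_incongruent = 7.85, far_incongruent = 7.85)
    sdv <- sqrt(pmax(c(near_congruent = 8.33, far_congruent = 8.33,
                       near_incongruent = 6.64,
                       far_incongruent = 6.64)^2 - noise_var, 1))
    if (is.null(n)) n <- 23L
  }
  mu <- mu[cell_labels(config)]
  sdv <- sdv[cell_labels(config)]
  if (null) mu[] <- 0
  cohort_spec(n = n, shift_mean = mu, shift_sd = sdv, shift_cor = 0.9,
              seed = seed)
}

#' Simulate a cohort of adaptive sessions
#'
#' Draws each participant's cell shifts (Gaussian) and slope (log-normal,
#' truncated below at `beta_floor`) from the cohort distributions, then
#' simulates each full session with a per-participant seed derived from
#' the master seed via `sample.int`. Deterministic given the spec.
#'
#' @param cohort A [cohort_spec()].
#' @param config A `toj_config` whose cells match the cohort's shift
#'   names.
#' @param grid A [psi_grid()].
#' @return A list of `toj_session` logs (one per participant, each with a
#'   `participant` column); the drawn true parameters are attached as
#'   attribute `truth`.
#' @export
simulate_cohort <- function(cohort, config, grid = psi_grid()) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(config, "toj_config"))
  cells <- cell_labels(config)
  if (!all(cells %in% names(cohort$shift_mean)))
    stop("cohort shift map does not cover the config's condition cells",
         call. = FALSE)
  set.seed(cohort$seed)
  seeds <- sample.int(.Machine$integer.max, cohort$n)
  # equicorrelated cell shifts: shared + cell-specific standard normals
  r <- cohort$shift_cor %||% 0
  shared <- stats::rnorm(cohort$n)
  shifts <- vapply(cells, function(cl) {
    z <- sqrt(r) * shared + sqrt(1 - r) * stats::rnorm(cohort$n)
    cohort$shift_mean[[cl]] + cohort$shift_sd[[cl]] * z
  }, numeric(cohort$n))
  shifts <- matrix(shifts, nrow = cohort$n,
                   dimnames = list(NULL, cells))
  betas <- pmax(cohort$beta_floor,
                exp(stats::rnorm(cohort$n, log(cohort$beta_mean),
                                 cohort$beta_log_sd)))
  ids <- sprintf("P%02d", seq_len(cohort$n))
  logs <- vector("list", cohort$n)
  for (i in seq_len(cohort$n)) {
    obs <- observer_spec(shifts = shifts[i, ], beta = betas[i],
                         lapse = cohort$lapse)
    log_i <- simulate_session(obs, config, seeds[i], grid)
    log_i$participant <- ids[i]
    logs[[i]] <- log_i
  }
  names(logs) <- ids
  attr(logs, "truth") <- data.frame(participant = ids, shifts, beta = betas,
                                    lapse = cohort$lapse, seed = seeds)
  attr(logs, "config") <- config
  logs
}
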