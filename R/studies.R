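#' Parameter-recovery study for the adaptive engine
#'
#' Runs independent adaptive series against a fixed generating observer
#' and summarizes how well the posterior-mean PSS recovers the truth at
#' each trial budget: bias, RMSE and median absolute error of
#' `alpha_hat - alpha`.
#'
#' @param trial_counts Trial budgets to probe.
#' @param n_reps Independent series per budget.
#' @param truth Generating [psychometric_params()].
#' @param grid A [psi_grid()].
#' @param soa_set Candidate SOAs; default the 10 SOAs of the first
#'   design.
#' @param lapse_fit Lapse assumed by the engine.
#' @param seed RNG seed.
#' @return Data frame with one row per budget: `trials`, `bias`, `rmse`,
#'   `median_abs_error`.
#' @export
pss_recovery_study <- function(trial_counts = c(20, 80, 320), n_reps = 200,
                               truth = psychometric_params(10, 0.05),
                               grid = psi_grid(),
                               soa_set = exp1_config()$soa_set,
                               lapse_fit = 0, seed = 1L) {
  set.seed(as.integer(seed))
  out <- lapply(trial_counts, function(nt) {
    err <- vapply(seq_len(n_reps), function(i) {
      res <- run_psi_series(truth, nt, grid, soa_set, lapse_fit)
      res$estimate$alpha - truth$alpha
    }, 0)
    data.frame(trials = nt, bias = mean(err), rmse = sqrt(mean(err^2)),
               median_abs_error = stats::median(abs(err)))
  })
  do.call(rbind, out)
}

#' Type-I-error calibration under the generative null
#'
#' Simulates cohorts whose cell-mean shifts are all zero (between-
#' participant variability retained), runs the full analysis pipeline on
#' each, and records how often the one-sample t test of the combined
#' unilateral PSS against zero rejects at `alpha_level`. Under the null
#' the rejection rate should sit at the nominal level.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param config A `toj_config` (default the first design).
#' @param n Participants per cohort (default the design's sample size).
#' @param alpha_level Nominal test level.
#' @param grid A [psi_grid()].
#' @param seed Master seed; per-cohort seeds are derived from it.
#' @return A list: `rate` (rejection rate over all unilateral cells),
#'   `n_tests`, `per_cell` (rates by condition cell), `p_values`.
#' @export
null_calibration_study <- function(n_cohorts = 400, config = exp1_config(),
                                   n = NULL, alpha_level = 0.05,
                                   grid = psi_grid(), seed = 1L) {
  set.seed(as.integer(seed))
  cohort_seeds <- sample.int(.Machine$integer.max, n_cohorts)
  pvals <- list()
  for (i in seq_len(n_cohorts)) {
    cohort <- reference_cohort(config, n = n, null = TRUE,
                               seed = cohort_seeds[i])
    res <- run_toj_analysis(simulate_cohort(cohort, config, grid), grid)
    tt <- res$t_tests
    uni <- if (config$experiment == "exp1")
      tt[grepl("^unilateral", tt$condition), ] else tt
    pvals[[i]] <- data.frame(cohort = i, condition = uni$condition,
                             p = uni$p, stringsAsFactors = FALSE)
  }
  pv <- do.call(rbind, pvals)
  list(rate = mean(pv$p <= alpha_level),
       n_tests = nrow(pv),
       per_cell = tapply(pv$p <= alpha_level, pv$condition, mean),
       p_values = pv)
}

#' Sign recovery of the near/far effect structure
#'
#' Simulates cohorts generated with a larger near-cell than far-cell
#' unilateral shift (the reported group effects) and records, per
#' replicate, whether the recovered mean unilateral near - far PSS
#' difference is positive and whether the cue-by-position interaction
#' contrast of the 2 x 2 ANOVA carries the generating (positive) sign.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param config A `toj_config` (the first design).
#' @param n Participants per cohort.
#' @param grid A [psi_grid()].
#' @param seed Master seed.
#' @return A list: `rate_diff_positive`, `rate_interaction_positive`,
#'   `details` (per-replicate differences and interaction contrasts).
#' @export
effect_recovery_study <- function(n_cohorts = 200, config = exp1_config(),
                                  n = NULL, grid = psi_grid(), seed = 1L) {
  set.seed(as.integer(seed))
  cohort_seeds <- sample.int(.Machine$integer.max, n_cohorts)
  diff_nf <- numeric(n_cohorts)
  inter <- numeric(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    cohort <- reference_cohort(config, n = n, seed = cohort_seeds[i])
    res <- run_toj_analysis(simulate_cohort(cohort, config, grid), grid)
    cvals <- res$cell_values
    near <- cvals$uni_pss[cvals$visual_position == "near"]
    far <- cvals$uni_pss[cvals$visual_position == "far"]
    diff_nf[i] <- mean(near) - mean(far)
    # interaction contrast: (uni near - uni far) - (bil near - bil far)
    bil_near <- cvals$bil_pss[cvals$visual_position == "near"]
    bil_far <- cvals$bil_pss[cvals$visual_position == "far"]
    inter[i] <- mean(near - far) - mean(bil_near - bil_far)
  }
  list(rate_diff_positive = mean(diff_nf > 0),
       rate_interaction_positive = mean(inter > 0),
       details = data.frame(cohort = seq_len(n_cohorts),
                            near_minus_far = diff_nf,
                            interaction_contrast = inter))
}
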