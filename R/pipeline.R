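#' Full analysis battery for a set of TOJ session logs
#'
#' Transforms trial-level session logs into the group-level measures and
#' statistics of the two designs:
#' \enumerate{
#'   \item per participant, condition cell and cue condition, the two
#'     response-modality blocks are pooled ([merge_modalities()]) and the
#'     logistic model refitted in one batch ([fit_condition()]);
#'   \item left- and right-cue PSS values are combined into one unilateral
#'     measure per cell ([combine_unilateral()]); unilateral slopes are
#'     averaged; bilateral cells (first design) are kept in the left/right
#'     frame;
#'   \item each cell's PSS is tested against zero ([one_sample_t()],
#'     Cohen's d);
#'   \item PSS and slope each enter a 2 x 2 repeated-measures ANOVA
#'     ([rm_anova_2x2()]) -- cue condition x position for the first
#'     design, position x hand congruency for the second -- with partial
#'     eta squared and within-participant contrasts;
#'   \item Cousineau within-subject confidence intervals are computed per
#'     cell ([cousineau_ci()]).
#' }
#'
#' @param logs A list of `toj_session` logs (e.g. from
#'   [simulate_cohort()]), one per participant, sharing one
#'   configuration; or a single combined trial data frame with a
#'   `participant` column (then `config` must be supplied).
#' @param grid A [psi_grid()] used for refitting.
#' @param config Configuration override when `logs` is a plain data
#'   frame.
#' @param refit `"pooled"` (default) refits one model on the 2 x 20
#'   pooled trials of a cell x cue; `"average"` instead averages the two
#'   per-block fits.
#' @return A list of class `toj_results`: `experiment`, `n`,
#'   `estimates` (per participant x cell x cue), `cell_values` (per
#'   participant x cell, merged measures), `t_tests`, `anova_pss`,
#'   `anova_slope`, `ci_pss`, `ci_slope`, `config`.
#' @export
run_toj_analysis <- function(logs, grid = psi_grid(), config = NULL,
                             refit = c("pooled", "average")) {
  refit <- match.arg(refit)
  if (is.data.frame(logs)) {
    if (is.null(config))
      stop("supply `config` when `logs` is a plain data frame", call. = FALSE)
    trials <- logs
  } else {
    configs <- lapply(logs, attr, "config")
    if (any(vapply(configs, is.null, TRUE)))
      stop("every session log must carry a config attribute", call. = FALSE)
    if (is.null(config)) config <- configs[[1]]
    same <- vapply(configs, function(cf)
      identical(unclass(cf), unclass(config)), TRUE)
    if (!all(same))
      stop("mixed configs: session logs were produced under different configurations",
           call. = FALSE)
    trials <- do.call(rbind, lapply(logs, as.data.frame))
  }
  if (!"participant" %in% names(trials))
    stop("trials must carry a participant column", call. = FALSE)
  validate_toj_config(config)

  cells <- data.frame(
    visual_position = rep(config$positions,
                          times = length(config$congruency %||% "none")),
    hand_congruency = rep(config$congruency %||% "none",
                          each = length(config$positions)),
    stringsAsFactors = FALSE)
  cells$cell <- cell_label(cells$visual_position, cells$hand_congruency)
  ids <- sort(unique(trials$participant))

  est <- list()
  for (pid in ids) {
    ptr <- trials[trials$participant == pid, ]
    for (ci in seq_len(nrow(cells))) {
      sel_cell <- ptr$visual_position == cells$visual_position[ci] &
        ptr$hand_congruency == cells$hand_congruency[ci]
      for (cue in config$cue_conditions) {
        sub <- ptr[sel_cell & ptr$cue_condition == cue, ]
        if (nrow(sub) == 0L)
          stop(sprintf("no trials for participant %s, cell %s, cue %s",
                       pid, cells$cell[ci], cue), call. = FALSE)
        if (refit == "pooled") {
          fit <- fit_condition(merge_modalities(sub), grid)
          pss <- fit$pss; slope <- fit$slope; ntr <- fit$n_trials
        } else {
          per_block <- lapply(split(sub, sub$response_modality), function(d)
            fit_condition(merge_modalities_quiet(d), grid))
          pss <- mean(vapply(per_block, `[[`, 0, "pss"))
          slope <- mean(vapply(per_block, `[[`, 0, "slope"))
          ntr <- nrow(sub)
        }
        est[[length(est) + 1L]] <- data.frame(
          participant = pid, cell = cells$cell[ci],
          visual_position = cells$visual_position[ci],
          hand_congruency = cells$hand_congruency[ci],
          cue_condition = cue, pss = pss, slope = slope, n_trials = ntr,
          stringsAsFactors = FALSE)
      }
    }
  }
  estimates <- do.call(rbind, est)

  cv <- list()
  for (pid in ids) {
    for (ci in seq_len(nrow(cells))) {
      e <- estimates[estimates$participant == pid &
                       estimates$cell == cells$cell[ci], ]
      row <- data.frame(
        participant = pid, cell = cells$cell[ci],
        visual_position = cells$visual_position[ci],
        hand_congruency = cells$hand_congruency[ci],
        uni_pss = combine_unilateral(e$pss[e$cue_condition == "left"],
                                     e$pss[e$cue_condition == "right"]),
        uni_slope = mean(e$slope[e$cue_condition %in% c("left", "right")]),
        stringsAsFactors = FALSE)
      if ("bilateral" %in% config$cue_conditions) {
        row$bil_pss <- e$pss[e$cue_condition == "bilateral"]
        row$bil_slope <- e$slope[e$cue_condition == "bilateral"]
      }
      cv[[length(cv) + 1L]] <- row
    }
  }
  cell_values <- do.call(rbind, cv)

  exp1 <- "bilateral" %in% config$cue_conditions
  if (exp1) {
    long_pss <- rbind(
      data.frame(participant = cell_values$participant,
                 cue_type = "unilateral",
                 visual_position = cell_values$visual_position,
                 value = cell_values$uni_pss, stringsAsFactors = FALSE),
      data.frame(participant = cell_values$participant,
                 cue_type = "bilateral",
                 visual_position = cell_values$visual_position,
                 value = cell_values$bil_pss, stringsAsFactors = FALSE))
    long_slope <- rbind(
      data.frame(participant = cell_values$participant,
                 cue_type = "unilateral",
                 visual_position = cell_values$visual_position,
                 value = cell_values$uni_slope, stringsAsFactors = FALSE),
      data.frame(participant = cell_values$participant,
                 cue_type = "bilateral",
                 visual_position = cell_values$visual_position,
                 value = cell_values$bil_slope, stringsAsFactors = FALSE))
    factors <- c("cue_type", "visual_position")
    cond_of <- function(d) paste(d$cue_type, d$visual_position)
  } else {
    long_pss <- data.frame(participant = cell_values$participant,
                           hand_congruency = cell_values$hand_congruency,
                           visual_position = cell_values$visual_position,
                           value = cell_values$uni_pss,
                           stringsAsFactors = FALSE)
    long_slope <- data.frame(participant = cell_values$participant,
                             hand_congruency = cell_values$hand_congruency,
                             visual_position = cell_values$visual_position,
                             value = cell_values$uni_slope,
                             stringsAsFactors = FALSE)
    factors <- c("visual_position", "hand_congruency")
    cond_of <- function(d) paste(d$visual_position, d$hand_congruency)
  }

  long_pss$condition <- cond_of(long_pss)
  long_slope$condition <- cond_of(long_slope)

  tt <- lapply(split(long_pss, long_pss$condition), function(d) {
    res <- one_sample_t(d$value)
    data.frame(condition = d$condition[1], mean = res$mean, sd = res$sd,
               t = res$t, df = res$df, p = res$p, cohens_d = res$cohens_d,
               degenerate = res$degenerate, stringsAsFactors = FALSE)
  })
  t_tests <- do.call(rbind, c(tt, make.row.names = FALSE))

  anova_pss <- rm_anova_2x2(long_pss, dv = "value", id = "participant",
                            factors = factors)
  anova_slope <- rm_anova_2x2(long_slope, dv = "value", id = "participant",
                              factors = factors)

  to_matrix <- function(long) {
    tapply(long$value, list(long$participant, long$condition), mean)
  }
  ci_pss <- cousineau_ci(to_matrix(long_pss))
  ci_slope <- cousineau_ci(to_matrix(long_slope))

  structure(list(experiment = config$experiment, n = length(ids),
                 estimates = estimates, cell_values = cell_values,
                 t_tests = t_tests, anova_pss = anova_pss,
                 anova_slope = anova_slope, ci_pss = ci_pss,
                 ci_slope = ci_slope, config = config, refit = refit),
            class = "toj_results")
}

merge_modalities_quiet <- function(trials)
  suppressWarnings(merge_modalities(trials))

#' @export
print.toj_results <- function(x, ...) {
  cat(sprintf("TOJ analysis (%s, n = %d participants, refit = %s)\n\n",
              x$experiment, x$n, x$refit))
  cat("PSS vs 0 (ms):\n")
  for (i in seq_len(nrow(x$t_tests))) {
    r <- x$t_tests[i, ]
    if (isTRUE(r$degenerate)) {
      cat(sprintf("  %s: degenerate (zero variance), mean = %.2f\n",
                  r$condition, r$mean))
    } else {
      cat(sprintf("  %s: M = %.2f, SD = %.2f, t(%d) = %.2f, p = %.4g, d = %.2f\n",
                  r$condition, r$mean, r$sd, r$df, r$t, r$p, r$cohens_d))
    }
  }
  cat("\nANOVA on PSS:\n")
  print(x$anova_pss)
  cat("\nANOVA on slope:\n")
  print(x$anova_slope)
  invisible(x)
}

#' Serialize an analysis bundle to JSON
#'
#' Writes every statistic of a [run_toj_analysis()] bundle (estimates,
#' merged cell values, t tests, ANOVA tables, contrasts, confidence
#' intervals) at full precision.
#'
#' @param results A `toj_results` object.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
results_to_json <- function(results, path = NULL) {
  stopifnot(inherits(results, "toj_results"))
  obj <- list(
    experiment = results$experiment,
    n = results$n,
    refit = results$refit,
    estimates = results$estimates,
    cell_values = results$cell_values,
    t_tests = results$t_tests,
    anova_pss = list(table = results$anova_pss$table,
                     contrasts = results$anova_pss$contrasts),
    anova_slope = list(table = results$anova_slope$table,
                       contrasts = results$anova_slope$contrasts),
    ci_pss = results$ci_pss,
    ci_slope = results$ci_slope
  )
  txt <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                          dataframe = "rows")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}
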