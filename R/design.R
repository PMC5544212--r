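#' Experiment configurations for the two TOJ designs
#'
#' `exp1_config()` encodes the first design: 10 SOAs
#' (+/-200, +/-90, +/-55, +/-30, +/-10 ms; negative = left stimulus first),
#' three nociceptive cue conditions (unilateral left, unilateral right,
#' bilateral), and four blocks crossing visual stimulus position (near/far
#' from the trunk) with response modality ("which first" / "which second").
#' Each block runs one 20-trial adaptive series per cue condition,
#' randomly interleaved, for 4 x 3 x 20 = 240 trials.
#'
#' `exp2_config()` encodes the second design: 20 SOAs
#' (+/-200, +/-145, +/-90, +/-75, +/-60, +/-45, +/-30, +/-15, +/-10, +/-5 ms),
#' two cue conditions (unilateral left/right, no bilateral cue), and eight
#' blocks crossing position, hand congruency (hands next to the judged
#' pair or the other pair) and response modality, for 8 x 2 x 20 = 320
#' trials.
#'
#' Timing fields (500 ms fixation lead, 200 ms cue-to-target interval,
#' 2000 ms inter-trial interval) are carried as metadata; the simulator is
#' not a real-time engine.
#'
#' @return An object of class `toj_config`.
#' @examples
#' cfg <- exp1_config()
#' n_session_trials(cfg)  # 240
#' @export
exp1_config <- function() {
  new_toj_config(
    experiment = "exp1",
    soa_set = sort(c(-1, 1) %o% c(200, 90, 55, 30, 10)),
    cue_conditions = c("left", "right", "bilateral"),
    positions = c("near", "far"),
    modalities = c("first", "second"),
    congruency = NULL,
    trials_per_series = 20L,
    cue_to_target_ms = 200,
    fixation_lead_ms = 500,
    inter_trial_ms = 2000
  )
}

#' @rdname exp1_config
#' @export
exp2_config <- function() {
  new_toj_config(
    experiment = "exp2",
    soa_set = sort(c(-1, 1) %o% c(200, 145, 90, 75, 60, 45, 30, 15, 10, 5)),
    cue_conditions = c("left", "right"),
    positions = c("near", "far"),
    modalities = c("first", "second"),
    congruency = c("congruent", "incongruent"),
    trials_per_series = 20L,
    cue_to_target_ms = 200,
    fixation_lead_ms = 500,
    inter_trial_ms = 2000
  )
}

new_toj_config <- function(experiment, soa_set, cue_conditions, positions,
                           modalities, congruency, trials_per_series,
                           cue_to_target_ms, fixation_lead_ms,
                           inter_trial_ms) {
  cfg <- structure(list(
    experiment = experiment,
    soa_set = as.numeric(soa_set),
    cue_conditions = cue_conditions,
    positions = positions,
    modalities = modalities,
    congruency = congruency,
    trials_per_series = as.integer(trials_per_series),
    cue_to_target_ms = cue_to_target_ms,
    fixation_lead_ms = fixation_lead_ms,
    inter_trial_ms = inter_trial_ms
  ), class = "toj_config")
  validate_toj_config(cfg)
}

validate_toj_config <- function(cfg) {
  soa <- sort(cfg$soa_set)
  if (length(soa) == 0L || any(!is.finite(soa)))
    stop("config field `soa_set`: must be non-empty and finite", call. = FALSE)
  if (any(soa == 0))
    stop("config field `soa_set`: must exclude 0", call. = FALSE)
  if (!isTRUE(all.equal(soa, -rev(soa))))
    stop("config field `soa_set`: must be symmetric about 0", call. = FALSE)
  if (anyDuplicated(soa))
    stop("config field `soa_set`: must not contain duplicates", call. = FALSE)
  if (!is.integer(cfg$trials_per_series) || cfg$trials_per_series <= 0L)
    stop("config field `trials_per_series`: must be a positive integer",
         call. = FALSE)
  if (length(cfg$cue_conditions) == 0L ||
      !all(cfg$cue_conditions %in% c("left", "right", "bilateral")))
    stop("config field `cue_conditions`: must be drawn from left/right/bilateral",
         call. = FALSE)
  if (!identical(cfg$positions, c("near", "far")))
    stop("config field `positions`: must be c('near', 'far')", call. = FALSE)
  if (!identical(cfg$modalities, c("first", "second")))
    stop("config field `modalities`: must be c('first', 'second')",
         call. = FALSE)
  if (!is.null(cfg$congruency) &&
      !identical(cfg$congruency, c("congruent", "incongruent")))
    stop("config field `congruency`: must be NULL or c('congruent', 'incongruent')",
         call. = FALSE)
  for (f in c("cue_to_target_ms", "fixation_lead_ms", "inter_trial_ms"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop(sprintf("config field `%s`: must be a single non-negative number", f),
           call. = FALSE)
  cfg
}

#' @export
print.toj_config <- function(x, ...) {
  cat(sprintf("toj_config '%s': %d SOAs, %d cue conditions, %d blocks, %d trials/series (%d per session)\n",
              x$experiment, length(x$soa_set), length(x$cue_conditions),
              nrow(block_table(x)), x$trials_per_series, n_session_trials(x)))
  invisible(x)
}

#' Block structure and session size of a configuration
#'
#' `block_table()` lists one row per block: the crossing of visual position
#' and response modality (and hand congruency when the design includes it),
#' with a compact block id. `n_session_trials()` is the total number of
#' trials a session comprises (blocks x cue conditions x trials per
#' series).
#'
#' @param config A `toj_config`.
#' @return A data frame (`block_table`) or an integer
#'   (`n_session_trials`).
#' @export
block_table <- function(config) {
  stopifnot(inherits(config, "toj_config"))
  if (is.null(config$congruency)) {
    tab <- expand.grid(visual_position = config$positions,
                       response_modality = config$modalities,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab$hand_congruency <- "none"
  } else {
    tab <- expand.grid(visual_position = config$positions,
                       hand_congruency = config$congruency,
                       response_modality = config$modalities,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  tab <- tab[, c("visual_position", "hand_congruency", "response_modality")]
  tab$block <- ifelse(tab$hand_congruency == "none",
                      paste(tab$visual_position, tab$response_modality, sep = "_"),
                      paste(tab$visual_position, tab$hand_congruency,
                            tab$response_modality, sep = "_"))
  tab
}

#' @rdname block_table
#' @export
n_session_trials <- function(config) {
  stopifnot(inherits(config, "toj_config"))
  nrow(block_table(config)) * length(config$cue_conditions) *
    config$trials_per_series
}

#' Seeded trial schedule for one session
#'
#' Produces the runnable skeleton of a session: blocks in a seeded random
#' order and, within each block, the cue conditions randomly and
#' equiprobably interleaved (each appearing exactly `trials_per_series`
#' times). SOAs and responses are left unassigned -- they are filled online
#' by the PSI engine, one independent series per (block x cue condition).
#'
#' @param config A `toj_config`.
#' @param seed Integer RNG seed; the same seed reproduces the schedule
#'   exactly.
#' @return A data frame with one row per trial: `trial` (global index),
#'   `block`, `block_index`, `visual_position`, `hand_congruency`,
#'   `response_modality`, `cue_condition`, `soa` (NA), `response` (NA).
#' @export
schedule_session <- function(config, seed) {
  stopifnot(inherits(config, "toj_config"))
  if (length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  set.seed(as.integer(seed))
  blocks <- block_table(config)
  blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
  per_block <- length(config$cue_conditions) * config$trials_per_series
  cue_seq <- unlist(lapply(seq_len(nrow(blocks)), function(i)
    sample(rep(config$cue_conditions, each = config$trials_per_series))))
  n <- nrow(blocks) * per_block
  sched <- data.frame(
    trial = seq_len(n),
    block = rep(blocks$block, each = per_block),
    block_index = rep(seq_len(nrow(blocks)), each = per_block),
    visual_position = rep(blocks$visual_position, each = per_block),
    hand_congruency = rep(blocks$hand_congruency, each = per_block),
    response_modality = rep(blocks$response_modality, each = per_block),
    cue_condition = cue_seq,
    soa = NA_real_,
    response = NA_character_,
    stringsAsFactors = FALSE
  )
  attr(sched, "config") <- config
  attr(sched, "seed") <- as.integer(seed)
  sched
}
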