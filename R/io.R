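#' Read and write session logs as annotated CSV
#'
#' Session logs are plain UTF-8 comma-separated files, one trial per row,
#' with the SOA stored only in the left/right frame (negative = left
#' stimulus first) -- other frames are derived at analysis time. A header
#' of `#`-prefixed comment lines records the seed, the experiment id, the
#' package version and the grid settings that produced the log.
#'
#' @param log A `toj_session` data frame (see [simulate_session()]).
#' @param path File path.
#' @return `write_session_log` returns `path` invisibly;
#'   `read_session_log` returns the trials data frame with `seed` and
#'   `experiment` attributes restored.
#' @export
write_session_log <- function(log, path) {
  cfg <- attr(log, "config")
  grid <- attr(log, "grid")
  header <- c(
    "# tojpsi session log",
    sprintf("# seed: %s", attr(log, "seed") %||% NA),
    sprintf("# experiment: %s", cfg$experiment %||% NA),
    sprintf("# package_version: %s", as.character(utils::packageVersion("tojpsi"))),
    if (!is.null(grid))
      sprintf("# grid_alpha: %g..%g (%d steps); grid_beta: %g..%g (%d log steps)",
              min(grid$alpha), max(grid$alpha), length(grid$alpha),
              min(grid$beta), max(grid$beta), length(grid$beta))
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(log), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^#", lines)
  dat <- utils::read.csv(text = paste(lines[!is_comment], collapse = "\n"),
                         stringsAsFactors = FALSE)
  required <- c("trial", "block", "visual_position", "hand_congruency",
                "response_modality", "cue_condition", "soa", "response")
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0)
    stop(sprintf("schema error in '%s': missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(!dat$response %in% c("left", "right"))
  if (length(bad) > 0)
    stop(sprintf("malformed response in '%s' at data row %d", path, bad[1]),
         call. = FALSE)
  get_field <- function(key) {
    ln <- grep(sprintf("^# %s:", key), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  attr(dat, "seed") <- suppressWarnings(as.integer(get_field("seed")))
  attr(dat, "experiment") <- get_field("experiment")
  dat
}

#' Read and write experiment configurations
#'
#' Configurations serialize to JSON (or YAML when the `yaml` package is
#' available and the file extension is `.yml`/`.yaml`). Reading validates
#' every field and reports the offending field by name.
#'
#' @param config A `toj_config`.
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a validated `toj_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "toj_config"))
  obj <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to write YAML configs", call. = FALSE)
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  need <- c("experiment", "soa_set", "cue_conditions", "positions",
            "modalities", "trials_per_series", "cue_to_target_ms",
            "fixation_lead_ms", "inter_trial_ms")
  missing <- setdiff(need, names(obj))
  if (length(missing) > 0)
    stop(sprintf("invalid config '%s': missing field(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  congruency <- obj$congruency
  if (!is.null(congruency) && (length(congruency) == 0 ||
                               all(is.na(congruency))))
    congruency <- NULL
  new_toj_config(
    experiment = obj$experiment,
    soa_set = as.numeric(obj$soa_set),
    cue_conditions = as.character(obj$cue_conditions),
    positions = as.character(obj$positions),
    modalities = as.character(obj$modalities),
    congruency = congruency,
    trials_per_series = as.integer(obj$trials_per_series),
    cue_to_target_ms = obj$cue_to_target_ms,
    fixation_lead_ms = obj$fixation_lead_ms,
    inter_trial_ms = obj$inter_trial_ms
  )
}

#' Simulate a cohort and write its session logs to disk
#'
#' Runs [simulate_cohort()] and writes one CSV per participant plus a
#' `manifest.json` recording the seed, the configuration, the grid
#' settings, the package version, the creation time and every output
#' file. All randomness flows from the cohort's master seed.
#'
#' @param config A `toj_config`.
#' @param cohort A [cohort_spec()]; its cells must cover the config's.
#' @param outdir Output directory (created if needed).
#' @param grid A [psi_grid()].
#' @return The manifest, invisibly.
#' @export
simulate_study <- function(config, cohort, outdir, grid = psi_grid()) {
  stopifnot(inherits(config, "toj_config"), inherits(cohort, "cohort_spec"))
  if (cohort$n < 1) stop("cohort must contain at least one participant",
                         call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logs <- simulate_cohort(cohort, config, grid)
  files <- character(length(logs))
  for (i in seq_along(logs)) {
    files[i] <- file.path(outdir, sprintf("%s.csv", names(logs)[i]))
    write_session_log(logs[[i]], files[i])
  }
  config_path <- file.path(outdir, "config.json")
  write_config(config, config_path)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("tojpsi")),
    seed = cohort$seed,
    experiment = config$experiment,
    n_participants = cohort$n,
    grid = list(alpha = range(grid$alpha), n_alpha = length(grid$alpha),
                beta = range(grid$beta), n_beta = length(grid$beta)),
    config_file = config_path,
    session_logs = files
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Analyze session logs from disk
#'
#' Reads a directory (or explicit vector) of session-log CSVs, checks
#' that they share one experiment, runs [run_toj_analysis()] and writes
#' `results.json` (all statistics at full precision),
#' `condition_estimates.csv` and a human-readable `report.txt`.
#'
#' @param paths A directory containing `P*.csv` logs, or a character
#'   vector of log files.
#' @param config The `toj_config` the logs were produced under.
#' @param outdir Output directory (created if needed).
#' @param grid A [psi_grid()].
#' @return The `toj_results` bundle, invisibly.
#' @export
analyze_study <- function(paths, config, outdir, grid = psi_grid()) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "^P.*\\.csv$",
                             full.names = TRUE))
  if (length(paths) == 0L) stop("no session logs found", call. = FALSE)
  logs <- lapply(paths, read_session_log)
  exps <- unique(vapply(logs, function(l)
    attr(l, "experiment") %||% NA_character_, ""))
  if (length(exps) > 1)
    stop("mixed configs: logs come from different experiments", call. = FALSE)
  trials <- do.call(rbind, lapply(seq_along(logs), function(i) {
    d <- logs[[i]]
    if (!"participant" %in% names(d))
      d$participant <- sub("\\.csv$", "", basename(paths[i]))
    d
  }))
  results <- run_toj_analysis(trials, grid = grid, config = config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results_to_json(results, file.path(outdir, "results.json"))
  utils::write.csv(results$estimates,
                   file.path(outdir, "condition_estimates.csv"),
                   row.names = FALSE)
  writeLines(utils::capture.output(print(results)),
             file.path(outdir, "report.txt"))
  invisible(results)
}
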