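#' Remap unilateral-cue trials from the left/right to the cued/uncued frame
#'
#' In the cued/uncued frame a negative SOA means the cued-side stimulus
#' was presented first. Left-cue trials already satisfy this (cued =
#' left), so they pass through; right-cue trials have their SOA sign
#' flipped and their report labels mirrored. After the remap the label
#' `"left"` plays the role of the cued side. Applying the remap twice
#' restores the original right-cue trials (it is an involution on the SOA
#' and response columns). Bilateral trials have no cued side and are
#' rejected.
#'
#' @param trials Data frame of unilateral-cue trials with columns
#'   `cue_condition`, `soa`, `response` (and `response_first` if already
#'   merged).
#' @return The trials with transformed `soa`/`response` columns and an
#'   attribute `frame` toggling between `"leftright"` and `"cued"`.
#' @export
remap_to_cue_frame <- function(trials) {
  need <- c("cue_condition", "soa", "response")
  if (!all(need %in% names(trials)))
    stop("trials must contain cue_condition, soa and response columns",
         call. = FALSE)
  if (any(trials$cue_condition == "bilateral"))
    stop("bilateral trials have no cued side; remove them before remapping",
         call. = FALSE)
  right <- trials$cue_condition == "right"
  trials$soa[right] <- -trials$soa[right]
  trials$response[right] <- other_side(trials$response[right])
  if ("response_first" %in% names(trials))
    trials$response_first[right] <- other_side(trials$response_first[right])
  frame <- attr(trials, "frame") %||% "leftright"
  attr(trials, "frame") <- if (frame == "cued") "leftright" else "cued"
  trials
}

#' Merge the two response modalities into first-judgment responses
#'
#' "Which second" reports are converted to the implied first judgments
#' (the side reported second implies the other side was perceived first)
#' and pooled with the "which first" trials; pooling the two modalities
#' dilutes response biases tied to a particular report rule. The output
#' keeps every input row and adds a `response_first` column; data already
#' coded as first judgments pass through unchanged, so the operation is
#' idempotent.
#'
#' @param trials Data frame with `response` and `response_modality`
#'   columns.
#' @return The trials with a `response_first` column.
#' @export
merge_modalities <- function(trials) {
  if (!all(c("response", "response_modality") %in% names(trials)))
    stop("trials must contain response and response_modality columns",
         call. = FALSE)
  if (!all(trials$response %in% c("left", "right")))
    stop("responses must be 'left' or 'right'", call. = FALSE)
  present <- unique(trials$response_modality)
  if (!all(c("first", "second") %in% present)) {
    warning("only one response modality present; proceeding on available data")
    attr(trials, "single_modality") <- TRUE
  }
  trials$response_first <- ifelse(trials$response_modality == "second",
                                  other_side(trials$response),
                                  trials$response)
  trials
}

#' Batch psychometric fit of one condition's pooled trials
#'
#' Updates the PSI posterior over the full parameter grid with all pooled
#' trials in a single batch (the product of Bernoulli likelihoods, so the
#' result is order-independent and identical to sequential updating) and
#' returns the posterior-mean PSS and slope. Fitting is done in the
#' left/right frame with the response coded as "right perceived first";
#' the lapse is held at the engine's fixed value.
#'
#' @param trials Data frame with `soa` and `response_first` columns (run
#'   [merge_modalities()] first), at least 10 trials spanning at least 3
#'   distinct SOAs.
#' @param grid A [psi_grid()].
#' @param lapse Fixed lapse of the fitted model (default 0).
#' @return A list of class `condition_estimate`: `pss` (ms), `slope`
#'   (1/ms), `n_trials`, `boundary` (TRUE when every response was
#'   identical, i.e. the fit sits against the data's boundary).
#' @export
fit_condition <- function(trials, grid = psi_grid(), lapse = 0) {
  if (!all(c("soa", "response_first") %in% names(trials)))
    stop("trials must contain soa and response_first columns (merge modalities first)",
         call. = FALSE)
  n <- nrow(trials)
  if (n < 10L) stop("need at least 10 trials to fit a condition", call. = FALSE)
  soa_set <- sort(unique(trials$soa))
  if (length(soa_set) < 3L)
    stop("need at least 3 distinct SOAs to fit a condition", call. = FALSE)
  r <- as.integer(trials$response_first == "right")
  s_idx <- match(trials$soa, soa_set)
  n1 <- vapply(seq_along(soa_set), function(s) sum(r[s_idx == s]), 0L)
  n0 <- tabulate(s_idx, length(soa_set)) - n1
  pair <- psi_cache_pair(grid, soa_set, lapse)
  lp <- log(as.vector(grid$prior)) +
    as.vector(log(pair$C1) %*% n1 + log(pair$C0) %*% n0)
  lp <- lp - max(lp)
  post <- exp(lp)
  post <- post / sum(post)
  est <- estimate_from_posterior(post, grid, lapse)
  boundary <- length(unique(r)) == 1L
  if (boundary)
    warning("all pooled responses are identical; estimate flagged as boundary")
  structure(list(pss = est$alpha, slope = est$beta, n_trials = n,
                 boundary = boundary),
            class = "condition_estimate")
}

#' Combine left- and right-cue PSS values into one unilateral measure
#'
#' The unilateral-cue PSS of a cell is the average of the left-cue PSS and
#' the sign-flipped right-cue PSS (both in the left/right frame):
#' `(pss_left_cue - pss_right_cue) / 2`. With mirror-symmetric cue
#' effects (+a, -a) this returns `+a`, the prioritization of the cued
#' side in ms.
#'
#' @param pss_left_cue,pss_right_cue PSS values (ms) fitted from the
#'   left-cue and right-cue series of the same cell.
#' @return Combined unilateral PSS (ms); positive = cued side
#'   prioritized.
#' @export
combine_unilateral <- function(pss_left_cue, pss_right_cue) {
  (pss_left_cue - pss_right_cue) / 2
}
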