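#' Parameters of the logistic psychometric function
#'
#' Bundle of the parameters describing one condition's temporal order
#' judgment (TOJ) performance: `alpha`, the threshold of the logistic in ms
#' (for a TOJ this is the point of subjective simultaneity, PSS), `beta`,
#' the slope in 1/ms, and an optional symmetric lapse rate.
#'
#' The core model is \deqn{f(x) = \frac{1}{1 + e^{-\beta (x - \alpha)}}}
#' with `x` the stimulus onset asynchrony (SOA) in ms. The lapse rate
#' extends the model to \eqn{\psi(x) = \lambda + (1 - 2\lambda) f(x)}, which
#' allows simulated observers to make occasional stimulus-independent
#' errors; fitting keeps `lapse = 0` so that estimates stay on the
#' two-parameter logistic.
#'
#' @param alpha Threshold / PSS in ms. Must be finite.
#' @param beta Slope in 1/ms. Must be strictly positive. Note that the
#'   derivative of the lapse-free curve at the PSS is `beta / 4`.
#' @param lapse Symmetric lapse rate in `[0, 0.5)`. Default 0.
#' @return An object of class `psychometric_params`.
#' @examples
#' p <- psychometric_params(alpha = 10, beta = 0.05)
#' response_probability(10, p)  # 0.5 at the PSS
#' jnd(p)                       # log(3) / beta
#' @seealso [response_probability()], [trial_likelihood()], [jnd()]
#' @export
psychometric_params <- function(alpha, beta, lapse = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("`alpha` must be a single finite number (ms)", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive number (1/ms)", call. = FALSE)
  if (!is.numeric(lapse) || length(lapse) != 1L || !is.finite(lapse) ||
      lapse < 0 || lapse >= 0.5)
    stop("`lapse` must lie in [0, 0.5)", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, lapse = lapse),
            class = "psychometric_params")
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf("psychometric_params: alpha (PSS) = %.3f ms, beta (slope) = %.5f 1/ms, lapse = %.3f\n",
              x$alpha, x$beta, x$lapse))
  invisible(x)
}

#' Probability of the reference response at a given SOA
#'
#' Evaluates the (lapse-extended) logistic psychometric function
#' \eqn{\psi(x) = \lambda + (1 - 2\lambda) / (1 + e^{-\beta(x - \alpha)})}.
#' In the left/right SOA frame used throughout the package (negative SOA =
#' left stimulus first), `psi(x)` is the probability that the *right*
#' stimulus is judged to have appeared first.
#'
#' @param soa SOA value(s) in ms; must be finite.
#' @param params A [psychometric_params()] object.
#' @return Probabilities in `(lapse, 1 - lapse)`, same length as `soa`.
#' @export
response_probability <- function(soa, params) {
  if (!inherits(params, "psychometric_params"))
    stop("`params` must be a psychometric_params object", call. = FALSE)
  if (!is.numeric(soa) || length(soa) == 0L || any(!is.finite(soa)))
    stop("`soa` must be finite (ms)", call. = FALSE)
  params$lapse + (1 - 2 * params$lapse) *
    stats::plogis(params$beta * (soa - params$alpha))
}

#' Bernoulli likelihood of one TOJ trial
#'
#' Likelihood of a binary first-judgment: `psi(soa)` when the reference
#' ("right first") response was given (`response = 1`), `1 - psi(soa)`
#' otherwise. The two branches sum to one.
#'
#' @param response 0/1 (or logical) response(s); 1 = reference stimulus
#'   judged first.
#' @param soa SOA value(s) in ms.
#' @param params A [psychometric_params()] object.
#' @return Likelihood value(s).
#' @export
trial_likelihood <- function(response, soa, params) {
  if (length(response) == 0L || !all(response %in% c(0, 1)))
    stop("`response` must be 0/1", call. = FALSE)
  p <- response_probability(soa, params)
  ifelse(response == 1, p, 1 - p)
}

#' Just noticeable difference of the logistic model
#'
#' The SOA distance between the 50% point (the PSS) and the 75% point of
#' the lapse-free logistic: `log(3) / beta`, in ms.
#'
#' @param params A [psychometric_params()] object with `lapse = 0`.
#' @return JND in ms.
#' @export
jnd <- function(params) {
  if (!inherits(params, "psychometric_params"))
    stop("`params` must be a psychometric_params object", call. = FALSE)
  if (params$lapse != 0)
    stop("the JND is defined on the underlying lapse-free logistic; set lapse = 0",
         call. = FALSE)
  log(3) / params$beta
}
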