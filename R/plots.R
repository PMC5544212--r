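utils::globalVariables(c("cell", "lower", "upper", "soa", "p", "pss"))

#' Plot cell means with Cousineau within-subject confidence intervals
#'
#' Bar panel of the per-cell mean PSS (or slope) with the within-subject
#' 95% intervals from [cousineau_ci()], in the style of a group-results
#' figure. Requires ggplot2.
#'
#' @param results A `toj_results` bundle.
#' @param measure `"pss"` or `"slope"`.
#' @return A ggplot object.
#' @export
plot_cell_means <- function(results, measure = c("pss", "slope")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  measure <- match.arg(measure)
  ci <- if (measure == "pss") results$ci_pss else results$ci_slope
  ggplot2::ggplot(ci, ggplot2::aes(x = cell, y = mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lower, ymax = upper),
                           width = 0.15) +
    ggplot2::labs(x = NULL,
                  y = if (measure == "pss") "PSS (ms)" else "slope (1/ms)") +
    ggplot2::theme_classic()
}

#' Plot group-level fitted psychometric curves
#'
#' Draws the logistic curve implied by the group-mean unilateral PSS and
#' slope of each condition cell, with dashed verticals at the PSS values.
#'
#' @param results A `toj_results` bundle.
#' @param soa_range SOA range (ms) to draw over.
#' @return A ggplot object.
#' @export
plot_psychometric_curves <- function(results, soa_range = c(-200, 200)) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  cv <- results$cell_values
  agg <- do.call(rbind, lapply(split(cv, cv$cell), function(d)
    data.frame(cell = d$cell[1], pss = mean(d$uni_pss),
               slope = mean(d$uni_slope))))
  x <- seq(soa_range[1], soa_range[2], length.out = 201)
  curves <- do.call(rbind, lapply(seq_len(nrow(agg)), function(i)
    data.frame(cell = agg$cell[i], soa = x,
               p = stats::plogis(agg$slope[i] * (x - agg$pss[i])))))
  ggplot2::ggplot(curves, ggplot2::aes(x = soa, y = p, colour = cell)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = agg,
                        ggplot2::aes(xintercept = pss, colour = cell),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey60",
                        linewidth = 0.3) +
    ggplot2::labs(x = "SOA (ms)", y = "p(judged first)") +
    ggplot2::theme_classic()
}
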