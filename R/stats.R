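#' Cohen's d from a one-sample t statistic
#'
#' For a one-sample design, `d = mean/SD = t/sqrt(n)`.
#'
#' @param t t statistic.
#' @param n Sample size.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the repeated-measures effect
#' size `SS_effect / (SS_effect + SS_error)`.
#'
#' @param f F statistic.
#' @param df1 Numerator degrees of freedom.
#' @param df2 Denominator (error) degrees of freedom.
#' @return Partial eta squared.
#' @export
partial_eta_squared <- function(f, df1, df2) (f * df1) / (f * df1 + df2)

#' One-sample t test against zero
#'
#' Classical two-sided one-sample t test with Cohen's d. Zero-variance
#' input is returned as a flagged degenerate result rather than an error.
#'
#' @param values Numeric vector of per-participant values (n >= 2).
#' @param mu Null value (default 0).
#' @return A list of class `toj_ttest`: `t`, `df`, `p`, `cohens_d`,
#'   `mean`, `sd`, `n`, `degenerate`.
#' @export
one_sample_t <- function(values, mu = 0) {
  if (!is.numeric(values) || length(values) < 2L || any(!is.finite(values)))
    stop("`values` must be >= 2 finite numbers", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    return(structure(list(t = NA_real_, df = n - 1L, p = NA_real_,
                          cohens_d = NA_real_, mean = m, sd = s, n = n,
                          degenerate = TRUE), class = "toj_ttest"))
  }
  t <- (m - mu) / (s / sqrt(n))
  structure(list(t = t, df = n - 1L,
                 p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
                 cohens_d = (m - mu) / s, mean = m, sd = s, n = n,
                 degenerate = FALSE),
            class = "toj_ttest")
}

#' @export
print.toj_ttest <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("one-sample t: degenerate (zero variance), mean = %.3f, n = %d\n",
                x$mean, x$n))
  } else {
    cat(sprintf("t(%d) = %.2f, p = %.4g, d = %.2f (mean = %.3f, sd = %.3f, n = %d)\n",
                x$df, x$t, x$p, x$cohens_d, x$mean, x$sd, x$n))
  }
  invisible(x)
}

#' Two-way fully within-participant ANOVA (2 x 2)
#'
#' Repeated-measures ANOVA computed from sums of squares: each effect is
#' tested against its own effect-by-participant interaction. Partial eta
#' squared is reported per effect; with two levels per factor sphericity
#' is trivially satisfied, so the Greenhouse-Geisser epsilon is 1 and the
#' correction is vacuous (reported as such). Contrast rows test one factor
#' at each level of the other as 1-df within-participant F tests (the
#' squared paired t on the difference scores).
#'
#' @param data Long data frame with one row per participant x cell.
#' @param dv Name of the value column.
#' @param id Name of the participant column.
#' @param factors Character vector naming the two within-participant
#'   factor columns, each with exactly two levels.
#' @return A list of class `rm_anova_2x2` with `table` (effects: F,
#'   df_num, df_den, p, partial_eta_sq, gg_epsilon), `contrasts`, `n` and
#'   `cell_means`.
#' @export
rm_anova_2x2 <- function(data, dv = "value", id = "participant", factors) {
  if (length(factors) != 2L || !all(c(dv, id, factors) %in% names(data)))
    stop("`data` must contain the dv, id and two factor columns",
         call. = FALSE)
  a_lev <- sort(unique(as.character(data[[factors[1]]])))
  b_lev <- sort(unique(as.character(data[[factors[2]]])))
  if (length(a_lev) != 2L || length(b_lev) != 2L)
    stop("both factors must have exactly two levels", call. = FALSE)
  ids <- sort(unique(as.character(data[[id]])))
  n <- length(ids)
  if (n < 3L) stop("need at least 3 participants", call. = FALSE)
  if (any(!is.finite(data[[dv]])))
    stop("non-finite values in the response", call. = FALSE)
  y <- array(NA_real_, dim = c(n, 2, 2),
             dimnames = list(ids, a_lev, b_lev))
  for (r in seq_len(nrow(data)))
    y[as.character(data[[id]][r]), as.character(data[[factors[1]]][r]),
      as.character(data[[factors[2]]][r])] <- data[[dv]][r]
  if (any(is.na(y)))
    stop("incomplete participant x cell matrix (no imputation is done)",
         call. = FALSE)

  g <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_ab <- apply(y, c(2, 3), mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)

  ss_a <- 2 * n * sum((m_a - g)^2)
  ss_b <- 2 * n * sum((m_b - g)^2)
  dev_ab <- sweep(sweep(m_ab, 1, m_a), 2, m_b) + g
  ss_ab <- n * sum(dev_ab^2)
  dev_sa <- m_sa - matrix(m_s, n, 2) - matrix(m_a, n, 2, byrow = TRUE) + g
  ss_sa <- 2 * sum(dev_sa^2)
  dev_sb <- m_sb - matrix(m_s, n, 2) - matrix(m_b, n, 2, byrow = TRUE) + g
  ss_sb <- 2 * sum(dev_sb^2)
  resid <- y
  for (i in seq_len(n)) for (a in 1:2) for (b in 1:2)
    resid[i, a, b] <- y[i, a, b] - m_ab[a, b] - m_sa[i, a] - m_sb[i, b] +
      m_a[a] + m_b[b] + m_s[i] - g
  ss_sab <- sum(resid^2)

  df_err <- n - 1L
  row_for <- function(effect, ss_eff, ss_err) {
    f <- (ss_eff / 1) / (ss_err / df_err)
    data.frame(effect = effect, ss = ss_eff, ss_error = ss_err,
               df_num = 1L, df_den = df_err, F = f,
               p = stats::pf(f, 1, df_err, lower.tail = FALSE),
               partial_eta_sq = ss_eff / (ss_eff + ss_err),
               gg_epsilon = 1, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row_for(factors[1], ss_a, ss_sa),
    row_for(factors[2], ss_b, ss_sb),
    row_for(paste(factors, collapse = ":"), ss_ab, ss_sab)
  )

  contrast_row <- function(d, label) {
    m <- mean(d); s <- stats::sd(d)
    t <- m / (s / sqrt(n)); f <- t^2
    data.frame(contrast = label, estimate = m, F = f, df_num = 1L,
               df_den = df_err,
               p = stats::pf(f, 1, df_err, lower.tail = FALSE),
               partial_eta_sq = f / (f + df_err), stringsAsFactors = FALSE)
  }
  contrasts <- rbind(
    contrast_row(y[, 1, 1] - y[, 1, 2],
                 sprintf("%s (%s vs %s) at %s = %s", factors[2], b_lev[1],
                         b_lev[2], factors[1], a_lev[1])),
    contrast_row(y[, 2, 1] - y[, 2, 2],
                 sprintf("%s (%s vs %s) at %s = %s", factors[2], b_lev[1],
                         b_lev[2], factors[1], a_lev[2])),
    contrast_row(y[, 1, 1] - y[, 2, 1],
                 sprintf("%s (%s vs %s) at %s = %s", factors[1], a_lev[1],
                         a_lev[2], factors[2], b_lev[1])),
    contrast_row(y[, 1, 2] - y[, 2, 2],
                 sprintf("%s (%s vs %s) at %s = %s", factors[1], a_lev[1],
                         a_lev[2], factors[2], b_lev[2]))
  )

  structure(list(table = tab, contrasts = contrasts, n = n,
                 factors = factors, cell_means = m_ab,
                 interaction_contrast = mean(y[, 1, 1] - y[, 1, 2] -
                                               y[, 2, 1] + y[, 2, 2])),
            class = "rm_anova_2x2")
}

#' @export
print.rm_anova_2x2 <- function(x, ...) {
  cat(sprintf("2 x 2 repeated-measures ANOVA (n = %d)\n", x$n))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %s: F(%d,%d) = %.2f, p = %.4g, eta_p^2 = %.2f\n",
                x$table$effect[i], x$table$df_num[i], x$table$df_den[i],
                x$table$F[i], x$table$p[i], x$table$partial_eta_sq[i]))
  cat("  contrasts:\n")
  for (i in seq_len(nrow(x$contrasts)))
    cat(sprintf("    %s: F(%d,%d) = %.2f, p = %.4g, eta_p^2 = %.2f\n",
                x$contrasts$contrast[i], x$contrasts$df_num[i],
                x$contrasts$df_den[i], x$contrasts$F[i], x$contrasts$p[i],
                x$contrasts$partial_eta_sq[i]))
  invisible(x)
}

#' Cousineau within-subject confidence intervals
#'
#' Removes between-participant offsets before computing per-cell
#' intervals: every value is replaced by
#' `value - participant mean + grand mean`, then each cell's interval is
#' `mean +/- t(1 - (1-level)/2, n-1) * SD_normalized / sqrt(n)`. The
#' optional Morey factor `sqrt(J/(J-1))` corrects the variance
#' underestimation induced by the normalization across `J` cells.
#'
#' @param mat Participant x cell numeric matrix (complete).
#' @param level Confidence level (default 0.95).
#' @param morey Apply the Morey correction factor? Default `FALSE` (plain
#'   Cousineau).
#' @return Data frame with one row per cell: `cell`, `mean`, `half_width`,
#'   `lower`, `upper`. The normalized matrix is attached as attribute
#'   `normalized`.
#' @export
cousineau_ci <- function(mat, level = 0.95, morey = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 participants", call. = FALSE)
  if (any(!is.finite(mat))) stop("matrix must be complete", call. = FALSE)
  n <- nrow(mat)
  j <- ncol(mat)
  norm <- mat - rowMeans(mat) + mean(mat)
  mult <- if (morey) sqrt(j / (j - 1)) else 1
  half <- stats::qt(1 - (1 - level) / 2, n - 1) *
    apply(norm, 2, stats::sd) / sqrt(n) * mult
  out <- data.frame(cell = colnames(mat) %||% paste0("cell", seq_len(j)),
                    mean = colMeans(mat), half_width = half,
                    lower = colMeans(mat) - half,
                    upper = colMeans(mat) + half,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "normalized") <- norm
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
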