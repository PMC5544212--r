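test_that("the one-sample t test matches stats::t.test and the d identity", {
  set.seed(701)
  for (i in 1:5) {
    x <- rnorm(sample(5:25, 1), mean = runif(1, -5, 5), sd = runif(1, 1, 10))
    res <- one_sample_t(x)
    ref <- t.test(x, mu = 0)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$cohens_d, res$t / sqrt(res$n), tolerance = 1e-9)
  }
})

test_that("zero-variance samples yield a flagged degenerate t result", {
  res <- one_sample_t(rep(3.2, 8))
  expect_true(res$degenerate)
  expect_true(is.na(res$t))
  expect_equal(res$mean, 3.2)
  expect_error(one_sample_t(2), "finite numbers")
})

test_that("the 2x2 within ANOVA reproduces a hand-computed sums-of-squares oracle", {
  # 4 participants x (A1/A2 x B1/B2); all SS terms worked out by hand:
  # SS_A = 56.25, SS_AxS = 0.75 -> F_A = 225
  # SS_B = 12.25, SS_BxS = 0.75 -> F_B = 49
  # SS_AB = 2.25, SS_ABxS = 0.75 -> F_AB = 9
  d <- expand.grid(participant = paste0("P", 1:4), A = c("a1", "a2"),
                   B = c("b1", "b2"), stringsAsFactors = FALSE)
  vals <- c(
    "P1.a1.b1" = 10, "P2.a1.b1" = 12, "P3.a1.b1" = 9, "P4.a1.b1" = 11,
    "P1.a1.b2" = 8, "P2.a1.b2" = 9, "P3.a1.b2" = 7, "P4.a1.b2" = 8,
    "P1.a2.b1" = 6, "P2.a2.b1" = 7, "P3.a2.b1" = 5, "P4.a2.b1" = 6,
    "P1.a2.b2" = 4, "P2.a2.b2" = 6, "P3.a2.b2" = 5, "P4.a2.b2" = 5)
  d$value <- vals[paste(d$participant, d$A, d$B, sep = ".")]
  res <- rm_anova_2x2(d, dv = "value", id = "participant",
                      factors = c("A", "B"))
  expect_equal(res$table$F, c(225, 49, 9), tolerance = 1e-10)
  expect_equal(res$table$ss, c(56.25, 12.25, 2.25), tolerance = 1e-10)
  expect_equal(res$table$ss_error, c(0.75, 0.75, 0.75), tolerance = 1e-10)
  expect_equal(res$table$df_num, rep(1L, 3))
  expect_equal(res$table$df_den, rep(3L, 3))
  expect_equal(res$table$partial_eta_sq,
               c(225 / 228, 49 / 52, 9 / 12), tolerance = 1e-10)
  expect_true(all(res$table$gg_epsilon == 1))
  # contrasts as squared paired t tests, worked out by hand
  expect_equal(res$contrasts$F, c(75, 6, 243, 54), tolerance = 1e-9)
  # interaction contrast (a1 - a2 difference of B differences)
  expect_equal(res$interaction_contrast, 1.5)
})

test_that("the within ANOVA agrees with stats::aov on random data", {
  set.seed(702)
  for (i in 1:3) {
    n <- sample(5:9, 1)
    d <- expand.grid(participant = paste0("P", seq_len(n)),
                     A = c("x", "y"), B = c("u", "v"),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d), sd = 3) + rep(rnorm(n, sd = 2), 4)
    res <- rm_anova_2x2(d, dv = "value", id = "participant",
                        factors = c("A", "B"))
    fit <- summary(aov(value ~ A * B + Error(factor(participant) / (A * B)),
                       data = d))
    f_aov <- c(fit[["Error: factor(participant):A"]][[1]]["A", "F value"],
               fit[["Error: factor(participant):B"]][[1]]["B", "F value"],
               fit[["Error: factor(participant):A:B"]][[1]]["A:B", "F value"])
    p_aov <- c(fit[["Error: factor(participant):A"]][[1]]["A", "Pr(>F)"],
               fit[["Error: factor(participant):B"]][[1]]["B", "Pr(>F)"],
               fit[["Error: factor(participant):A:B"]][[1]]["A:B", "Pr(>F)"])
    expect_equal(res$table$F, f_aov, tolerance = 1e-8)
    expect_equal(res$table$p, p_aov, tolerance = 1e-8)
  }
})

test_that("adding a constant to every cell leaves all F values unchanged", {
  set.seed(703)
  d <- expand.grid(participant = paste0("P", 1:6), A = c("x", "y"),
                   B = c("u", "v"), stringsAsFactors = FALSE)
  d$value <- rnorm(24)
  d2 <- d; d2$value <- d$value + 100
  r1 <- rm_anova_2x2(d, factors = c("A", "B"))
  r2 <- rm_anova_2x2(d2, factors = c("A", "B"))
  expect_equal(r1$table$F, r2$table$F, tolerance = 1e-9)
  expect_equal(r1$contrasts$F, r2$contrasts$F, tolerance = 1e-9)
})

test_that("incomplete or too-small ANOVA designs are rejected", {
  d <- expand.grid(participant = paste0("P", 1:4), A = c("x", "y"),
                   B = c("u", "v"), stringsAsFactors = FALSE)
  d$value <- rnorm(16)
  expect_error(rm_anova_2x2(d[-1, ], factors = c("A", "B")), "incomplete")
  expect_error(rm_anova_2x2(d[d$participant %in% c("P1", "P2"), ],
                            factors = c("A", "B")), "3 participants")
})

test_that("Cousineau normalization equalizes participant means and matches a worked example", {
  m <- matrix(c(2, 4, 4, 8, 3, 6), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("c1", "c2")))
  # rows: (2,4), (4,8), (3,6); grand mean 4.5; normalized cells have sd 0.5
  ci <- cousineau_ci(m)
  norm <- attr(ci, "normalized")
  expect_equal(unname(rowMeans(norm)), rep(4.5, 3))
  expect_equal(ci$mean, c(3, 6))
  expect_equal(ci$half_width, rep(qt(0.975, 2) * 0.5 / sqrt(3), 2),
               tolerance = 1e-12)
  expect_equal(ci$half_width, rep(1.2420689, 2), tolerance = 1e-6)
  expect_equal(ci$lower, ci$mean - ci$half_width)
  # a pure between-participant offset does not widen the intervals
  m2 <- m + c(10, -5, 7)
  ci2 <- cousineau_ci(m2)
  expect_equal(ci2$half_width, ci$half_width, tolerance = 1e-12)
  # Morey variant inflates by sqrt(J/(J-1))
  ci3 <- cousineau_ci(m, morey = TRUE)
  expect_equal(ci3$half_width, ci$half_width * sqrt(2), tolerance = 1e-12)
  expect_error(cousineau_ci(m[1, , drop = FALSE]), "2 participants")
})

test_that("effect-size helpers implement the defining identities", {
  expect_equal(cohens_d_from_t(3, 9), 1)
  expect_equal(partial_eta_squared(5, 1, 20), 5 / 25)
  expect_equal(partial_eta_squared(2.5, 2, 30), 5 / 35)
})
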