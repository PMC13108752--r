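# independent oracle: repeated-measures sums of squares by explicit loops
rm_anova_oracle <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ssm <- 0
  for (j in 1:k) ssm <- ssm + n * (mean(Y[, j]) - grand)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + grand)^2
  }
  F_ <- (ssm / (k - 1)) / (sse / ((n - 1) * (k - 1)))
  list(F = F_, peta = ssm / (ssm + sse))
}

test_that("the default design reports df1 = 3 and df2 = 27", {
  set.seed(51)
  Y <- matrix(rnorm(40, 50, 10), 10, 4)
  an <- rm_anova(Y)
  expect_equal(an$df1, 3L)
  expect_equal(an$df2, 27L)
})

test_that("identical method columns give F = 0 and p = 1", {
  Y <- matrix(rep(rnorm(10, 50, 5), 4), 10, 4)
  an <- rm_anova(Y)
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
  expect_equal(an$partial_eta_sq, 0)
})

test_that("F matches the brute-force sums-of-squares oracle to 1e-10", {
  set.seed(52)
  for (i in 1:25) {
    Y <- matrix(rnorm(40, 50, 15), 10, 4)
    an <- rm_anova(Y)
    orc <- rm_anova_oracle(Y)
    expect_equal(an$F, orc$F, tolerance = 1e-10)
    expect_equal(an$partial_eta_sq, orc$peta, tolerance = 1e-10)
  }
})

test_that("the decomposition agrees with aov's within-subject error stratum", {
  set.seed(53)
  Y <- matrix(rnorm(40, 30, 8), 10, 4)
  an <- rm_anova(Y)
  df <- data.frame(
    y = as.vector(Y),
    subj = factor(rep(1:10, 4)),
    method = factor(rep(1:4, each = 10))
  )
  fit <- summary(stats::aov(y ~ method + Error(subj / method), data = df))
  tab <- fit[["Error: subj:method"]][[1]]
  expect_equal(an$F, tab["method", "F value"], tolerance = 1e-10)
  expect_equal(an$p, tab["method", "Pr(>F)"], tolerance = 1e-10)
})

test_that("adding a per-participant constant leaves F unchanged", {
  set.seed(54)
  Y <- matrix(rnorm(40, 50, 10), 10, 4)
  shifted <- Y + matrix(rnorm(10, 0, 100), 10, 4)
  expect_equal(rm_anova(shifted)$F, rm_anova(Y)$F, tolerance = 1e-10)
})

test_that("partial eta squared lies in [0,1] and increases with F", {
  set.seed(55)
  base <- matrix(rnorm(40, 0, 5), 10, 4)
  effects <- c(0, 5, 15, 40)
  res <- vapply(effects, function(d) {
    Y <- base + matrix(rep(c(0, d, 2 * d, 3 * d), each = 10), 10, 4)
    an <- rm_anova(Y)
    c(an$F, an$partial_eta_sq)
  }, c(0, 0))
  expect_true(all(res[2, ] >= 0 & res[2, ] <= 1))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) > 0))
})

test_that("incomplete matrices are rejected", {
  Y <- matrix(rnorm(40), 10, 4); Y[3, 2] <- NA
  expect_error(rm_anova(Y), "complete")
})

test_that("Greenhouse-Geisser epsilon lands in [1/(k-1), 1] and shifts p upward", {
  set.seed(56)
  Y <- matrix(rnorm(40, 50, 10), 10, 4) +
    matrix(rep(c(0, 3, 6, 9), each = 10), 10, 4)
  an <- rm_anova(Y, gg_correction = TRUE)
  expect_gte(an$gg_epsilon, 1 / 3)
  expect_lte(an$gg_epsilon, 1)
  expect_gte(an$p_gg, an$p)
})

test_that("pairwise comparisons reproduce the paired t closed form with x6 Bonferroni", {
  set.seed(57)
  Y <- matrix(rnorm(40, 50, 10), 10, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  out <- pairwise_bonferroni(Y)
  expect_equal(nrow(out), 6L)
  d <- Y[, "a"] - Y[, "b"]
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  row <- out[out$method_a == "a" & out$method_b == "b", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  p_hand <- 2 * stats::pt(abs(t_hand), df = 9, lower.tail = FALSE)
  expect_equal(row$p_raw, p_hand, tolerance = 1e-12)
  expect_equal(row$p_bonferroni, min(1, 6 * p_hand), tolerance = 1e-12)
  ci_hand <- mean(d) + c(-1, 1) * stats::qt(0.975, 9) * sd(d) / sqrt(10)
  expect_equal(c(row$ci_low, row$ci_high), ci_hand, tolerance = 1e-12)
  expect_true(all(out$p_bonferroni >= out$p_raw))
  expect_true(all(out$ci_low <= out$mean_diff_mm &
                    out$mean_diff_mm <= out$ci_high))
})

test_that("identical columns yield capped p = 1; zero-variance contrasts are flagged", {
  base <- rnorm(8, 40, 3)
  Y <- cbind(a = base, b = base, c = base + 5)
  out <- pairwise_bonferroni(Y)
  ab <- out[out$method_a == "a" & out$method_b == "b", ]
  expect_equal(ab$p_bonferroni, 1)
  expect_equal(ab$mean_diff_mm, 0)
  ac <- out[out$method_a == "a" & out$method_b == "c", ]
  expect_true(ac$degenerate)
  expect_equal(ac$p_raw, 0)
  expect_equal(ac$direction, "a < c")
})

test_that("tidiers return one-row-per-test tibbles", {
  set.seed(58)
  an <- rm_anova(matrix(rnorm(40, 50, 10), 10, 4), group = "wrist_R")
  td <- tidy(an)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$group, "wrist_R")
  expect_equal(td$df2, 27L)
  gl <- glance(an)
  expect_equal(gl$n, 10L)
  expect_equal(gl$k, 4L)
})

test_that("report assembly writes deterministic CSVs with sorting-oracle box stats", {
  set.seed(59)
  n <- 400
  tab <- structure(tibble::tibble(
    participant = sample(1:4, n, TRUE),
    method = sample(c("tri", "mono"), n, TRUE),
    sequence = 1,
    group = factor(sample(c("wrist_R", "face"), n, TRUE),
                   levels = hpeval:::group_levels()),
    keypoint = "wrist_right", frame = seq_len(n),
    e = rexp(n, 1 / 30)
  ), class = c("error_table", class(tibble::tibble())))
  dc <- structure(tibble::tibble(voxel_size_mm = c(10, 50), dice = c(0.2, 0.8)),
                  class = c("dice_curve", class(tibble::tibble())))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- assemble_report(tab, dice_curve = dc, dir = d1)
  r2 <- assemble_report(tab, dice_curve = dc, dir = d2)
  expect_identical(unname(tools::md5sum(sort(list.files(d1, full.names = TRUE)))),
                   unname(tools::md5sum(sort(list.files(d2, full.names = TRUE)))))
  # whisker convention: furthest points within 1.5 IQR, via explicit sorting
  e <- sort(tab$e[tab$method == "tri" & tab$group == "wrist_R"])
  q <- stats::quantile(e, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  row <- r1$errors_summary[r1$errors_summary$method == "tri" &
                             r1$errors_summary$group == "wrist_R", ]
  expect_equal(row$whisker_low, min(e[e >= q[1] - 1.5 * iqr]))
  expect_equal(row$whisker_high, max(e[e <= q[2] + 1.5 * iqr]))
  expect_equal(row$median, stats::median(e))
  expect_true(file.exists(file.path(d1, "report.md")))
})
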