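#' One-way repeated-measures ANOVA on a participant x method matrix
#'
#' Classical within-subject decomposition for a complete design: with `n`
#' participants (rows) and `k` methods (columns),
#' `SS_method` (df `k - 1`), `SS_subject`, and the residual
#' `SS_error` (df `(n - 1)(k - 1)`); `F = MS_method / MS_error` and the
#' effect size is partial eta squared `SS_method / (SS_method + SS_error)`.
#' With the default 10 x 4 design this gives df1 = 3 and df2 = 27.
#'
#' No sphericity correction is applied by default; a Greenhouse-Geisser
#' corrected p-value is available via `gg_correction = TRUE`.
#'
#' @param means Numeric n x k matrix (or data frame) of cell means, rows =
#'   participants, columns = methods. Must be complete.
#' @param group Optional label carried into the result.
#' @param gg_correction Apply Greenhouse-Geisser correction to the dfs used
#'   for the p-value.
#' @return An `rm_anova` object (list with `group, F, df1, df2, p,
#'   partial_eta_sq, n, k`, plus `gg_epsilon`/`p_gg` when requested).
#' @export
rm_anova <- function(means, group = NA, gg_correction = FALSE) {
  Y <- as.matrix(means)
  if (anyNA(Y)) abort("Repeated-measures ANOVA requires a complete matrix.")
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L || k < 2L) abort("Need at least 2 participants and 2 methods.")
  grand <- mean(Y)
  col_m <- colMeans(Y); row_m <- rowMeans(Y)
  ss_method <- n * sum((col_m - grand)^2)
  ss_subject <- k * sum((row_m - grand)^2)
  resid <- Y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_error <- sum(resid^2)
  # sums of squares that are zero up to rounding (e.g. identical columns)
  # are treated as exactly zero so F and p are well defined
  ss_floor <- 1e-12 * max(sum((Y - grand)^2), .Machine$double.xmin)
  if (ss_method < ss_floor) ss_method <- 0
  if (ss_error < ss_floor) ss_error <- 0
  df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
  F_ <- if (ss_method == 0) 0
  else if (ss_error == 0) Inf
  else (ss_method / df1) / (ss_error / df2)
  out <- list(
    group = group, F = F_, df1 = df1, df2 = df2,
    p = pf(F_, df1, df2, lower.tail = FALSE),
    partial_eta_sq = if (ss_method + ss_error > 0) ss_method / (ss_method + ss_error) else 0,
    ss_method = ss_method, ss_subject = ss_subject, ss_error = ss_error,
    n = n, k = k
  )
  if (gg_correction) {
    S <- stats::cov(Y)
    sbar <- mean(S); d <- mean(diag(S)); srow <- rowMeans(S)
    eps <- (k^2 * (d - sbar)^2) /
      ((k - 1) * (sum(S^2) - 2 * k * sum(srow^2) + k^2 * sbar^2))
    eps <- min(1, max(1 / (k - 1), eps))
    out$gg_epsilon <- eps
    out$p_gg <- pf(F_, eps * df1, eps * df2, lower.tail = FALSE)
  }
  structure(out, class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA%s: F(%d, %d) = %.3f, p = %s, partial eta^2 = %.3f\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$df1, x$df2, x$F, format.pval(x$p, digits = 3, eps = 1e-16),
              x$partial_eta_sq))
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired t-tests on every method pair; raw p-values are multiplied by the
#' number of pairs (`choose(k, 2)`, capped at 1) and 95% confidence intervals
#' of the mean paired difference use the t distribution with `n - 1` df. A
#' zero-variance nonzero difference yields an infinite t statistic, reported
#' as p = 0 and flagged `degenerate`.
#'
#' @param means Complete participant x method matrix (named columns).
#' @param alpha Significance level for the `direction` verdict.
#' @param group Optional label.
#' @return A `pairwise_bonferroni` tibble: `group, method_a, method_b,
#'   mean_diff_mm, ci_low, ci_high, t, p_raw, p_bonferroni, direction,
#'   degenerate`.
#' @export
pairwise_bonferroni <- function(means, alpha = 0.05, group = NA) {
  Y <- as.matrix(means)
  if (anyNA(Y)) abort("Pairwise comparisons require a complete matrix.")
  meths <- colnames(Y) %||% paste0("method", seq_len(ncol(Y)))
  colnames(Y) <- meths
  n <- nrow(Y)
  pairs <- utils::combn(meths, 2)
  m <- ncol(pairs)
  rows <- purrr::map(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- Y[, a] - Y[, b]
    degenerate <- sd(d) == 0
    if (degenerate) {
      md <- mean(d)
      praw <- if (md == 0) 1 else 0
      tt <- if (md == 0) 0 else sign(md) * Inf
      ci <- c(md, md)
    } else {
      ht <- stats::t.test(d)
      md <- unname(ht$estimate); praw <- ht$p.value
      tt <- unname(ht$statistic); ci <- as.numeric(ht$conf.int)
    }
    pb <- min(1, praw * m)
    dir <- if (pb < alpha) {
      if (md < 0) paste(a, "<", b) else paste(a, ">", b)
    } else "n.s."
    tibble(group = group, method_a = a, method_b = b, mean_diff_mm = md,
           ci_low = ci[1], ci_high = ci[2], t = tt, p_raw = praw,
           p_bonferroni = pb, direction = dir, degenerate = degenerate)
  })
  structure(bind_rows(rows),
            class = c("pairwise_bonferroni", class(tibble())))
}

#' @rdname hpeval-tidiers
#' @export
#' @method tidy rm_anova
tidy.rm_anova <- function(x, ...) {
  tibble(group = x$group, term = "method", df1 = x$df1, df2 = x$df2,
         statistic = x$F, p.value = x$p, partial.eta.squared = x$partial_eta_sq)
}

#' Broom-style tidiers
#'
#' `tidy()` returns one row per test; `glance()` a one-row model summary.
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @name hpeval-tidiers
#' @export
#' @method glance rm_anova
glance.rm_anova <- function(x, ...) {
  tibble(n = x$n, k = x$k, ss.method = x$ss_method,
         ss.subject = x$ss_subject, ss.error = x$ss_error)
}

box_stats <- function(e) {
  q <- quantile(e, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(e[e >= q[1] - 1.5 * iqr])
  hi <- max(e[e <= q[3] + 1.5 * iqr])
  tibble(q1 = q[1], median = q[2], q3 = q[3],
         whisker_low = lo, whisker_high = hi,
         n_outliers = sum(e < lo | e > hi))
}

#' Assemble the statistical report bundle
#'
#' Runs the per-group repeated-measures ANOVAs and Bonferroni post-hoc
#' comparisons from an error table, computes box-plot summary statistics
#' (whiskers at the furthest observations within 1.5 IQR of the quartiles),
#' and — when a directory is given — writes deterministic CSVs
#' (`anova.csv`, `pairwise.csv`, `errors_summary.csv`, `dice_curve.csv`) and
#' a markdown `report.md`.
#'
#' @param errors An `error_table`.
#' @param dice_curve Optional `dice_curve` tibble.
#' @param dir Optional output directory.
#' @param alpha Significance level for post-hoc verdicts.
#' @return A list: `anova` (tibble), `pairwise` (tibble), `errors_summary`,
#'   `cell_means`, `overall`, `dice_curve`, and `files` when written.
#' @export
assemble_report <- function(errors, dice_curve = NULL, dir = NULL,
                            alpha = 0.05) {
  agg <- aggregate_participant_means(errors)
  groups <- sort(unique(as.character(errors$group)))
  anova_rows <- list(); pw_rows <- list()
  n_valid <- errors |>
    group_by(.data$group) |>
    summarise(N_valid = dplyr::n(), .groups = "drop")
  for (g in groups) {
    wide <- agg$cell_means |>
      filter(as.character(.data$group) == g) |>
      select("participant", "method", "mean_error_mm") |>
      tidyr::pivot_wider(names_from = "method", values_from = "mean_error_mm")
    Y <- as.matrix(wide[, -1, drop = FALSE])
    if (anyNA(Y)) next  # incomplete cell: excluded, reported via N_valid
    an <- rm_anova(Y, group = g)
    anova_rows[[g]] <- tidy(an)
    pw_rows[[g]] <- pairwise_bonferroni(Y, alpha = alpha, group = g)
  }
  anova_tbl <- bind_rows(anova_rows) |>
    left_join(n_valid, by = "group")
  pairwise_tbl <- bind_rows(pw_rows)
  summary_tbl <- errors |>
    group_by(.data$method, .data$group) |>
    summarise(box_stats(.data$e), mean = mean(.data$e), .groups = "drop")
  out <- list(anova = anova_tbl, pairwise = pairwise_tbl,
              errors_summary = summary_tbl, cell_means = agg$cell_means,
              overall = agg$overall, dice_curve = dice_curve)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      anova = file.path(dir, "anova.csv"),
      pairwise = file.path(dir, "pairwise.csv"),
      errors_summary = file.path(dir, "errors_summary.csv"),
      report = file.path(dir, "report.md")
    )
    readr::write_csv(anova_tbl, files[["anova"]])
    readr::write_csv(pairwise_tbl, files[["pairwise"]])
    readr::write_csv(summary_tbl, files[["errors_summary"]])
    if (!is.null(dice_curve)) {
      files[["dice_curve"]] <- file.path(dir, "dice_curve.csv")
      readr::write_csv(as_tibble(dice_curve), files[["dice_curve"]])
    }
    writeLines(render_report_md(out), files[["report"]])
    out$files <- files
  }
  out
}

fmt_p <- function(p) ifelse(p < 0.001, "<.001", sprintf("%.3f", p))

md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.4g", col) else as.character(col)
  }, character(nrow(df)))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

render_report_md <- function(out) {
  lines <- c("# Keypoint error report", "", "## Repeated-measures ANOVA", "")
  an <- out$anova
  if (nrow(an)) {
    an_disp <- mutate(an, p.value = fmt_p(.data$p.value))
    lines <- c(lines, md_table(an_disp), "")
  }
  if (!is.null(out$pairwise) && nrow(out$pairwise)) {
    pw_disp <- out$pairwise |>
      mutate(p_bonferroni = fmt_p(.data$p_bonferroni)) |>
      select("group", "method_a", "method_b", "mean_diff_mm",
             "ci_low", "ci_high", "p_bonferroni", "direction")
    lines <- c(lines, "## Bonferroni pairwise comparisons", "",
               md_table(pw_disp), "")
  }
  lines <- c(lines, "## Per-method overall mean error (mm)", "",
             md_table(out$overall), "")
  if (!is.null(out$dice_curve)) {
    lines <- c(lines, "## Gesture-space Dice coefficient by voxel size", "",
               md_table(as_tibble(out$dice_curve)), "")
  }
  lines
}
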