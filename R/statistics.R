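#' Percentile summary of per-cell frequencies for one group
#'
#' The boxplot convention used throughout: box at the 25th/75th percentiles,
#' whiskers at the 10th/90th, median as the mid line. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param frequencies numeric vector (one value per cell/track).
#' @param label group label (strain or condition, e.g. an IAA dose).
#' @return one-row data frame of class `"group_stats"`: `label`, `n`, `mean`,
#'   `p10`, `p25`, `p50`, `p75`, `p90`.
#' @export
summarize_group <- function(frequencies, label = "") {
  if (length(frequencies) == 0) stop("empty group: ", label)
  q <- stats::quantile(frequencies, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       type = 7, names = FALSE)
  structure(data.frame(label = label, n = length(frequencies),
                       mean = mean(frequencies),
                       p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4],
                       p90 = q[5]),
            class = c("group_stats", "data.frame"))
}

#' Two-group comparison with the sample-size rule
#'
#' Applies the selection rule used for reversal-frequency comparisons: a
#' two-sided Wilcoxon rank-sum test when either group has fewer than 40 cells,
#' a two-sample Student t-test (equal variances; Welch behind `welch = TRUE`)
#' when both have at least 40. The Wilcoxon p-value is exact (full rank-sum
#' distribution) when both groups have at most 8 observations and no ties;
#' otherwise the normal approximation with continuity and tie correction is
#' used.
#'
#' @param a,b numeric vectors of per-cell frequencies.
#' @param n_threshold rule boundary: Wilcoxon iff `min(n_a, n_b) <
#'   n_threshold`.
#' @param welch use the Welch t-test instead of equal-variance Student.
#' @return list of class `"test_result"`: `test`, `statistic`, `p_value`,
#'   `n_a`, `n_b`, `rule_reason`, `flag`.
#' @export
compare_groups <- function(a, b, n_threshold = 40, welch = FALSE) {
  stopifnot(length(a) > 0, length(b) > 0)
  n_a <- length(a); n_b <- length(b)
  use_wilcox <- min(n_a, n_b) < n_threshold
  flag <- NULL
  if (use_wilcox) {
    exact <- n_a <= 8 && n_b <= 8 && !any(duplicated(c(a, b)))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    test <- "wilcoxon"
    reason <- sprintf("min(n) = %d < %d: Wilcoxon rank-sum%s",
                      min(n_a, n_b), n_threshold,
                      if (exact) " (exact)" else " (normal approx.)")
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      flag <- "zero variance in both groups"
      return(structure(list(test = "t_test",
                            statistic = if (same) 0 else Inf,
                            p_value = if (same) 1 else 0,
                            n_a = n_a, n_b = n_b,
                            rule_reason = sprintf(
                              "min(n) = %d >= %d: Student t-test (degenerate)",
                              min(n_a, n_b), n_threshold),
                            flag = flag),
                       class = "test_result"))
    }
    ht <- stats::t.test(a, b, var.equal = !welch)
    test <- "t_test"
    reason <- sprintf("min(n) = %d >= %d: %s t-test",
                      min(n_a, n_b), n_threshold,
                      if (welch) "Welch" else "Student")
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value, n_a = n_a, n_b = n_b,
                 rule_reason = reason, flag = flag),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d vs %d; %s)\n",
              x$test, x$statistic, x$p_value, x$n_a, x$n_b, x$rule_reason))
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Dose-response table of reversal frequencies
#'
#' Summarizes per-cell frequencies per stimulation dose (e.g. IAA, % v/v),
#' sorted ascending, with pairwise comparisons between consecutive doses.
#' Duplicate dose labels are merged with a warning. P-values are reported raw
#' (no multiple-testing correction).
#'
#' @param groups named list: names are numeric doses, values numeric vectors
#'   of per-cell frequencies.
#' @return list with `table` (data frame: dose, n, mean, percentiles) and
#'   `tests` (list of [compare_groups()] results between consecutive doses).
#' @export
dose_response <- function(groups) {
  doses <- as.numeric(names(groups))
  if (any(is.na(doses))) stop("group names must be numeric doses")
  if (length(unique(doses)) < 2) stop("need at least 2 distinct doses")
  if (any(duplicated(doses))) {
    warning("duplicate dose labels merged")
    groups <- lapply(split(groups, doses), function(g) unlist(g, use.names = FALSE))
    doses <- as.numeric(names(groups))
  }
  ord <- order(doses)
  groups <- groups[ord]; doses <- doses[ord]
  tab <- do.call(rbind, lapply(seq_along(groups), function(i)
    summarize_group(groups[[i]], label = as.character(doses[i]))))
  tab <- cbind(dose = doses, tab)
  tests <- lapply(seq_len(length(groups) - 1), function(i) {
    tr <- compare_groups(groups[[i]], groups[[i + 1]])
    tr$comparison <- sprintf("%g vs %g", doses[i], doses[i + 1])
    tr
  })
  list(table = tab, tests = tests)
}

#' Population speed summary
#'
#' Mean speed per cell (mean of the instantaneous speed series of each
#' track), then population mean, SD and n — the form in which strain speeds
#' are reported (e.g. 1.7 +/- 0.8 um/min for wild type).
#'
#' @param track_set a duration-filtered `"track_set"`.
#' @return list: `mean_um_min`, `sd_um_min`, `n`, `per_cell` (data frame).
#' @export
speed_summary <- function(track_set) {
  stopifnot(inherits(track_set, "track_set"))
  tr <- track_set$tracks
  if (nrow(tr) == 0)
    return(list(mean_um_min = NA_real_, sd_um_min = NA_real_, n = 0L,
                per_cell = data.frame(track_id = integer(0),
                                      speed_um_min = numeric(0))))
  per <- do.call(rbind, lapply(split(tr, tr$track_id), function(df)
    data.frame(track_id = df$track_id[1],
               speed_um_min = mean(df$speed_um_min, na.rm = TRUE))))
  rownames(per) <- NULL
  list(mean_um_min = mean(per$speed_um_min),
       sd_um_min = stats::sd(per$speed_um_min),
       n = nrow(per), per_cell = per)
}
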