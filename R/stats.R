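# --- group summaries ---------------------------------------------------------

#' Mean, SEM and 95% confidence interval of a sample
#'
#' `SEM = sd / sqrt(n)`; the confidence interval is
#' `mean +/- t(0.975, n-1) * SEM`.
#'
#' @param values numeric vector, `n >= 2`.
#' @param conf confidence level.
#' @return list with `mean`, `sem`, `ci` (length-2), `n`.
#' @examples
#' group_summary(c(1, 2, 3)) # mean 2, SEM 0.57735
#' @export
group_summary <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  sem <- sd(values) / sqrt(n)
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  list(mean = m, sem = sem, ci = c(m - tq * sem, m + tq * sem), n = n)
}

# --- paired / unpaired comparisons -------------------------------------------

#' Paired t-test between two measurement groups
#'
#' Two-sided paired t-test on the differences `y - x` (pairing by position).
#' Degenerate zero-variance differences are handled explicitly: identical
#' samples give `t = 0, p = 1` (flagged); constant nonzero differences give
#' `t = +/-Inf, p = 0` (flagged).
#'
#' @param x,y equal-length numeric vectors; element i of `x` is paired with
#'   element i of `y`.
#' @param measure label for reporting.
#' @param labels group labels, e.g. `c("7 DIV", "17 DIV")`.
#' @return object of class `group_comparison`: list with `measure`,
#'   `labels`, `summary_x`, `summary_y` (from [group_summary]), `t`, `df`,
#'   `p`, `variant = "paired"`, `flag`.
#' @examples
#' paired_t(c(1, 2, 3), c(1.1, 2.3, 2.9)) # t ~ 0.866, df 2
#' @export
paired_t <- function(x, y, measure = "measure",
                     labels = c("group 1", "group 2")) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length for a paired test; ",
         "use welch_t() for unpaired groups", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- y - x
  flag <- NA_character_
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1; flag <- "degenerate: identical samples"
    } else {
      t_stat <- sign(mean(d)) * Inf; p <- 0
      flag <- "degenerate: zero-variance nonzero differences"
    }
    df <- length(d) - 1
  } else {
    ht <- stats::t.test(y, x, paired = TRUE, alternative = "two.sided")
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(list(measure = measure, labels = labels,
                 summary_x = group_summary(x), summary_y = group_summary(y),
                 t = t_stat, df = df, p = p, variant = "paired", flag = flag),
            class = "group_comparison")
}

#' Welch two-sample t-test between two measurement groups
#'
#' Unpaired fallback used when no pairing map between the groups exists
#' (the two time points sample different cells); two-sided.
#'
#' @inheritParams paired_t
#' @return a `group_comparison` with `variant = "welch"`.
#' @export
welch_t <- function(x, y, measure = "measure",
                    labels = c("group 1", "group 2")) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  if (sd(c(x - mean(x), y - mean(y))) == 0) {
    d <- mean(y) - mean(x)
    res <- list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(x) + length(y) - 2,
                p = if (d == 0) 1 else 0,
                flag = "degenerate: zero within-group variance")
  } else {
    ht <- stats::t.test(x = y, y = x, var.equal = FALSE,
                        alternative = "two.sided")
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, flag = NA_character_)
  }
  structure(list(measure = measure, labels = labels,
                 summary_x = group_summary(x), summary_y = group_summary(y),
                 t = res$t, df = res$df, p = res$p, variant = "welch",
                 flag = res$flag),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(s) sprintf("%.4g +/- %.4g", s$mean, s$sem)
  cat(sprintf("%s: %s %s vs %s %s | %s t = %.4g, df = %.4g, p = %.4g\n",
              x$measure, x$labels[1], fmt(x$summary_x),
              x$labels[2], fmt(x$summary_y), x$variant, x$t, x$df, x$p))
  if (!is.na(x$flag)) cat("  [", x$flag, "]\n")
  invisible(x)
}

#' Build a group-comparison report table
#'
#' One row per measure, in the style of a summary table: group means with
#' SEM, the t statistic, degrees of freedom, two-sided p, and the test
#' variant used. When `pairing` is `TRUE` the paired test is used (the
#' caller asserts that positions pair up); otherwise Welch's unpaired test.
#'
#' @param measures named list; each element is a list with components `x`
#'   and `y` (numeric vectors).
#' @param labels group labels.
#' @param pairing logical: use the paired test (requires an explicit pairing
#'   of positions); default `FALSE` (Welch).
#' @return data.frame with columns `measure, mean_1, sem_1, mean_2, sem_2,
#'   t, df, p, variant`.
#' @export
comparison_table <- function(measures, labels = c("group 1", "group 2"),
                             pairing = FALSE) {
  rows <- lapply(names(measures), function(nm) {
    m <- measures[[nm]]
    cmp <- if (pairing) paired_t(m$x, m$y, nm, labels) else welch_t(m$x, m$y, nm, labels)
    data.frame(measure = nm,
               mean_1 = cmp$summary_x$mean, sem_1 = cmp$summary_x$sem,
               mean_2 = cmp$summary_y$mean, sem_2 = cmp$summary_y$sem,
               t = cmp$t, df = cmp$df, p = cmp$p, variant = cmp$variant)
  })
  out <- do.call(rbind, rows)
  names(out)[c(2, 3, 4, 5)] <- c(paste0("mean_", gsub(" ", "_", labels[1])),
                                 paste0("sem_", gsub(" ", "_", labels[1])),
                                 paste0("mean_", gsub(" ", "_", labels[2])),
                                 paste0("sem_", gsub(" ", "_", labels[2])))
  out
}
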