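#' One-way analysis of variance
#'
#' Classic equal-variance one-way ANOVA computed from the textbook sums of
#' squares: `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of
#' freedom, p from the upper tail of the F distribution. Degenerate data
#' with zero within-group variance but unequal group means are reported as
#' `F = Inf`, `p = 0` with `degenerate = TRUE` rather than silently; data
#' with no variance at all are an error.
#'
#' @param data data.frame holding the metric table.
#' @param value,group column names of the numeric response and group label.
#' @return An object of class `hq_anova`: list with `F`, `df` (between,
#'   within), `p`, `ms_within`, `group_stats` (group, n, mean, sd), and
#'   `degenerate`.
#' @examples
#' d <- data.frame(group = rep(c("a", "b", "c"), each = 3),
#'                 value = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
#' one_way_anova(d)$F   # 3
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  stopifnot(all(c(value, group) %in% names(data)))
  y <- data[[value]]
  g <- factor(data[[group]])
  if (any(!is.finite(y))) stop("all values must be finite")
  k <- nlevels(g)
  N <- length(y)
  if (k < 2) stop("at least 2 groups are required")
  if (N <= k) stop("need more observations than groups")
  n_i <- as.numeric(table(g))
  m_i <- as.numeric(tapply(y, g, mean))
  s_i <- as.numeric(tapply(y, g, stats::sd))
  grand <- mean(y)
  ssb <- sum(n_i * (m_i - grand)^2)
  ssw <- sum((y - m_i[as.integer(g)])^2)
  dfb <- k - 1; dfw <- N - k
  degenerate <- FALSE
  if (ssw <= .Machine$double.eps * sum(y^2)) {
    if (ssb <= .Machine$double.eps * max(sum(y^2), 1))
      stop("no variance: all values are identical")
    Fstat <- Inf; p <- 0; degenerate <- TRUE
  } else {
    Fstat <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(F = Fstat, df = c(between = dfb, within = dfw), p = p,
                 ss = c(between = ssb, within = ssw),
                 ms_within = ssw / dfw,
                 group_stats = data.frame(group = levels(g), n = n_i,
                                          mean = m_i, sd = s_i),
                 degenerate = degenerate),
            class = "hq_anova")
}

#' @export
print.hq_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df[1], x$df[2], x$F, x$p,
              if (x$degenerate) "  [degenerate: zero within-group variance]" else ""))
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD all-pairs post hoc comparison
#'
#' For every pair of groups, the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MS_within * (1/n_i + 1/n_j) / 2)`
#' (the Tukey-Kramer form, exact for balanced designs and conservative for
#' unbalanced ones) with the adjusted p-value from the studentized-range
#' distribution on `(k, N - k)`; a pair is flagged significant when the
#' adjusted p is below `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha familywise significance level.
#' @return data.frame with one row per pair: group_a, group_b, mean_a, sd_a,
#'   mean_b, sd_b, diff (mean_b - mean_a), se, q, p_adj, significant. The
#'   underlying `hq_anova` is attached as attribute `"anova"`.
#' @export
tukey_hsd <- function(data, value = "value", group = "group", alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  an <- one_way_anova(data, value = value, group = group)
  gs <- an$group_stats
  k <- nrow(gs)
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- gs$mean[i2] - gs$mean[i1]
    se <- sqrt(an$ms_within * (1 / gs$n[i1] + 1 / gs$n[i2]) / 2)
    if (an$degenerate) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = an$df["within"], lower.tail = FALSE)
    }
    data.frame(group_a = gs$group[i1], group_b = gs$group[i2],
               mean_a = gs$mean[i1], sd_a = gs$sd[i1],
               mean_b = gs$mean[i2], sd_b = gs$sd[i2],
               diff = diff, se = se, q = q, p_adj = p,
               significant = p < alpha)
  })
  out <- do.call(rbind, res)
  attr(out, "anova") <- an
  out
}

#' ANOVA + Tukey HSD across a panel of metrics
#'
#' Runs [one_way_anova()] and [tukey_hsd()] on each metric column and stacks
#' the pairwise results into one long table. No cross-metric multiplicity
#' adjustment is applied — each biomarker panel member is tested on its own,
#' as is conventional for exploratory blood-chemistry panels. Metrics whose
#' data violate the ANOVA preconditions are reported as skipped (attribute
#' `"skipped"`), not fatal.
#'
#' @param data data.frame with a group column and one column per metric.
#' @param metrics character vector of metric column names.
#' @param group group column name.
#' @param alpha familywise level per metric.
#' @return Long data.frame: metric, group_a, group_b, mean_a, sd_a, mean_b,
#'   sd_b, diff, q, p_adj, significant, plus per-metric ANOVA columns
#'   f_stat and anova_p. Attribute `"skipped"` names metrics that failed.
#' @export
compare_all_metrics <- function(data, metrics, group = "group", alpha = 0.05) {
  stopifnot(group %in% names(data))
  out <- list()
  skipped <- character(0)
  for (m in metrics) {
    if (!m %in% names(data)) {
      skipped <- c(skipped, m)
      message("metric '", m, "' not found; skipped")
      next
    }
    tk <- tryCatch(tukey_hsd(data.frame(group = data[[group]], value = data[[m]]),
                             alpha = alpha),
                   error = function(e) {
                     message("metric '", m, "' skipped: ", conditionMessage(e))
                     NULL
                   })
    if (is.null(tk)) { skipped <- c(skipped, m); next }
    an <- attr(tk, "anova")
    tk$metric <- m
    tk$f_stat <- an$F
    tk$anova_p <- an$p
    out[[m]] <- tk
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group_a = character(0), group_b = character(0),
               mean_a = numeric(0), sd_a = numeric(0), mean_b = numeric(0),
               sd_b = numeric(0), diff = numeric(0), se = numeric(0),
               q = numeric(0), p_adj = numeric(0), significant = logical(0),
               metric = character(0), f_stat = numeric(0), anova_p = numeric(0))
  rownames(res) <- NULL
  cols <- c("metric", "group_a", "group_b", "mean_a", "sd_a", "mean_b", "sd_b",
            "diff", "se", "q", "p_adj", "significant", "f_stat", "anova_p")
  res <- res[, cols]
  attr(res, "skipped") <- skipped
  res
}
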