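#' One-way fixed-effects ANOVA across groups
#'
#' Classical single-factor ANOVA on one behavioral metric, one value per
#' larva. Thin wrapper over `stats::oneway.test(var.equal = TRUE)`, exposed
#' with explicit degrees of freedom so downstream post-hoc tests share the
#' same decomposition.
#'
#' @param groups Named list of numeric vectors, one per group; every group
#'   needs at least 2 finite values.
#' @return List with `F`, `df_between` (k - 1), `df_within` (N - k), and
#'   `p_value`.
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
anova_oneway <- function(groups) {
  groups <- check_groups(groups, min_per_group = 2L)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)))
  k <- length(groups)
  n <- length(values)
  ss_total <- sum((values - mean(values))^2)
  ss_within <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  if (ss_total < .Machine$double.eps * n &&
      ss_within < .Machine$double.eps * n) {
    stop("F undefined: zero variance both within and between groups",
         call. = FALSE)
  }
  ft <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(
    F = unname(ft$statistic),
    df_between = k - 1L,
    df_within = n - k,
    p_value = unname(ft$p.value)
  )
}

check_groups <- function(groups, min_per_group = 1L) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("at least 2 groups are required", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  for (nm in names(groups)) {
    v <- groups[[nm]]
    if (!is.numeric(v) || length(v) < min_per_group || any(!is.finite(v))) {
      stop(sprintf(
        "group '%s' must hold at least %d finite numeric value(s)",
        nm, min_per_group), call. = FALSE)
    }
  }
  groups
}

#' Tukey-Kramer all-pairs post-hoc comparisons
#'
#' For each pair of groups the critical range is
#' `q(1 - alpha; k, df_within) * sqrt((MSW / 2) * (1/n_a + 1/n_b))`,
#' with the studentized-range quantile from [stats::qtukey()] (computed
#' numerically, not from a table) and MSW the pooled within-group mean
#' square. Unequal group sizes are handled by the Kramer adjustment in the
#' standard-error term. A pair is significant iff the absolute mean
#' difference strictly exceeds its critical range.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param alpha Familywise significance level in (0, 1); default 0.05.
#' @return Data frame with one row per unordered pair: `group_a`, `group_b`,
#'   `mean_diff` (mean_a - mean_b), `critical_range`, `significant`.
#' @examples
#' tukey_kramer(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(9, 10, 11)))
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups, min_per_group = 1L)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  df_within <- N - k
  if (df_within < 1L) {
    stop("Tukey-Kramer requires df_within >= 1", call. = FALSE)
  }
  msw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2))) / df_within
  means <- vapply(groups, mean, numeric(1))
  q_crit <- stats::qtukey(1 - alpha, nmeans = k, df = df_within)
  pairs <- utils::combn(names(groups), 2L)
  out <- data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    mean_diff = means[pairs[1L, ]] - means[pairs[2L, ]],
    critical_range = NA_real_, significant = NA,
    stringsAsFactors = FALSE
  )
  out$critical_range <- q_crit *
    sqrt((msw / 2) * (1 / n[out$group_a] + 1 / n[out$group_b]))
  out$significant <- abs(out$mean_diff) > out$critical_range
  rownames(out) <- NULL
  out
}

#' Pfaffl relative expression ratio
#'
#' Efficiency-corrected fold change of a target transcript relative to a
#' reference gene (e.g. `rps7`):
#' `E_target^dCt_target / E_ref^dCt_ref`.
#'
#' Sign convention: each delta-Ct is **control minus sample** cycles, so a
#' knocked-down target (later amplification in the sample, i.e. higher Ct)
#' yields a fold change below 1.
#'
#' @param efficiency_target,efficiency_ref Amplification efficiencies per
#'   cycle (2 = perfect doubling). Must be positive; values outside the
#'   plausible `[1, 2.5]` range trigger a warning.
#' @param delta_ct_target,delta_ct_ref Delta-Ct values, control minus sample.
#' @return Fold change (positive real).
#' @examples
#' pfaffl_ratio(2, 2, 2, 0)        # 4-fold up
#' pfaffl_ratio(1.9, 1, 2.0, 1)    # 0.95
#' @export
pfaffl_ratio <- function(efficiency_target, delta_ct_target,
                         efficiency_ref, delta_ct_ref) {
  for (e in c(efficiency_target, efficiency_ref)) {
    if (!is.numeric(e) || !is.finite(e) || e <= 0) {
      stop("amplification efficiencies must be positive", call. = FALSE)
    }
    if (e < 1 || e > 2.5) {
      warning(sprintf(
        "efficiency %.3g outside the plausible [1, 2.5] range", e),
        call. = FALSE)
    }
  }
  stopifnot(is.finite(delta_ct_target), is.finite(delta_ct_ref))
  efficiency_target^delta_ct_target / efficiency_ref^delta_ct_ref
}

behavior_metrics <- c("n_turns", "n_movements", "avg_velocity_mm_s",
                      "resting_time_s")

#' Compare one behavioral metric across treatment groups
#'
#' Runs the one-way ANOVA first and always reports the Tukey-Kramer pairwise
#' table; the pairwise outcomes are flagged authoritative only when the
#' ANOVA is itself significant at `alpha`, mirroring the
#' significant-then-post-hoc convention.
#'
#' @param summaries Data frame of per-larva behavior summaries (see
#'   [summarize_tracks()]).
#' @param metric One of `"n_turns"`, `"n_movements"`, `"avg_velocity_mm_s"`,
#'   `"resting_time_s"`.
#' @param group_col Name of the grouping column (default `"treatment"`).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return An object of class `"comparison_result"`: list with `metric`,
#'   `F`, `df_between`, `df_within`, `p_value`, `alpha`, `authoritative`
#'   (ANOVA p < alpha), and `pairwise` (the [tukey_kramer()] table).
#' @export
compare_metric <- function(summaries, metric, group_col = "treatment",
                           alpha = 0.05) {
  if (!metric %in% behavior_metrics) {
    stop(sprintf("unknown metric '%s'; expected one of %s", metric,
                 paste(behavior_metrics, collapse = ", ")), call. = FALSE)
  }
  if (!group_col %in% names(summaries)) {
    stop(sprintf("grouping column '%s' not found", group_col), call. = FALSE)
  }
  groups <- split(summaries[[metric]], summaries[[group_col]])
  if (length(groups) < 2L) {
    stop("at least 2 groups are required to compare a metric", call. = FALSE)
  }
  av <- anova_oneway(groups)
  pw <- tukey_kramer(groups, alpha = alpha)
  structure(
    list(
      metric = metric,
      F = av$F, df_between = av$df_between, df_within = av$df_within,
      p_value = av$p_value, alpha = alpha,
      authoritative = av$p_value < alpha,
      pairwise = pw
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$metric, x$df_between, x$df_within, x$F, x$p_value,
              if (x$authoritative) sprintf(" (significant at alpha = %g)",
                                           x$alpha) else ""))
  print(x$pairwise)
  invisible(x)
}

#' Compare all four behavioral metrics across groups
#'
#' Convenience wrapper running [compare_metric()] for turns, movements,
#' velocity, and resting time, flattened into one long report table. No
#' correction is applied across the four metrics.
#'
#' @inheritParams compare_metric
#' @return Data frame with columns
#'   `metric,F,df1,df2,p,pair,mean_diff,critical,significant`; each metric
#'   contributes one ANOVA row (`pair = ""`) followed by its pairwise rows.
#' @export
compare_all_metrics <- function(summaries, group_col = "treatment",
                                alpha = 0.05) {
  rows <- lapply(behavior_metrics, function(m) {
    cr <- compare_metric(summaries, m, group_col = group_col, alpha = alpha)
    anova_row <- data.frame(
      metric = m, F = cr$F, df1 = cr$df_between, df2 = cr$df_within,
      p = cr$p_value, pair = "", mean_diff = NA_real_, critical = NA_real_,
      significant = cr$authoritative, stringsAsFactors = FALSE
    )
    pair_rows <- data.frame(
      metric = m, F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
      p = NA_real_,
      pair = paste(cr$pairwise$group_a, cr$pairwise$group_b, sep = " vs "),
      mean_diff = cr$pairwise$mean_diff,
      critical = cr$pairwise$critical_range,
      significant = cr$pairwise$significant, stringsAsFactors = FALSE
    )
    rbind(anova_row, pair_rows)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
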