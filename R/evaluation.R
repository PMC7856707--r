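#' Round half away from zero
#'
#' Presentation rounding for percentages (base R's `round()` rounds half
#' to even, which does not match how clinical tables are typically
#' printed).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Match rate as a percentage to one decimal place
#'
#' @param k Number of correctly matched records.
#' @param n Number of gold-standard-eligible records.
#' @return `100 * k / n`, rounded half away from zero to 1 decimal.
#' @examples
#' match_rate_pct(1202, 1242)  # 96.8
#' match_rate_pct(1211, 1242)  # 97.5
#' @export
match_rate_pct <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  round_half_up(100 * k / n, 1)
}

#' Format a "percent (count)" table cell
#'
#' @param k Count in the category.
#' @param n Group size.
#' @return A string like `"58.5 (24)"`.
#' @examples
#' fmt_pct_n(24, 41)  # "58.5 (24)"
#' @export
fmt_pct_n <- function(k, n) {
  sprintf("%.1f (%d)", round_half_up(100 * k / n, 1), k)
}

#' Score a linkage result against the gold standard
#'
#' A pair is a true match when it coincides with a gold pair; a false
#' positive when its surgery record has no gold partner or a different
#' one; a false negative when a gold pair is absent from the result. The
#' match-rate denominator is the gold-standard-eligible count (surgery
#' records with a true ICU partner), not the full registry size; both are
#' reported.
#'
#' @param result A `linkage_result` from [link_probabilistic()] or
#'   [run_stages()].
#' @param gold Gold-standard data frame (`surgery_id`, `icu_id`, possibly
#'   `stratum`) from [generate_registries()].
#' @return An object of class `eval_report`: counts (`n_eligible`,
#'   `n_surgery_total`, `n_matched_true`, `n_false_positive`,
#'   `n_false_negative`, `n_pairs`) and `match_rate_pct`.
#' @export
evaluate_linkage <- function(result, gold) {
  stopifnot(inherits(result, "linkage_result"))
  pairs <- result$pairs
  if (!all(pairs$surgery_id %in% gold$surgery_id)) {
    stop("linkage result contains surgery ids absent from the gold standard",
         call. = FALSE)
  }
  truth <- gold$icu_id[match(pairs$surgery_id, gold$surgery_id)]
  true_match <- !is.na(truth) & pairs$icu_id == truth
  eligible <- gold$surgery_id[!is.na(gold$icu_id)]
  n_true <- sum(true_match)
  report <- list(
    n_eligible = length(eligible),
    n_surgery_total = nrow(gold),
    n_pairs = nrow(pairs),
    n_matched_true = n_true,
    n_false_positive = nrow(pairs) - n_true,
    n_false_negative = length(eligible) - n_true,
    match_rate_pct = match_rate_pct(n_true, length(eligible)),
    method = result$method)
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s): %d/%d true matches (%.1f%%), %d FP, %d FN (n total %d)\n",
              x$method, x$n_matched_true, x$n_eligible, x$match_rate_pct,
              x$n_false_positive, x$n_false_negative, x$n_surgery_total))
  invisible(x)
}

#' Compare two match rates with a Pearson chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 table of matched/unmatched counts in two groups.
#'
#' @param k1,n1 Matched count and group size for the first strategy.
#' @param k2,n2 Matched count and group size for the second strategy.
#' @param correct Apply the Yates continuity correction? Default `FALSE`.
#' @return A list with `statistic`, `df` and `p_value`.
#' @examples
#' compare_match_rates(1202, 1242, 1151, 1242)$p_value  # < 0.001
#' @export
compare_match_rates <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a margin is zero", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

fmt_mean_sd <- function(x) sprintf("%.1f (%.1f)",
                                   round_half_up(mean(x), 1),
                                   round_half_up(stats::sd(x), 1))

fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
}

safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_)

#' Compare baseline characteristics across cohorts
#'
#' Emits a characteristics table in the conventional layout: age as mean
#' (sd) with a Student's t-test (two groups, equal variances) or one-way
#' ANOVA (more); male sex and urgency as percent (n) with a Pearson
#' chi-square; risk of death as median (IQR), reported in percent, with a
#' Wilcoxon rank-sum (two groups) or Kruskal-Wallis test (more); procedure
#' type as percent (n) per category with a single chi-square over the full
#' contingency table. A degenerate comparison (for example zero variance
#' in both groups) reports `NA` for its p-value.
#'
#' @param cohorts Named list of surgery registry data frames, one per
#'   cohort (for example matched vs unmatched, or the unmatched sets of
#'   several strategies).
#' @return A data frame with one row per characteristic (procedure types
#'   one row per category), a formatted cell per cohort, the test name and
#'   the p-value.
#' @export
compare_cohorts <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2,
            !is.null(names(cohorts)), all(nzchar(names(cohorts))))
  g <- length(cohorts)
  two <- g == 2
  grp_factor <- factor(rep(names(cohorts), vapply(cohorts, nrow, integer(1))),
                       levels = names(cohorts))
  pull <- function(col) unlist(lapply(cohorts, function(d) d[[col]]),
                               use.names = FALSE)

  rows <- list()
  cell <- function(label, cells, test, p) {
    as.data.frame(c(list(characteristic = label),
                    stats::setNames(as.list(cells), names(cohorts)),
                    list(test = test, p_value = p)),
                  check.names = FALSE)
  }

  age <- pull("age")
  p_age <- if (two) {
    safe_p(stats::t.test(age ~ grp_factor, var.equal = TRUE)$p.value)
  } else {
    safe_p(summary(stats::aov(age ~ grp_factor))[[1]][["Pr(>F)"]][1])
  }
  rows$age <- cell("Age (mean, sd)",
                   vapply(cohorts, function(d) fmt_mean_sd(d$age), character(1)),
                   if (two) "t-test" else "ANOVA", p_age)

  male <- vapply(cohorts, function(d) sum(d$sex == "M"), integer(1))
  sizes <- vapply(cohorts, nrow, integer(1))
  p_male <- safe_p(compare_counts_chisq(male, sizes))
  rows$male <- cell("Male sex (%, n)", mapply(fmt_pct_n, male, sizes),
                    "chi-square", p_male)

  risk <- pull("risk_of_death") * 100
  p_risk <- if (two) {
    safe_p(stats::wilcox.test(risk ~ grp_factor, exact = FALSE)$p.value)
  } else {
    safe_p(stats::kruskal.test(risk ~ grp_factor)$p.value)
  }
  rows$risk <- cell("Risk of death % (median, IQR)",
                    vapply(cohorts, function(d) fmt_median_iqr(d$risk_of_death * 100),
                           character(1)),
                    if (two) "Wilcoxon rank-sum" else "Kruskal-Wallis", p_risk)

  urg <- vapply(cohorts, function(d) sum(d$urgency == "urgent"), integer(1))
  p_urg <- safe_p(compare_counts_chisq(urg, sizes))
  rows$urgency <- cell("Urgent/emergent procedure (%, n)",
                       mapply(fmt_pct_n, urg, sizes), "chi-square", p_urg)

  ptype_levels <- c("CABG", "valve", "CABG+valve", "other")
  tab <- vapply(cohorts,
                function(d) table(factor(d$procedure_type, ptype_levels)),
                integer(length(ptype_levels)))
  p_ptype <- safe_p(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$p.value))
  for (j in seq_along(ptype_levels)) {
    rows[[paste0("ptype_", j)]] <- cell(
      sprintf("Procedure type: %s (%%, n)", ptype_levels[j]),
      mapply(fmt_pct_n, tab[j, ], sizes), "chi-square",
      if (j == 1) p_ptype else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# chi-square over a k-group success/failure table
compare_counts_chisq <- function(successes, sizes) {
  tab <- rbind(successes, sizes - successes)
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}
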