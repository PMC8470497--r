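## Kaplan-Meier estimation, log-rank comparison, demographics.
## The product-limit machinery is delegated to the survival package; the
## surrounding accessors implement the conventions used throughout the
## pipeline (median = first time with S <= 0.5, step interpolation).

#' Kaplan-Meier fit
#'
#' Product-limit estimator; at tied times deaths are processed before
#' censorings (the survival-package convention).
#'
#' @param time non-negative follow-up times (months).
#' @param event 1/TRUE = death observed, 0/FALSE = censored.
#' @return list of class `km_curve`: `times`, `survival`, `at_risk`,
#'   `events` (all starting at time 0, S(0) = 1).
#' @export
km_fit <- function(time, event) {
  stopifnot(length(time) >= 1, all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  structure(list(times = c(0, fit$time),
                 survival = c(1, fit$surv),
                 at_risk = c(length(time), fit$n.risk),
                 events = c(0L, fit$n.event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n=%d, %d events, median=%s months\n", x$at_risk[1],
              sum(x$events), format(km_median(x))))
  invisible(x)
}

#' Median survival of a Kaplan-Meier curve
#'
#' Smallest observed time with survival at or below 0.5; `NA` when the
#' curve never reaches 0.5 (e.g. all-censored input).
#'
#' @param curve a `km_curve`.
#' @return months, or `NA`.
#' @export
km_median <- function(curve) {
  idx <- which(curve$survival <= 0.5)
  if (!length(idx)) return(NA_real_)
  curve$times[idx[1]]
}

#' Landmark survival S(t)
#'
#' Step interpolation of the Kaplan-Meier curve; beyond the last observed
#' time the last estimate is carried forward.
#'
#' @param curve a `km_curve`.
#' @param t landmark time (months, >= 0).
#' @return survival proportion.
#' @export
landmark_survival <- function(curve, t) {
  stopifnot(t >= 0)
  f <- stats::stepfun(curve$times[-1], curve$survival)
  f(t)
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' @param time,event follow-up and event indicator.
#' @param group group labels (>= 2 non-empty groups).
#' @return list of class `survival_comparison`: `groups`, `chi_square`,
#'   `df`, `p_value`, `medians` (per-group KM medians).
#' @export
logrank_test <- function(time, event, group) {
  tab <- table(group)   # factor input keeps empty levels
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab == 0))
    stop("group with zero records: ", names(tab)[tab == 0][1])
  group <- as.character(group)
  if (sum(event) < 1) stop("need at least one event")
  sd <- survival::survdiff(
    survival::Surv(time, as.integer(event)) ~ group)
  df <- length(sd$n) - 1
  meds <- vapply(names(tab), function(g)
    km_median(km_fit(time[group == g], event[group == g])), numeric(1))
  structure(list(groups = names(tab), chi_square = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 medians = meds),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("<survival_comparison> chi2=%.3f df=%d p=%.4g\n", x$chi_square,
              x$df, x$p_value))
  print(round(x$medians, 1))
  invisible(x)
}

#' Export a Kaplan-Meier curve as TSV
#' @param curve a `km_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.table(
    data.frame(time = curve$times, survival = curve$survival,
               at_risk = curve$at_risk, events = curve$events),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

tukey_keep <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2] - q[1]
  x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr
}

#' Demographic summary per molecular subgroup
#'
#' Age central tendency (mean, SEM, median; outliers excluded by the Tukey
#' 1.5 x IQR fence for the trimmed mean), male-to-female ratio,
#' white-to-black ethnicity ratio (cases with missing ethnicity excluded
#' from the denominator), tumor location distribution, and pairwise Welch
#' two-tailed t-tests on age between subgroups (raw p-values, plus a
#' Holm-adjusted column as a labelled extension).
#'
#' @param cohort a `gbm_cohort`.
#' @param subgroup_calls result of [classify_cohort()].
#' @return list: `by_subgroup` data.frame and `age_tests` data.frame.
#' @export
demographic_summary <- function(cohort, subgroup_calls) {
  cl <- merge(cohort$clinical, subgroup_calls[, c("case_id", "label")],
              by = "case_id")
  cl$col <- subgroup_column(cl$label)
  cl <- cl[!is.na(cl$col), , drop = FALSE]
  groups <- split(cl, cl$col)
  by_subgroup <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    age <- x$age
    keep <- tukey_keep(age)
    m <- sum(x$sex == "M"); f <- sum(x$sex == "F")
    w <- sum(x$ethnicity %in% "White"); b <- sum(x$ethnicity %in% "Black")
    loc <- table(factor(x$location, levels = GBM_LOCATION))
    data.frame(subgroup = g, n = nrow(x),
               age_mean = mean(age[keep]),
               age_sem = stats::sd(age[keep]) /
                 sqrt(sum(keep)),
               age_median = stats::median(age),
               n_age_outliers = sum(!keep),
               male = m, female = f,
               mf_ratio = if (f > 0) m / f else NA_real_,
               white = w, black = b,
               wb_ratio = if (b > 0) w / b else NA_real_,
               pct_frontal = 100 * unname(loc["frontal"]) / nrow(x),
               pct_temporal = 100 * unname(loc["temporal"]) / nrow(x),
               pct_midline = 100 * unname(loc["midline"] +
                                            loc["corpus_callosum"]) / nrow(x),
               stringsAsFactors = FALSE)
  }))
  if (length(groups) < 2) {
    return(list(by_subgroup = by_subgroup,
                age_tests = data.frame(group1 = character(),
                                       group2 = character(),
                                       p_value = numeric(), note = character(),
                                       p_holm = numeric())))
  }
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  age_tests <- do.call(rbind, lapply(pairs, function(p) {
    a <- groups[[p[1]]]$age; b <- groups[[p[2]]]$age
    a <- a[tukey_keep(a)]; b <- b[tukey_keep(b)]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(group1 = p[1], group2 = p[2], p_value = NA_real_,
                        note = "subgroup too small, test skipped",
                        stringsAsFactors = FALSE))
    data.frame(group1 = p[1], group2 = p[2],
               p_value = stats::t.test(a, b)$p.value, note = "",
               stringsAsFactors = FALSE)
  }))
  age_tests$p_holm <- stats::p.adjust(age_tests$p_value, method = "holm")
  list(by_subgroup = by_subgroup, age_tests = age_tests)
}
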