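#' Dichotomize expression around mean +/- delta * SD
#'
#' Patients with expression strictly below `mean - delta * sd` form the low
#' group, those strictly above `mean + delta * sd` the high group. Under the
#' default two-cutoff rule the patients strictly inside the band are excluded
#' from the comparison; `rule = "single"` instead splits at the mean alone
#' (low = below, high = at-or-above), the alternative reading of a
#' "mean +/- 0.25 SD" cutoff phrase.
#'
#' @param values numeric expression vector (one entry per patient).
#' @param delta cutoff width in sample standard deviations (default 0.25).
#' @param rule `"two-cutoff"` (default) or `"single"`.
#' @return tibble (class `expression_groups`) with `value` and `group`
#'   (`"low"`, `"high"`, `"excluded"`); cutoffs attached as attributes
#'   `lower` and `upper`.
#' @export
dichotomize <- function(values, delta = 0.25, rule = c("two-cutoff", "single")) {
  rule <- match.arg(rule)
  if (length(values) < 3) abort("at least 3 patients required")
  if (sd(values) == 0) abort("expression vector is constant")
  mu <- mean(values)
  s <- sd(values)
  lower <- mu - delta * s
  upper <- mu + delta * s
  group <- if (rule == "two-cutoff") {
    ifelse(values < lower, "low", ifelse(values > upper, "high", "excluded"))
  } else {
    ifelse(values < mu, "low", "high")
  }
  out <- tibble(value = values, group = group)
  if (!is.null(names(values))) out <- bind_cols(tibble(patient_id = names(values)), out)
  structure(out, lower = lower, upper = upper,
            class = c("expression_groups", class(tibble())))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function: right-continuous,
#' nonincreasing, starting at 1.
#'
#' @param time event/censoring times (> 0).
#' @param event 1 = event, 0 = censored.
#' @return tibble (class `km_fit`) with `time`, `n_risk`, `n_event`,
#'   `surv` — one row per observed time point.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) abort("at least one record required")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(
    tibble(time = fit$time, n_risk = fit$n.risk,
           n_event = fit$n.event, surv = fit$surv),
    class = c("km_fit", class(tibble()))
  )
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (hypergeometric variance, 1 df), with the
#' p-value from the chi-square upper tail. With no events in either group the
#' test is undefined; statistic 0 and p = 1 are returned with a warning.
#'
#' @param time,event survival outcome over all patients.
#' @param group two-level grouping vector.
#' @return tibble with `statistic`, `df`, `p_value`, and per-group `n`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2) abort("exactly two groups required")
  if (sum(event) == 0) {
    warn("no events in either group: log-rank undefined, returning p = 1")
    return(tibble(statistic = 0, df = 1L, p_value = 1,
                  n1 = sum(group == levels(group)[1]),
                  n2 = sum(group == levels(group)[2])))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble(
    statistic = sd_$chisq,
    df = 1L,
    p_value = pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
    n1 = sd_$n[1], n2 = sd_$n[2]
  )
}

#' Chi-square association between expression group and tumor stage
#'
#' Pearson chi-square on the group-by-stage contingency table (no continuity
#' correction), `df = (r - 1)(s - 1)`. Excluded patients are dropped first;
#' all-zero rows or columns are removed with a warning.
#'
#' @param groups an [dichotomize()] result or a character vector of group
#'   labels (values `"excluded"` are dropped).
#' @param stages categorical stage labels, aligned with `groups`.
#' @return tibble with `statistic`, `df`, `p_value`.
#' @export
chi_square_association <- function(groups, stages) {
  g <- if (inherits(groups, "expression_groups")) groups$group else groups
  keep <- g != "excluded"
  g <- g[keep]
  st <- as.character(stages)[keep]
  tab <- table(g, st)
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warn("dropping all-zero rows/columns from the contingency table")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("need at least 2 group levels and 2 stage levels")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' ROC curve and AUC by the rank statistic
#'
#' `AUC = P(score_case > score_control) + 0.5 * P(tie)`, computed from
#' mid-ranks (the Mann-Whitney U identity `AUC = U / (n1 * n2)`). The score
#' direction is fixed — higher score predicts case — and never flipped, so
#' AUC values below 0.5 are reported as such.
#'
#' @param scores numeric marker values.
#' @param labels logical or two-level vector; `TRUE` (or the level `"case"`,
#'   or the second factor level) marks cases.
#' @return list (class `roc_result`) with `auc` and `points`, a tibble of
#'   `threshold`, `fpr`, `tpr` tracing the ROC curve.
#' @export
roc_auc <- function(scores, labels) {
  case <- if (is.logical(labels)) labels
  else if (all(labels %in% c("case", "control"))) labels == "case"
  else as.factor(labels) == levels(as.factor(labels))[2]
  n1 <- sum(case)
  n0 <- sum(!case)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)  # mid-ranks handle ties
  auc <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[case] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!case] >= t), numeric(1))
  )
  structure(list(auc = auc, points = points), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d thresholds)\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' Validate one candidate biomarker against clinical outcomes
#'
#' Dichotomizes the marker's expression, then runs the Kaplan-Meier /
#' log-rank comparison of the low and high groups and the chi-square
#' stage-association test.
#'
#' @param values named expression vector over patients.
#' @param clinical tibble with `patient_id`, `os_time_days`, `os_event`,
#'   `inss_stage`.
#' @param delta dichotomization width (default 0.25 SD).
#' @return tibble with the marker's log-rank `lr_statistic` / `lr_p`,
#'   chi-square `chisq_statistic` / `chisq_p`, and group sizes.
#' @export
validate_biomarker <- function(values, clinical, delta = 0.25) {
  stopifnot(all(c("patient_id", "os_time_days", "os_event", "inss_stage") %in%
                  names(clinical)))
  values <- values[clinical$patient_id]
  grp <- dichotomize(values, delta = delta)
  keep <- grp$group != "excluded"
  lr <- if (length(unique(grp$group[keep])) == 2) {
    logrank_test(clinical$os_time_days[keep], clinical$os_event[keep],
                 grp$group[keep])
  } else {
    tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
           n1 = NA_integer_, n2 = NA_integer_)
  }
  cs <- tryCatch(
    chi_square_association(grp, clinical$inss_stage),
    error = function(e) tibble(statistic = NA_real_, df = NA_integer_,
                               p_value = NA_real_)
  )
  tibble(
    n_low = sum(grp$group == "low"), n_high = sum(grp$group == "high"),
    n_excluded = sum(grp$group == "excluded"),
    lr_statistic = lr$statistic, lr_p = lr$p_value,
    chisq_statistic = cs$statistic, chisq_p = cs$p_value
  )
}
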