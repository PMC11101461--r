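#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_abline labs scale_y_log10 theme_minimal
NULL

#' Plot an SNF convergence curve
#'
#' Relative spectral-norm change between fused matrices at consecutive
#' hyperparameter values, on a log scale.
#'
#' @param object a [convergence_curve()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.snf_convergence <- function(object, ...) {
  ggplot(object, aes(x = .data$value, y = .data$relative_change)) +
    geom_line() +
    geom_point() +
    scale_y_log10() +
    labs(
      x = paste("SNF parameter", unique(object$parameter)),
      y = "relative change (spectral norm)",
      title = "SNF convergence"
    ) +
    theme_minimal()
}

#' Plot the quality-ratio profile of a cluster-count selection
#'
#' @param object a [select_n_clusters()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cluster_selection <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$c, y = .data$q)) +
    geom_line() +
    geom_point() +
    labs(x = "number of clusters", y = "quality ratio Q",
         title = sprintf("Cluster selection (c* = %d)", object$c_star)) +
    theme_minimal()
}

#' Plot a Kaplan-Meier estimate
#'
#' @param object a [km_estimate()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, n_risk = max(object$n_risk),
                         n_event = 0L, surv = 1), object)
  ggplot(df, aes(x = .data$time, y = .data$surv)) +
    geom_step() +
    labs(x = "time (days)", y = "survival probability",
         title = "Kaplan-Meier estimate") +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object a [roc_auc()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Plot a feature-ranking score decay
#'
#' NMI concordance score against rank within a layer; the characteristic
#' shape is a steep initial decline followed by a flat noise floor.
#'
#' @param object a [rank_features()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.feature_ranking <- function(object, ...) {
  ggplot(object, aes(x = .data$rank, y = .data$score)) +
    geom_line() +
    labs(x = "rank", y = "NMI score",
         title = sprintf("rSNF ranking (%s)", unique(object$layer))) +
    theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
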