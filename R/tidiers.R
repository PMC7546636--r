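# broom-style tidiers for fitted objects.

#' @describeIn fit_tails Long-form parameter table of a tail-fit report.
#' @param x A `tail_fit` object.
#' @param ... Unused.
#' @export
tidy.tail_fit <- function(x, ...) {
  tibble(
    term = c("k", "sigma", "mu", "beta", "theta", "gamma", "x_min"),
    estimate = c(x$k, x$sigma, x$mu, x$beta, x$theta, x$gamma, x$x_min)
  ) |> dplyr::filter(is.finite(.data$estimate))
}

#' @describeIn fit_tails One-row summary (verdict, tail size, KS).
#' @export
glance.tail_fit <- function(x, ...) {
  tibble(verdict = x$verdict, k = x$k, n_tail = x$n_tail, ks_gp = x$ks_gp)
}

#' @describeIn fit_cowe Ensemble weights per base learner.
#' @param x A `cowe_ensemble`.
#' @param ... Unused.
#' @export
tidy.cowe_ensemble <- function(x, ...) {
  tibble(learner = names(x$weights), weight = as.numeric(x$weights))
}

#' @describeIn fit_cowe One-row summary of the fitted ensemble.
#' @export
glance.cowe_ensemble <- function(x, ...) {
  tibble(
    n_learners_combined = length(x$weights),
    boosting_rounds = x$config$n_learners,
    learning_rate = x$config$learning_rate,
    cv_mse = x$cv_mse,
    solver = attr(x$weights, "solver")
  )
}

#' @describeIn loo_xv Per-subject decisions of the cross-validation.
#' @param x A `loo_result`.
#' @param ... Unused.
#' @export
tidy.loo_result <- function(x, ...) x$decisions

#' @describeIn loo_xv One-row metrics summary.
#' @export
glance.loo_result <- function(x, ...) x$metrics

#' @describeIn unsupervised_sgn_classifier Per-subject decisions.
#' @param x An `sgn_result`.
#' @param ... Unused.
#' @export
tidy.sgn_result <- function(x, ...) x$decisions

#' @describeIn unsupervised_sgn_classifier One-row metrics summary.
#' @export
glance.sgn_result <- function(x, ...) {
  x$metrics %||% tibble(n_subjects = nrow(x$decisions))
}

#' @describeIn run_cohort Combined tidy decisions of both classifiers.
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @export
tidy.cohort_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$loo$decisions, classifier = "cowe_loo"),
    dplyr::mutate(x$sgn$decisions, classifier = "sgn_k")
  )
}

#' @describeIn run_cohort Combined one-row-per-classifier metrics.
#' @export
glance.cohort_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$loo$metrics, classifier = "cowe_loo"),
    dplyr::mutate(x$sgn$metrics, classifier = "sgn_k")
  )
}
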