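# broom-style tidiers for fitted objects.

#' @describeIn cox_univariate Tidy the fit into one row per term.
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble(term = paste0("group", x$levels[2]),
         estimate = x$beta, std.error = x$se,
         statistic = if (is.na(x$se)) NA_real_ else x$beta / x$se,
         p.value = x$p_value,
         conf.low = log(x$ci_low), conf.high = log(x$ci_high))
}

#' @describeIn cox_univariate One-row model summary (hazard-ratio scale).
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event, hr = x$hr,
         hr_conf.low = x$ci_low, hr_conf.high = x$ci_high,
         p.value = x$p_value, converged = x$converged,
         separation = x$separation)
}

#' @describeIn logrank_test Tidy the test into a one-row tibble.
#' @param x A `logrank_test`.
#' @param ... Unused.
#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(statistic = x$chi2, df = 1, p.value = x$p_value)
}

#' @describeIn km_curve One-row summary per group: subjects, events and
#'   median survival time (first time the curve drops to 0.5 or below).
#' @param x A `km_fit`.
#' @param ... Unused.
#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  summarise_arm <- function(d) {
    med <- d$time[d$surv <= 0.5]
    tibble(n = max(d$n_risk), n_event = sum(d$n_event),
           median_survival = if (length(med) > 0) min(med) else NA_real_)
  }
  if ("group" %in% names(x)) {
    dplyr::group_modify(dplyr::group_by(as_tibble(x), .data$group),
                        ~ summarise_arm(.x)) |> dplyr::ungroup()
  } else {
    summarise_arm(x)
  }
}

#' @describeIn roc_cutoff Tidy the ROC curve (one row per cutoff).
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  x$curve
}

#' @describeIn roc_cutoff One-row summary with AUC and the optimal
#'   cutoff.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, cutoff = x$cutoff, sensitivity = x$sensitivity,
         specificity = x$specificity, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @describeIn cohort_table Tidy the test into a one-row tibble.
#' @param x A `cohort_test`.
#' @param ... Unused.
#' @method tidy cohort_test
#' @export
tidy.cohort_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p.value = x$p_value)
}
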