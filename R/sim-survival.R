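#' Configuration for the synthetic survival-cohort generator
#'
#' Two-group exponential survival with a group hazard ratio and
#' independent exponential censoring, emulating a high- versus
#' low-expression cohort comparison.
#'
#' @param n_per_group Subjects per group.
#' @param hazard_ratio Hazard of the `"high"` group relative to `"low"`.
#' @param baseline_rate Event rate of the `"low"` group (events per unit
#'   time).
#' @param censor_rate Rate of the independent censoring process; `0`
#'   disables censoring.
#' @param seed Integer seed.
#'
#' @return A validated `surv_sim_config` list.
#' @export
surv_sim_config <- function(n_per_group = 100L,
                            hazard_ratio = 2,
                            baseline_rate = 0.1,
                            censor_rate = 0.05,
                            seed = 1L) {
  structure(
    list(n_per_group = check_count(n_per_group, "n_per_group"),
         hazard_ratio = check_number(hazard_ratio, "hazard_ratio",
                                     min = 0, strict_min = TRUE),
         baseline_rate = check_number(baseline_rate, "baseline_rate",
                                      min = 0, strict_min = TRUE),
         censor_rate = check_number(censor_rate, "censor_rate", min = 0),
         seed = check_count(seed, "seed", min = 0L)),
    class = "surv_sim_config"
  )
}

#' Simulate a two-group survival table
#'
#' Event times are exponential with the `"low"` group at `baseline_rate`
#' and the `"high"` group at `baseline_rate * hazard_ratio`; censoring
#' times are independent exponential at `censor_rate`. The observed time
#' is the minimum of the two, and the event flag is 1 when the event
#' precedes (or ties) censoring.
#'
#' @param config A [surv_sim_config()].
#'
#' @return A tibble with columns `subject_id`, `group` (factor with levels
#'   `low`, `high`), `time` and `event` (0/1).
#' @export
simulate_survival <- function(config = surv_sim_config()) {
  stopifnot(inherits(config, "surv_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_per_group
    group <- factor(rep(c("low", "high"), each = n), levels = c("low", "high"))
    rate <- ifelse(group == "high",
                   config$baseline_rate * config$hazard_ratio,
                   config$baseline_rate)
    t_event <- rexp(2L * n, rate = rate)
    t_cens <- if (config$censor_rate > 0) {
      rexp(2L * n, rate = config$censor_rate)
    } else {
      rep(Inf, 2L * n)
    }
    tibble(
      subject_id = sprintf("subj_%04d", seq_len(2L * n)),
      group = group,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}
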