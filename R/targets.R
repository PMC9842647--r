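# Target-prioritization funnel: DEG x program intersection, group
# dichotomization, Kaplan-Meier / log-rank / Cox survival filtering.

check_survival_table <- function(data, need_group = FALSE) {
  if (!all(c("time", "event") %in% names(data))) {
    abort("Survival table needs columns `time` and `event`.")
  }
  if (any(data$time <= 0) || anyNA(data$time)) abort("All times must be > 0.")
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0/1.")
  if (need_group) {
    if (!"group" %in% names(data)) abort("Survival table needs a `group` column.")
    if (length(unique(data$group)) != 2) {
      abort("`group` must have exactly 2 levels.")
    }
  }
  invisible(data)
}

#' Intersect DEG and top-program gene lists
#'
#' Exact, case-sensitive set intersection of two candidate gene lists.
#'
#' @param deg_genes,program_top_genes Non-empty character vectors.
#' @return Character vector of shared genes (unique, input order of
#'   `deg_genes`).
#' @export
intersect_candidates <- function(deg_genes, program_top_genes) {
  if (length(deg_genes) == 0 || length(program_top_genes) == 0) {
    abort("Both gene lists must be non-empty.")
  }
  intersect(deg_genes, program_top_genes)
}

#' Dichotomize a numeric vector into high/low groups
#'
#' Default rule: `high` when the value strictly exceeds the median, `low`
#' otherwise (ties at the cut go to `low`). An explicit `cutoff` replaces
#' the median.
#'
#' @param values Numeric vector of length >= 4; constant vectors are
#'   rejected.
#' @param cutoff Optional explicit cut point.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(values, cutoff = NULL) {
  if (length(values) < 4) abort("Need >= 4 values to dichotomize.")
  if (anyNA(values)) abort("Missing values not allowed.")
  if (max(values) == min(values)) abort("Cannot dichotomize a constant vector.")
  cut_at <- cutoff %||% median(values)
  factor(ifelse(values > cut_at, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate of the survival function for one arm; censored
#' subjects leave the risk set after their recorded time, and S(0) = 1.
#'
#' @param data Tibble with columns `time` and `event` (optionally
#'   `group`, in which case one curve per group is computed).
#' @return A `km_fit` object: tibble with `group` (when present), `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(data) {
  check_survival_table(data)
  one_arm <- function(d) {
    ut <- sort(unique(d$time))
    n_risk <- vapply(ut, function(t) sum(d$time >= t), 0)
    n_event <- vapply(ut, function(t) sum(d$time == t & d$event == 1), 0)
    n_censor <- vapply(ut, function(t) sum(d$time == t & d$event == 0), 0)
    tibble(time = ut, n_risk = n_risk, n_event = n_event,
           n_censor = n_censor, surv = cumprod(1 - n_event / n_risk))
  }
  out <- if ("group" %in% names(data)) {
    dplyr::group_modify(dplyr::group_by(data, .data$group), ~ one_arm(.x)) |>
      dplyr::ungroup()
  } else {
    one_arm(data)
  }
  structure(out, class = c("km_fit", class(out)))
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom log-rank chi-square over the pooled event times,
#' with the hypergeometric variance at each event time. No events at all
#' gives `chi2 = 0, p = 1`.
#'
#' @param data Tibble with `time`, `event` and a 2-level `group`.
#' @return A `logrank_test` list: `chi2`, `p_value`, `observed`,
#'   `expected` (per group).
#' @export
logrank_test <- function(data) {
  check_survival_table(data, need_group = TRUE)
  g <- factor(data$group)
  ut <- sort(unique(data$time[data$event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at_risk <- data$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(data$time == t & data$event == 1)
    d1 <- sum(data$time == t & data$event == 1 & g == levels(g)[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (length(ut) == 0 || v == 0) {
    chi2 <- 0
    p <- 1
  } else {
    chi2 <- (o1 - e1)^2 / v
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  obs <- c(o1, sum(data$event) - o1)
  exp_ <- c(e1, sum(data$event) - e1)
  names(obs) <- names(exp_) <- levels(g)
  structure(list(chi2 = chi2, p_value = p, observed = obs, expected = exp_),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g (1 df), p = %.4g\n", x$chi2, x$p_value))
  invisible(x)
}

#' Univariate Cox proportional-hazards fit for a binary covariate
#'
#' Newton-Raphson maximization of the Cox partial likelihood with Breslow
#' tie handling. The hazard ratio contrasts the second factor level of
#' `group` against the first (`low` -> `high` for the default survival
#' tables). Convergence when `|delta beta| < 1e-8`, at most 50
#' iterations. Monotone likelihood (complete separation of events) is
#' flagged and returns an infinite HR bound.
#'
#' @param data Tibble with `time`, `event` and a 2-level `group`; both
#'   levels must carry at least one event between them.
#' @return A `cox_fit` list: `beta`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `n_event`, `converged`, `separation`.
#' @export
cox_univariate <- function(data) {
  check_survival_table(data, need_group = TRUE)
  g <- factor(data$group)
  x <- as.numeric(g) - 1
  if (sum(data$event) < 1) abort("Need at least one event.")
  # sort by decreasing time so risk-set sums are cumulative sums
  ord <- order(-data$time)
  time <- data$time[ord]
  event <- data$event[ord]
  x <- x[ord]
  ut <- unique(time[event == 1])
  # index of the last subject still at risk at each event time, and the
  # per-time event count / event covariate sum (Breslow ties)
  k_t <- vapply(ut, function(t) max(which(time >= t)), 0L)
  d_t <- vapply(ut, function(t) sum(event[time == t]), 0)
  dx_t <- vapply(ut, function(t) sum(x[time == t & event == 1]), 0)

  score_info <- function(beta) {
    w <- exp(beta * x)
    cw <- cumsum(w)
    cwx <- cumsum(w * x)
    s0 <- cw[k_t]
    s1 <- cwx[k_t]
    U <- sum(dx_t - d_t * s1 / s0)
    I <- sum(d_t * (s1 / s0) * (1 - s1 / s0))  # x binary: s2 = s1
    c(U = U, I = I)
  }

  beta <- 0
  converged <- FALSE
  separation <- FALSE
  for (it in 1:50) {
    si <- score_info(beta)
    if (si["I"] < 1e-12 || abs(beta) > 15) {
      separation <- TRUE
      break
    }
    delta <- si["U"] / si["I"]
    beta <- beta + delta
    if (abs(delta) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (separation) {
    hr <- exp(sign(beta) * Inf)
    out <- list(beta = sign(beta) * Inf, se = NA_real_, hr = hr,
                ci_low = if (beta > 0) 0 else 0,
                ci_high = Inf, p_value = NA_real_,
                n = nrow(data), n_event = sum(data$event),
                converged = FALSE, separation = TRUE,
                levels = levels(g))
    return(structure(out, class = "cox_fit"))
  }
  beta <- unname(beta)
  se <- unname(1 / sqrt(score_info(beta)["I"]))
  z <- beta / se
  structure(
    list(beta = as.numeric(beta), se = as.numeric(se), hr = exp(beta),
         ci_low = exp(beta - 1.959964 * se),
         ci_high = exp(beta + 1.959964 * se),
         p_value = 2 * pnorm(-abs(z)),
         n = nrow(data), n_event = sum(data$event),
         converged = converged, separation = FALSE, levels = levels(g)),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH (%s vs %s): HR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$levels[2], x$levels[1], x$hr, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Rank candidate target genes through the survival funnel
#'
#' For each candidate gene: dichotomize tumour-cohort expression at the
#' median, run the log-rank test and univariate Cox fit of high versus
#' low, and compute the tumour-versus-normal log2 fold change from the
#' supplied expression matrices. A gene passes when it is in both input
#' lists, its hazard ratio exceeds 1, the log-rank p is below `p_max` and
#' it is up-regulated in tumours.
#'
#' @param deg_genes,program_genes The two gene lists whose intersection
#'   defines the candidates.
#' @param tumor_expr Genes x subjects expression matrix for the survival
#'   cohort (rownames = genes, colnames = subject ids).
#' @param normal_expr Genes x samples expression matrix for normal
#'   tissue.
#' @param survival Tibble with `subject_id`, `time`, `event` covering the
#'   columns of `tumor_expr`.
#' @param p_max Log-rank p-value ceiling for the pass flag.
#' @param eps Pseudo-value in the fold-change ratio.
#' @return Tibble with one row per candidate, sorted by log-rank p:
#'   `gene_id`, `in_deg`, `in_program`, `km_logrank_p`, `cox_hr`,
#'   `cox_ci_low`, `cox_ci_high`, `cox_p`, `tumor_vs_normal_log_fc`,
#'   `pass`.
#' @export
rank_targets <- function(deg_genes, program_genes, tumor_expr, normal_expr,
                         survival, p_max = 0.05, eps = 1e-9) {
  candidates <- intersect_candidates(deg_genes, program_genes)
  empty_proto <- tibble(gene_id = character(), in_deg = logical(),
                        in_program = logical(), km_logrank_p = numeric(),
                        cox_hr = numeric(), cox_ci_low = numeric(),
                        cox_ci_high = numeric(), cox_p = numeric(),
                        tumor_vs_normal_log_fc = numeric(), pass = logical())
  if (length(candidates) == 0) return(empty_proto)
  if (!all(c("subject_id", "time", "event") %in% names(survival))) {
    abort("`survival` needs subject_id, time, event.")
  }
  tumor_expr <- check_matrix(tumor_expr, "tumor_expr")
  normal_expr <- check_matrix(normal_expr, "normal_expr")
  subj <- intersect(colnames(tumor_expr), survival$subject_id)
  if (length(subj) < 4) abort("Fewer than 4 subjects shared with `survival`.")
  surv <- survival[match(subj, survival$subject_id), ]

  rows <- purrr::map_dfr(candidates, function(gene) {
    if (!gene %in% rownames(tumor_expr) || !gene %in% rownames(normal_expr)) {
      return(tibble(gene_id = gene, in_deg = TRUE, in_program = TRUE,
                    km_logrank_p = NA_real_, cox_hr = NA_real_,
                    cox_ci_low = NA_real_, cox_ci_high = NA_real_,
                    cox_p = NA_real_, tumor_vs_normal_log_fc = NA_real_,
                    pass = FALSE))
    }
    vals <- tumor_expr[gene, subj]
    lfc_ratio <- (mean(vals) + eps) / (mean(normal_expr[gene, ]) + eps)
    lfc <- if (lfc_ratio > 0) log2(lfc_ratio) else NA_real_
    grp <- tryCatch(dichotomize(vals), error = function(e) NULL)
    if (is.null(grp)) {
      return(tibble(gene_id = gene, in_deg = TRUE, in_program = TRUE,
                    km_logrank_p = NA_real_, cox_hr = NA_real_,
                    cox_ci_low = NA_real_, cox_ci_high = NA_real_,
                    cox_p = NA_real_, tumor_vs_normal_log_fc = lfc,
                    pass = FALSE))
    }
    d <- tibble(time = surv$time, event = surv$event, group = grp)
    lr <- logrank_test(d)
    cx <- cox_univariate(d)
    tibble(gene_id = gene, in_deg = TRUE, in_program = TRUE,
           km_logrank_p = lr$p_value, cox_hr = cx$hr,
           cox_ci_low = cx$ci_low, cox_ci_high = cx$ci_high,
           cox_p = cx$p_value, tumor_vs_normal_log_fc = lfc,
           pass = !is.na(cx$hr) & cx$hr > 1 & lr$p_value < p_max &
             !is.na(lfc) & lfc > 0)
  })
  dplyr::arrange(rows, .data$km_logrank_p)
}
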