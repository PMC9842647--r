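test_that("candidate intersection is an exact set operation", {
  expect_equal(intersect_candidates(c("a", "b"), c("c", "d")), character(0))
  expect_equal(intersect_candidates(c("a", "b"), c("b", "a")), c("a", "b"))
  expect_error(intersect_candidates(character(0), "a"), "non-empty")

  # lists planted to share exactly 37 genes
  shared <- sprintf("shared_%02d", 1:37)
  degs <- c(shared, sprintf("deg_%03d", 1:150))
  prog <- c(sprintf("prog_%03d", 1:80), shared)
  expect_length(intersect_candidates(degs, prog), 37L)
})

test_that("dichotomization splits at the median with ties to low", {
  g <- dichotomize(1:10)
  expect_equal(sum(g == "high"), 5L)
  expect_equal(sum(g == "low"), 5L)
  expect_error(dichotomize(rep(3, 10)), "constant")
  expect_error(dichotomize(c(1, 2, 3)), ">= 4")
  # explicit cutoff rule
  g2 <- dichotomize(c(1, 5, 6, 10), cutoff = 5)
  expect_equal(as.character(g2), c("low", "low", "high", "high"))
  # group sizes differ by at most 1 for distinct values
  set.seed(12)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    g3 <- dichotomize(sample(seq_len(1000), n))
    expect_lte(abs(sum(g3 == "high") - sum(g3 == "low")), 1L)
  }
})

test_that("the product-limit curve matches closed forms and a hand oracle", {
  no_events <- tibble::tibble(time = c(2, 5, 9), event = 0)
  expect_true(all(km_curve(no_events)$surv == 1))

  all_events <- tibble::tibble(time = 1:3, event = 1)
  expect_equal(km_curve(all_events)$surv, c(2 / 3, 1 / 3, 0))

  # censoring pattern: event at 1, censored at 2 (x2), event at 3
  mixed <- tibble::tibble(time = c(1, 2, 2, 3), event = c(1, 0, 0, 1))
  km <- km_curve(mixed)
  expect_equal(km$surv[km$time == 1], 3 / 4)
  expect_equal(km$surv[km$time == 3], 0)

  # no censoring: KM equals the empirical survival function exactly
  set.seed(3)
  t <- rexp(40)
  km2 <- km_curve(tibble::tibble(time = t, event = 1))
  emp <- vapply(km2$time, function(u) mean(t > u), 0)
  expect_equal(km2$surv, emp, tolerance = 1e-12)
})

test_that("km_curve agrees with survival::survfit under censoring", {
  skip_if_not_installed("survival")
  d <- simulate_survival(surv_sim_config(seed = 19))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = d[c("time", "event")])
  km <- km_curve(d[c("time", "event")])
  expect_equal(km$surv, sf$surv, tolerance = 1e-12)
})

test_that("log-rank statistic matches the hand computation on six subjects", {
  d <- tibble::tibble(time = c(1, 2, 3, 4, 5, 6),
                      event = c(1, 1, 1, 1, 0, 1),
                      group = c("a", "b", "a", "b", "a", "b"))
  lr <- logrank_test(d)
  # hand computation of observed - expected and hypergeometric variance
  o1 <- 2
  e1 <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 0
  v <- (3 / 6) * (3 / 6) + (2 / 5) * (3 / 5) + (2 / 4) * (2 / 4) +
    (1 / 3) * (2 / 3) + 0
  expect_equal(unname(lr$observed["a"]), o1)
  expect_equal(unname(lr$expected["a"]), e1, tolerance = 1e-12)
  expect_equal(lr$chi2, (o1 - e1)^2 / v, tolerance = 1e-12)

  # label swap leaves the statistic unchanged
  d2 <- dplyr::mutate(d, group = ifelse(group == "a", "b", "a"))
  expect_equal(logrank_test(d2)$chi2, lr$chi2, tolerance = 1e-12)

  # duplicated data across both groups: no separation
  dup <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = 1,
                        group = rep(c("a", "b"), each = 3))
  expect_equal(logrank_test(dup)$chi2, 0)
  expect_equal(logrank_test(dup)$p_value, 1)

  # no events at all
  none <- tibble::tibble(time = 1:4, event = 0,
                         group = rep(c("a", "b"), 2))
  expect_equal(logrank_test(none)$p_value, 1)
})

test_that("log-rank agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  for (s in 1:3) {
    d <- simulate_survival(surv_sim_config(n_per_group = 80, seed = s))
    ref <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    expect_equal(logrank_test(d)$chi2, ref$chisq, tolerance = 1e-8)
  }
})

test_that("Cox fit matches closed forms, a grid search, and coxph", {
  # identical groups: HR = 1
  dup <- tibble::tibble(time = rep(c(1, 2, 3, 4), 2), event = 1,
                        group = rep(c("a", "b"), each = 4))
  expect_equal(cox_univariate(dup)$hr, 1, tolerance = 1e-6)

  # four subjects, no ties: grid-search the Breslow partial likelihood
  d2 <- tibble::tibble(time = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
                       group = c("a", "b", "a", "b"))
  fit <- cox_univariate(d2)
  # x = 1 for group "b"; failures at t = 1 (x=0), 2 (x=1), 3 (x=0)
  pl <- function(beta) {
    -log(2 + 2 * exp(beta)) + (beta - log(1 + 2 * exp(beta))) +
      (0 - log(1 + exp(beta)))
  }
  grid <- seq(-5, 5, by = 1e-3)
  expect_equal(fit$beta, grid[which.max(vapply(grid, pl, 0))],
               tolerance = 2e-3)

  skip_if_not_installed("survival")
  d <- simulate_survival(surv_sim_config(n_per_group = 150, seed = 9))
  d$time <- round(d$time, 1) + 0.05  # introduce ties
  ref <- survival::coxph(survival::Surv(time, event) ~ group, data = d,
                         ties = "breslow")
  mine <- cox_univariate(d)
  expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(mine$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-7)
  expect_equal(glance(mine)$hr, exp(unname(coef(ref))), tolerance = 1e-6)
})

test_that("complete separation is flagged with an infinite HR bound", {
  d <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                      event = c(1, 1, 1, 0, 0, 0),
                      group = rep(c("high", "low"), each = 3))
  fit <- cox_univariate(d)
  expect_true(fit$separation)
  expect_true(is.infinite(fit$ci_high) || is.infinite(fit$hr))
})

test_that("Cox and log-rank agree in direction on significant fixtures", {
  hits <- 0
  for (s in 1:10) {
    d <- simulate_survival(surv_sim_config(n_per_group = 100,
                                           hazard_ratio = 2.5, seed = s))
    lr <- logrank_test(d)
    if (lr$p_value < 0.05) {
      hits <- hits + 1
      cx <- cox_univariate(d)
      km <- km_curve(d)
      # evaluate both step curves at the earlier of the two groups' last
      # event times, where both are still estimated
      surv_at <- function(g, t) {
        s <- km$surv[km$group == g & km$time <= t]
        if (length(s) == 0) 1 else min(s)
      }
      t_star <- min(tapply(d$time[d$event == 1], d$group[d$event == 1], max))
      expect_equal(unname(cx$hr > 1),
                   surv_at("high", t_star) < surv_at("low", t_star))
    }
  }
  expect_gt(hits, 0)
})

test_that("the target funnel passes exactly the planted gene", {
  set.seed(77)
  n_sub <- 200
  genes <- sprintf("cand_%02d", 1:20)
  tumor <- matrix(rnorm(20 * n_sub) + 5, 20, n_sub,
                  dimnames = list(genes, sprintf("s%03d", 1:n_sub)))
  normal <- matrix(rnorm(20 * 50) + 5, 20, 50, dimnames = list(genes, NULL))
  # planted target: strong survival effect and tumour up-regulation
  target <- "cand_07"
  normal[target, ] <- normal[target, ] - 2
  high <- tumor[target, ] > median(tumor[target, ])
  time <- rexp(n_sub, rate = 0.05 * ifelse(high, 3, 1))
  surv <- tibble::tibble(subject_id = colnames(tumor), time = time, event = 1L)
  res <- rank_targets(genes, genes, tumor, normal, surv)
  expect_true(res$pass[res$gene_id == target])
  expect_equal(res$gene_id[1], target)  # sorted by log-rank p
  expect_lte(sum(res$pass), 2)  # at most chance-level false passes

  # invariant: pass implies all filter conditions
  ok <- res$pass
  expect_true(all(res$cox_hr[ok] > 1))
  expect_true(all(res$km_logrank_p[ok] < 0.05))
  expect_true(all(res$tumor_vs_normal_log_fc[ok] > 0))
})

test_that("the funnel controls false passes under a global null", {
  set.seed(31)
  n_sub <- 100
  genes <- sprintf("null_%02d", 1:40)
  tumor <- matrix(rnorm(40 * n_sub) + 5, 40, n_sub,
                  dimnames = list(genes, sprintf("s%03d", 1:n_sub)))
  normal <- matrix(rnorm(40 * 30) + 5, 40, 30, dimnames = list(genes, NULL))
  surv <- tibble::tibble(subject_id = colnames(tumor),
                         time = rexp(n_sub, 0.1), event = 1L)
  res <- rank_targets(genes, genes, tumor, normal, surv)
  # pass requires p < 0.05 AND HR > 1 AND upregulation: well below 0.05 each
  expect_lte(sum(res$pass), ceiling(0.05 * length(genes)) + 2)

  # empty intersection yields an empty result, not an error
  empty <- rank_targets("only_in_deg", "only_in_prog", tumor, normal, surv)
  expect_equal(nrow(empty), 0L)
  # a candidate absent from the matrices is carried with pass = FALSE
  absent <- rank_targets("absent_gene", "absent_gene", tumor, normal, surv)
  expect_equal(nrow(absent), 1L)
  expect_false(absent$pass)
})
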