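# Cohort-1 (n = 29) and cohort-2 (n = 293) contingency tables, as counts
# of high/low marker expression by clinical category.
cohort1_tables <- list(
  age = matrix(c(9, 12, 5, 3), 2),
  gender = matrix(c(16, 5, 8, 0), 2),
  fuhrman = matrix(c(12, 9, 6, 2), 2),
  tnm = matrix(c(16, 5, 7, 1), 2),
  os5 = matrix(c(17, 4, 2, 6), 2)
)
cohort2_tables <- list(
  age = matrix(c(69, 43, 113, 68), 2),
  gender = matrix(c(77, 35, 114, 67), 2),
  fuhrman = matrix(c(89, 23, 150, 31), 2),
  tnm = matrix(c(94, 18, 164, 17), 2)
)

test_that("Fisher exact p-values reproduce the small-cohort references to 4 dp", {
  expected <- c(age = 0.4270, gender = 0.2832, fuhrman = 0.6706,
                tnm = 0.6472, os5 = 0.0089)
  for (nm in names(cohort1_tables)) {
    expect_equal(round(fisher_exact_2x2(cohort1_tables[[nm]]), 4),
                 unname(expected[nm]))
  }
})

test_that("Fisher p equals brute-force enumeration and respects symmetries", {
  tabs <- list(matrix(c(3, 2, 1, 5), 2), matrix(c(1, 1, 1, 1), 2),
               matrix(c(0, 4, 6, 2), 2), matrix(c(5, 0, 0, 5), 2),
               matrix(c(2, 7, 3, 4), 2))
  for (m in tabs) {
    expect_equal(fisher_exact_2x2(m), fisher_enum_p(m), tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  # simultaneous row and column swap leaves p unchanged
  m <- matrix(c(9, 3, 2, 8), 2)
  expect_equal(fisher_exact_2x2(m), fisher_exact_2x2(m[2:1, 2:1]),
               tolerance = 1e-12)
  # zero margin
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1)
})

test_that("chi-square p-values reproduce the large-cohort references to 4 dp", {
  expected <- c(age = 0.8877, gender = 0.3140, fuhrman = 0.4646,
                tnm = 0.0867)
  for (nm in names(cohort2_tables)) {
    expect_equal(round(chi_square_2x2(cohort2_tables[[nm]])$p_value, 4),
                 unname(expected[nm]))
  }
})

test_that("chi-square is transpose-invariant and exact on proportional tables", {
  m <- matrix(c(20, 10, 40, 20), 2)  # perfectly proportional
  res <- chi_square_2x2(m)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  m2 <- cohort2_tables$tnm
  expect_equal(chi_square_2x2(m2)$chi2, chi_square_2x2(t(m2))$chi2,
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "fisher")
})

test_that("H-score follows the weighted-percentage formula and its bounds", {
  expect_equal(h_score(c(0, 0, 0, 100)), 300)
  expect_equal(h_score(c(100, 0, 0, 0)), 0)
  expect_equal(h_score(c(25, 25, 25, 25)), 150)
  # linear in the fractions
  a <- c(40, 30, 20, 10)
  b <- c(10, 20, 30, 40)
  expect_equal(h_score((a + b) / 2), (h_score(a) + h_score(b)) / 2)
  # bounds attained only at pure-class corners
  expect_lt(h_score(c(0, 0, 1, 99)), 300)
  expect_gt(h_score(c(99, 1, 0, 0)), 0)
  expect_error(h_score(c(50, 10, 10, 10)), "sum to 100")
  df <- data.frame(negative = c(0, 100), low_positive = 0, positive = 0,
                   high_positive = c(100, 0))
  expect_equal(h_score(df), c(300, 0))
})

test_that("ROC handles separation, the null, and matches pair concordance", {
  sep <- roc_cutoff(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1)
  expect_gt(sep$cutoff, 3)
  expect_lt(sep$cutoff, 11)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  set.seed(14)
  null_roc <- roc_cutoff(rnorm(1000), rbinom(1000, 1, 0.5))
  expect_lt(abs(null_roc$auc - 0.5), 0.05)

  # exhaustive pair-concordance oracle on small inputs, with ties
  set.seed(8)
  for (i in 1:10) {
    sc <- sample(1:5, 8, replace = TRUE)
    out <- c(0, 0, 0, 0, 1, 1, 1, 1)
    expect_equal(roc_cutoff(sc, out)$auc, auc_enum(sc, out),
                 tolerance = 1e-12)
  }
  expect_error(roc_cutoff(1:4, c(1, 1, 1, 1)), "Both")
})

test_that("ROC AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- rnorm(60)
  out <- rbinom(60, 1, plogis(sc))
  mine <- roc_cutoff(sc, out)
  ref <- suppressMessages(pROC::roc(out, sc))
  expect_equal(mine$auc, as.numeric(ref$auc), tolerance = 1e-10)
})

test_that("cohort_table picks the conventional test and reproduces references", {
  expand_records <- function(m, cat_levels, grp_levels) {
    data.frame(
      category = rep(rep(cat_levels, 2), times = as.vector(m)),
      group = rep(grp_levels, each = 2)[rep(1:4, as.vector(m))]
    )
  }
  # small cohort gender: expected count < 5 selects Fisher
  rec1 <- expand_records(cohort1_tables$gender, c("male", "female"),
                         c("high", "low"))
  res1 <- cohort_table(rec1, "category", "group")
  expect_equal(res1$test, "fisher")
  expect_equal(round(res1$p_value, 4), 0.2832)

  # large cohort gender: chi-square
  rec2 <- expand_records(cohort2_tables$gender, c("male", "female"),
                         c("high", "low"))
  res2 <- cohort_table(rec2, "category", "group")
  expect_equal(res2$test, "chi-square")
  expect_equal(round(res2$p_value, 4), 0.3140)

  # tabulation equals direct counting on synthetic records
  set.seed(3)
  rec3 <- data.frame(category = sample(c("yes", "no"), 60, TRUE),
                     group = sample(c("high", "low"), 60, TRUE))
  res3 <- cohort_table(rec3, "category", "group")
  expect_equal(sum(res3$table), 60)
  expect_equal(res3$table["yes", "high"],
               sum(rec3$category == "yes" & rec3$group == "high"))
  expect_error(cohort_table(data.frame(category = c("a", "b", "c"),
                                       group = c("x", "y", "x")),
                            "category", "group"),
               "2 levels")
})

test_that("tidiers return one-row summaries for clinical results", {
  roc <- roc_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  g <- glance(roc)
  expect_equal(g$auc, 1)
  expect_named(tidy(roc), c("cutoff", "sensitivity", "specificity"))
  ct <- cohort_table(data.frame(category = rep(c("a", "b"), 30),
                                group = rep(c("x", "y"), each = 30)),
                     "category", "group")
  expect_equal(tidy(ct)$p.value, ct$p_value)
})
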