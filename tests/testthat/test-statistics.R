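test_that("Kruskal-Wallis matches the rank-sum formula and is symmetric", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  out <- kruskal_wallis(g)
  expect_equal(out$statistic, 7.2)
  expect_equal(out$df, 2)
  # identical samples degenerate to H = 0, p = 1
  same <- kruskal_wallis(list(rep(2, 4), rep(2, 4), rep(2, 4)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  # permuting group order leaves H unchanged
  expect_equal(kruskal_wallis(g[c(3, 1, 2)])$statistic, out$statistic)
  # with ties, the statistic matches the hand formula
  set.seed(31)
  gt <- list(round(rnorm(12), 1), round(rnorm(9), 1), round(rnorm(15), 1))
  expect_equal(kruskal_wallis(gt)$statistic, kw_by_hand(gt))
  expect_error(kruskal_wallis(list(1:3)), "at least two")
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(32)
  g <- list(rnorm(10), rnorm(12, 0.5), rnorm(8, 1))
  h0 <- kruskal_wallis(g)$statistic
  for (f in list(exp, function(x) x^3, function(x) atan(x) * 5 + 100)) {
    expect_equal(kruskal_wallis(lapply(g, f))$statistic, h0)
  }
})

test_that("chi-square matches the 2x2 closed form and is transpose-invariant", {
  tab <- matrix(c(20, 10, 10, 20), 2)
  out <- chi_square(tab)
  # closed form n (ad - bc)^2 / (row and column products)
  expect_equal(out$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30))
  expect_equal(out$statistic, 6.667, tolerance = 1e-3)
  expect_equal(out$df, 1)
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi_square(t(tab))$statistic, out$statistic)
  set.seed(33)
  r <- matrix(rpois(4, 15) + 1, 2)
  n <- sum(r)
  closed <- n * (r[1, 1] * r[2, 2] - r[1, 2] * r[2, 1])^2 /
    prod(rowSums(r)) / prod(colSums(r))
  expect_equal(chi_square(r)$statistic, closed)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
  expect_error(chi_square(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("BH step-up matches direct enumeration and behaves at the extremes", {
  out <- bh_adjust(c(0.001, 0.008, 0.039, 0.041), q = 0.01)
  expect_equal(sum(out$reject), 1)
  expect_true(out$reject[1])
  expect_true(all(bh_adjust(rep(0, 5), 0.01)$reject))
  expect_false(any(bh_adjust(rep(1, 5), 0.01)$reject))
  # adjusted values are monotone in p
  set.seed(34)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- runif(1, 0.005, 0.2)
    out <- bh_adjust(p, q)
    expect_equal(out$reject, bh_by_hand(p, q))
    o <- order(p)
    expect_true(all(diff(out$p_adjusted[o]) >= -1e-12))
  }
  expect_error(bh_adjust(numeric(0)), "Empty")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH rejections are non-decreasing in the FDR level", {
  set.seed(35)
  p <- c(runif(30, 0, 0.02), runif(30))
  qs <- c(0.001, 0.01, 0.05, 0.1, 0.25)
  rej <- vapply(qs, function(q) sum(bh_adjust(p, q)$reject), numeric(1))
  expect_true(all(diff(rej) >= 0))
})

test_that("the default comparison family has 87 tests on the standard cohort", {
  cc <- cohort_config(n_per_group = 10, seed = 16)
  cmp <- compare_groups(generate_cohort_metrics(cc),
                        generate_demographics(cc))
  expect_equal(cmp$family_size, 87)
  res <- tidy(cmp)
  # 60 regional + 5 whole-lung omnibus, 15 whole-lung pairwise, 7 demographic
  expect_equal(sum(res$test == "kruskal_wallis" & res$region != "demographics"), 65)
  expect_equal(sum(res$in_family & res$test == "pairwise_rank"), 15)
  expect_equal(sum(res$region == "demographics"), 7)
  expect_equal(sum(res$region == "demographics" & res$test == "chi_square"), 2)
  # every emitted test joins the family under family = "all"
  cmp_all <- compare_groups(generate_cohort_metrics(cc),
                            generate_demographics(cc), family = "all")
  expect_equal(cmp_all$family_size, nrow(tidy(cmp_all)))
  expect_gt(cmp_all$family_size, 87)
})

test_that("identical groups yield zero rejections and constant inputs do not crash", {
  m <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:30),
                          variable = "Emph", region = "whole")
  m$group <- rep(c("healthy", "asthma", "COPD"), each = 10)[
    match(m$subject_id, sprintf("s%02d", 1:30))]
  m$value <- 3.7
  cmp <- compare_groups(m, q = 0.01)
  expect_equal(cmp$n_rejected, 0)
  res <- tidy(cmp)
  expect_true(all(res$p_value == 1))
})

test_that("variables observed in fewer than two groups are skipped with a log entry", {
  m <- tibble::tibble(subject_id = sprintf("s%d", 1:10), group = "healthy",
                      variable = "ADI", region = "whole",
                      value = rnorm(10))
  expect_message(cmp <- compare_groups(m), "Skipped")
  expect_equal(nrow(tidy(cmp)), 0)
})

test_that("strong configured effects are flagged with the figure footnote marks", {
  cc <- cohort_config(n_per_group = 60, seed = 17)
  cmp <- compare_groups(generate_cohort_metrics(cc),
                        generate_demographics(cc))
  res <- tidy(cmp)
  fsad <- res[res$variable == "fSAD" & res$region == "whole" &
                res$test == "pairwise_rank", ]
  expect_setequal(fsad$mark, c("*", "†", "‡"))
  g <- glance(cmp)
  expect_equal(g$family_size, 87)
  expect_gt(g$n_rejected, 0)
  rep <- report_markdown(cmp)
  expect_true(any(grepl("healthy vs asthma", rep)))
  expect_true(any(grepl("†", rep)))
})
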