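test_that("metadata binning follows the stated boundaries", {
  meta <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                         age = c(20, 24.9, 25, 49, 49.9, 47),
                         bmi = c(18.49, 18.5, 24.99, 25, 30, 16))
  b <- bin_metadata(meta, age_start = 20)
  expect_equal(as.character(b$age_bin[1:3]),
               c("[20,25)", "[20,25)", "[25,30)"))
  expect_equal(as.character(b$age_bin[4:5]), c("[45,50]", "[45,50]"))
  expect_equal(as.character(b$bmi_bin),
               c("underweight", "normal", "normal", "obese", "obese",
                 "underweight"))
  expect_equal(nlevels(b$age_bin), 6)

  # out-of-span ages are flagged, not dropped
  meta2 <- tibble::tibble(sample_id = c("a", "b"), age = c(20, 80), bmi = 22)
  expect_warning(b2 <- bin_metadata(meta2, age_start = 20), "outside")
  expect_equal(attr(b2, "out_of_range"), "b")
  expect_true(is.na(b2$age_bin[2]))
})

test_that("two-group tests behave at the null and under separation", {
  set.seed(2)
  x <- rnorm(20); g <- rep(c("A", "B"), 10)
  same <- two_group_test(rep(x, 1), g, "whites", seed = 1)
  expect_gt(same$p_value, 0.01)
  expect_true(same$conf_low <= 0 || abs(same$conf_low) < 1)

  vals <- c(rnorm(20), rnorm(20, 3))
  lab <- rep(c("A", "B"), each = 20)
  for (m in c("wilcoxon", "whites")) {
    res <- two_group_test(vals, lab, m, seed = 2)
    expect_lt(res$p_value, 0.01)
    expect_lt(res$estimate, 0)
  }
  expect_error(two_group_test(vals, rep("A", 40)), "two groups")
})

test_that("the permutation test is calibrated and bounded below", {
  set.seed(7)
  reps <- 200
  p <- vapply(seq_len(reps), function(i) {
    v <- rnorm(24)
    two_group_test(v, rep(c("A", "B"), each = 12), "whites",
                   permutations = 199, boots = 50, seed = i)$p_value
  }, 0)
  typeI <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(typeI - 0.05), 3 * se + 1e-9)
  expect_true(all(p >= 1 / 200))
})

test_that("KW statistic, eta squared and post hoc match first principles", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  bins <- rep(c("a", "b", "c"), each = 3)
  res <- multi_group_test(vals, bins)
  # untied data: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  r <- rank(vals); rb <- tapply(r, bins, mean)
  h <- 12 / (9 * 10) * sum(3 * (rb - 5)^2)
  expect_equal(res$test$statistic, h, tolerance = 1e-10)
  expect_equal(res$test$eta_squared, (h - 3 + 1) / (9 - 3), tolerance = 1e-10)
  expect_equal(nrow(res$posthoc), 3)

  # identical group distributions: H ~ 0, eta^2 = -(k-1)/(n-k) -> 0 with n
  flat <- multi_group_test(rep(1:10, 3), rep(c("a", "b", "c"), each = 10))
  expect_lt(abs(flat$test$eta_squared), 0.1)
  expect_error(multi_group_test(vals, rep(c("a", "b"), c(5, 4))), "3 groups")
})

test_that("Tukey-Kramer flags exactly the contrasts involving a shifted group", {
  set.seed(12)
  vals <- c(rnorm(15), rnorm(15), rnorm(15, 8))
  bins <- rep(c("g1", "g2", "g3"), each = 15)
  res <- multi_group_test(vals, bins)
  ph <- res$posthoc
  with_g3 <- grepl("g3", ph$group1) | grepl("g3", ph$group2)
  expect_true(all(ph$significant[with_g3]))
  expect_false(any(ph$significant[!with_g3]))
})

test_that("trend summaries recover monotone structure and planted links", {
  # strictly increasing bin medians -> rho 1
  m <- rbind(up = rep(c(1, 2, 3, 4), each = 3) + 0,
             flat = rep(5, 12))
  colnames(m) <- sprintf("s%d", 1:12)
  bins <- stats::setNames(factor(rep(1:4, each = 3), ordered = TRUE),
                          colnames(m))
  tr <- trend_summary(tiny_table(m), bins)
  expect_equal(tr$rho[tr$feature_id == "up"], 1)
  expect_equal(tr$direction[tr$feature_id == "up"], "increasing")
  expect_equal(tr$direction[tr$feature_id == "flat"], "none")

  # a generator metadata link is recovered with its planted direction
  ml <- tibble::tibble(feature = 4, covariate = "bmi",
                       direction = "decreasing", rho = 0.5)
  sim <- generate_cohorts(cohort_spec(n_samples = c(TR = 60, UR = 60),
                                      n_features = 30, metadata_links = ml,
                                      seed = 23))
  b <- suppressWarnings(bin_metadata(sim$metadata))
  rel <- to_relative(sim$table)
  tr2 <- trend_summary(rel, stats::setNames(b$bmi_bin, b$sample_id))
  expect_equal(tr2$direction[tr2$feature_id == "OTU_004"], "decreasing")
})

test_that("shuffled bins rarely produce a trend call", {
  set.seed(31)
  hits <- vapply(1:40, function(i) {
    m <- matrix(rpois(5 * 24, 30), 5, 24,
                dimnames = list(sprintf("f%d", 1:5), sprintf("s%d", 1:24)))
    bins <- factor(sample(rep(1:4, each = 6)), ordered = TRUE)
    tr <- trend_summary(tiny_table(m), stats::setNames(bins, colnames(m)))
    sum(tr$direction != "none")
  }, 0)
  expect_lt(mean(hits > 0), 0.1)
})
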