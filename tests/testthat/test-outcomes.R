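test_that("MVC averaging follows the three-trial, two-limb protocol", {
  expect_equal(average_mvc(c(100, 110, 120), c(100, 110, 120), 50), 2.2)
  expect_equal(average_mvc(rep(90, 3), rep(110, 3), 50), 2.0)
  # identical limbs reduce to single-limb mean over mass
  expect_equal(average_mvc(c(95, 100, 105), c(95, 100, 105), 40), 100 / 40)
  expect_warning(average_mvc(c(100, 110), c(100, 110, 120), 50),
                 "3 trials")
})

test_that("IQR fences flag exactly the points beyond 1.5 x IQR", {
  # identical values: fences collapse onto the value, nothing flagged
  expect_false(any(iqr_outliers(rep(5, 6))$outlier))
  # the trial's own screening case: one wildly high cost of transport
  v <- c(4.0, 4.5, 5.0, 5.5, 6.0, 16.9)
  res <- iqr_outliers(v)
  expect_identical(which(res$outlier), 6L)
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(res$upper, q[2] + 1.5 * (q[2] - q[1]), tolerance = 1e-12)
  # a single low extreme in otherwise symmetric data
  v2 <- c(-20, 9, 10, 10, 11, 12)
  expect_identical(which(iqr_outliers(v2)$outlier), 1L)
  expect_warning(iqr_outliers(c(1, 2, 3)), "Fewer than 4")
})

test_that("IQR screening never flags interior points by construction", {
  withr::with_seed(3, {
    for (i in 1:20) {
      v <- runif(8, 10, 11) # max - min below any 1.5 IQR excess
      f <- iqr_outliers(v)
      expect_true(all(v[!f$outlier] >= f$lower & v[!f$outlier] <= f$upper))
      inside <- v >= f$lower & v <= f$upper
      expect_identical(f$outlier, !inside)
    }
  })
})

test_that("Lilliefors test is calibrated under normality and rejects skew", {
  rejections <- withr::with_seed(101, {
    sapply(1:200, function(i) {
      lilliefors_normality(rnorm(25), n_mc = 2000, seed = i)$p_value < 0.05
    })
  })
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.08)
  power <- withr::with_seed(102, {
    sapply(1:60, function(i) {
      lilliefors_normality(rexp(50), n_mc = 1000, seed = i)$p_value < 0.05
    })
  })
  expect_gt(mean(power), 0.5)
  # runs and stays in [0, 1] at the study's n = 6
  p6 <- lilliefors_normality(c(2.1, 1.8, 2.5, 2.2, 1.9, 2.4), seed = 1)
  expect_gte(p6$p_value, 0)
  expect_lte(p6$p_value, 1)
  deg <- lilliefors_normality(rep(2, 6), seed = 1)
  expect_true(deg$degenerate)
  expect_identical(deg$p_value, 0)
})

test_that("Lilliefors p-values track the reference implementation", {
  withr::with_seed(103, {
    for (i in 1:5) {
      x <- rnorm(30) + rexp(30) * (i %% 2)
      ours <- lilliefors_normality(x, n_mc = 10000, seed = i)
      ref <- nortest::lillie.test(x)
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_lt(abs(ours$p_value - ref$p.value), 0.05)
    }
  })
})

test_that("paired t matches the textbook formula including degenerate cases", {
  pre <- c(1, 2, 3, 4)
  post <- c(3, 6, 9, 12) # diffs 2, 4, 6, 8
  res <- paired_t(pre, post)
  oracle <- textbook_paired_t(pre, post)
  expect_equal(res$t, oracle$t, tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  expect_identical(res$df, 3)
  expect_equal(res$t, 5 / (sd(c(2, 4, 6, 8)) / 2), tolerance = 1e-10)
  # random-input property against the independent formula
  withr::with_seed(11, {
    for (i in 1:25) {
      n <- sample(3:12, 1)
      a <- rnorm(n)
      b <- a + rnorm(n, 0.3)
      got <- paired_t(a, b)
      want <- textbook_paired_t(a, b)
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$p_value, want$p, tolerance = 1e-10)
    }
  })
  same <- paired_t(pre, pre)
  expect_identical(same$t, 0)
  expect_identical(same$p_value, 1)
  shift <- paired_t(pre, pre + 1)
  expect_true(shift$degenerate)
  expect_identical(shift$p_value, 0)
  expect_error(paired_t(1, 2), class = "exoresist_invalid_argument")
})

test_that("Holm-Bonferroni matches the step-down definition", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04),
               tolerance = 1e-12)
  expect_equal(holm_bonferroni(rep(1, 4)), rep(1, 4))
  withr::with_seed(12, {
    for (i in 1:25) {
      p <- runif(sample(2:8, 1))
      adj <- holm_bonferroni(p)
      expect_equal(adj, textbook_holm(p), tolerance = 1e-12)
      expect_true(all(adj >= p))
      expect_true(!is.unsorted(adj[order(p)]))
    }
  })
  expect_error(holm_bonferroni(c(0.2, 1.4)),
               class = "exoresist_invalid_argument")
})

test_that("Cohen's d variants match hand computation and flip with sign", {
  pre <- c(1, 2, 3, 4)
  post <- c(3, 6, 9, 12)
  expect_equal(cohens_d(pre, post, "dz"), 5 / sd(c(2, 4, 6, 8)),
               tolerance = 1e-10)
  expect_equal(cohens_d(pre, post, "dav"),
               5 / mean(c(sd(pre), sd(post))), tolerance = 1e-10)
  expect_equal(cohens_d(post, pre, "dz"), -cohens_d(pre, post, "dz"),
               tolerance = 1e-12)
  expect_identical(cohens_d(pre, pre), 0)
})

test_that("trial analysis removes planted outliers and reports missing data", {
  coh <- generate_cohort(6, null_effects(noise_cv = 0.02), seed = 40)
  tab <- coh$outcomes
  # plant the trial's hallmark artefact: an absurd pre-assessment CoT
  tab$pre[tab$measure == "cot" & tab$participant == "S3"] <- 16.9
  # and one missed post-assessment walk test
  tab$post[tab$measure == "sixmwt" & tab$participant == "S4"] <- NA
  fit <- analyze_trial(tab, normality = FALSE)
  res <- tidy(fit)
  cot <- res[res$measure == "cot", ]
  expect_identical(cot$outliers_removed[[1]], "S3")
  expect_identical(cot$n_used, 5L)
  walk <- res[res$measure == "sixmwt", ]
  expect_identical(walk$n_used, 5L)
  expect_match(walk$note, "1 incomplete pair")
})

test_that("trial analysis is deterministic and Holm-adjusts across measures", {
  coh <- generate_cohort(6, effect_config(), seed = 41)
  f1 <- analyze_trial(coh$outcomes, seed = 9, normality_reps = 2000)
  f2 <- analyze_trial(coh$outcomes, seed = 9, normality_reps = 2000)
  expect_equal(tidy(f1), tidy(f2))
  res <- tidy(f1)
  tested <- !is.na(res$p_raw)
  expect_equal(res$p_adjusted[tested],
               textbook_holm(res$p_raw[tested]), tolerance = 1e-12)
  expect_true(all(res$p_normal_pre[tested] >= 0 &
                    res$p_normal_pre[tested] <= 1))
  g <- glance(f1)
  expect_identical(g$n_measures, 5L)
})

test_that("measures with too few pairs are skipped with a note", {
  tab <- tibble::tibble(
    participant = c("S1", "S2", "S1", "S2"),
    measure = c("mvc", "mvc", "tug", "tug"),
    pre = c(2, 2.1, 9, NA),
    post = c(2.4, 2.6, 8, 8)
  )
  fit <- analyze_trial(tab, normality = FALSE)
  res <- tidy(fit)
  expect_match(res$note[res$measure == "tug"], "skipped")
  expect_false(is.na(res$p_raw[res$measure == "mvc"]))
})
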