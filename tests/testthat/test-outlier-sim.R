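test_that("contaminated sampling has the mixture mean and variance", {
  set.seed(21)
  x0 <- generate_contaminated_sample(1e5, mean = 0, contamination_rate = 0)
  expect_equal(var(x0), 1, tolerance = 0.02)
  # mixture variance 1 + 0.05 * 10^2 = 6
  x1 <- generate_contaminated_sample(1e5, mean = 0,
                                     contamination_rate = 0.05,
                                     contamination_sd = 10)
  expect_equal(var(x1), 6, tolerance = 0.3)
  # contamination noise is mean-zero
  x2 <- generate_contaminated_sample(1e5, mean = 0.5,
                                     contamination_rate = 0.05,
                                     contamination_sd = 10)
  expect_equal(mean(x2), 0.5, tolerance = 3 * sqrt(6 / 1e5))
})

test_that("sd filter keeps points within c_sd sample SDs of the mean", {
  # hand arithmetic: mean 20, SD sqrt(2000) = 44.72; |100 - 20| = 80 is
  # inside 2 SDs (89.4) but outside 1 SD (44.7)
  x <- c(0, 0, 0, 0, 100)
  expect_identical(sd_filter(x, 2), x)
  expect_identical(sd_filter(x, 1), c(0, 0, 0, 0))
  y <- c(-1, 0, 1)
  expect_identical(sd_filter(y, 3), y)
  set.seed(22)
  z <- rnorm(1e6)
  expect_equal(length(sd_filter(z, 3)) / 1e6, 2 * pnorm(3) - 1,
               tolerance = 1e-3)
  expect_error(sd_filter(5, 2), class = "qrprates_domain_error")
})

test_that("Tukey fences drop points beyond 1.5 IQR from the quartiles", {
  # type-7 quartiles of (1,2,3,4,100): Q1 = 2, Q3 = 4, fences [-1, 7]
  expect_identical(tukey_fence_filter(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  s <- c(-2, -1, 0, 1, 2)
  expect_identical(tukey_fence_filter(s), s)
  set.seed(23)
  z <- rnorm(1e6)
  # normal-theory fence coverage 2*Phi(2.698) - 1 = 0.9930
  expect_equal(length(tukey_fence_filter(z)) / 1e6, 2 * pnorm(2.698) - 1,
               tolerance = 1.5e-3)
  expect_error(tukey_fence_filter(c(1, 2, 3)),
               class = "qrprates_domain_error")
})

test_that("the vectorized t-test path agrees exactly with stats::t.test", {
  cfg <- outlier_sim_config(analysis_sequence = character(0),
                            mode = "full_data_first",
                            effect_size = 0.3, n_reps = 200, seed = 31)
  est <- estimate_rejection_prob(cfg)$estimate
  set.seed(31)
  dat <- qrprates:::outlier_draw_data(cfg)
  p <- vapply(seq_len(200), function(i) {
    stats::t.test(dat$E[i, ], dat$C[i, ], alternative = "greater",
                  var.equal = TRUE)$p.value
  }, 0)
  expect_identical(est, mean(p < 0.05))
})

test_that("the vectorized rank-sum path agrees with stats::wilcox.test", {
  cfg <- outlier_sim_config(analysis_sequence = "rank_sum",
                            effect_size = 0.3, n_reps = 200, seed = 32)
  est <- estimate_rejection_prob(cfg)$estimate
  set.seed(32)
  dat <- qrprates:::outlier_draw_data(cfg)
  p <- vapply(seq_len(200), function(i) {
    suppressWarnings(stats::wilcox.test(
      dat$E[i, ], dat$C[i, ], alternative = "greater",
      exact = FALSE, correct = TRUE
    ))$p.value
  }, 0)
  expect_identical(est, mean(p < 0.05))
})

test_that("longer analysis sequences can only add rejections (paired data)", {
  seqs <- list(
    "sd3",
    c("sd3", "sd2.5"),
    c("sd3", "sd2.5", "sd2"),
    c("sd3", "sd2.5", "sd2", "tukey_fences"),
    c("sd3", "sd2.5", "sd2", "tukey_fences", "rank_sum")
  )
  ests <- vapply(seqs, function(s) {
    estimate_rejection_prob(
      outlier_sim_config(analysis_sequence = s, n_reps = 4000, seed = 33)
    )$estimate
  }, 0)
  expect_true(all(diff(ests) >= 0))
  # full sequence strictly exceeds the single analysis on the same data
  expect_gt(ests[5], ests[1])
})

test_that("rejection estimates are reproducible and properly bracketed", {
  cfg <- outlier_sim_config(n_reps = 4000, seed = 34)
  e1 <- estimate_rejection_prob(cfg)
  e2 <- estimate_rejection_prob(cfg)
  expect_identical(e1, e2)
  # d = 0 full sequence: above one test at level alpha, below five
  # independent tests
  expect_gt(e1$estimate, 0.05)
  expect_lt(e1$estimate, 1 - 0.95^5)
  expect_error(
    estimate_rejection_prob(outlier_sim_config(n_reps = 2000,
                                               analysis_sequence = character(0))),
    class = "qrprates_domain_error"
  )
})

test_that("power of the outlier strategy increases with effect size", {
  est_d <- vapply(c(0.5, 0.8), function(d) {
    estimate_rejection_prob(
      outlier_sim_config(effect_size = d, n_reps = 4000, seed = 35)
    )$estimate
  }, 0)
  expect_gt(est_d[2], est_d[1])
})

test_that("one- and two-sample variants show the same ordering over k", {
  ks <- c(1, 3, 5)
  seqs <- list("sd3", c("sd3", "sd2.5", "sd2"),
               c("sd3", "sd2.5", "sd2", "tukey_fences", "rank_sum"))
  for (form in c("two_sample", "one_sample")) {
    ests <- vapply(seqs, function(s) {
      estimate_rejection_prob(
        outlier_sim_config(test_form = form, analysis_sequence = s,
                           n_reps = 4000, seed = 36)
      )$estimate
    }, 0)
    expect_true(all(diff(ests) >= 0))
  }
})

test_that("run_outlier_strategy_once is a single draw of the simulation", {
  cfg <- outlier_sim_config(n_reps = 1000, seed = 37)
  set.seed(37)
  once <- vapply(1:50, function(i) run_outlier_strategy_once(cfg), NA)
  expect_type(once, "logical")
  # at d = 0 the long-run rate is far from both 0 and 1
  expect_true(mean(once) >= 0 && mean(once) <= 0.5)
})

test_that("analysis sequences must respect the canonical order", {
  expect_error(
    outlier_sim_config(analysis_sequence = c("sd2", "sd3")),
    class = "qrprates_domain_error"
  )
  expect_error(
    outlier_sim_config(analysis_sequence = c("sd3", "median")),
    class = "qrprates_domain_error"
  )
  ok <- outlier_sim_config(analysis_sequence = c("sd2.5", "rank_sum"))
  expect_s3_class(ok, "outlier_sim_config")
})
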