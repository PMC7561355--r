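test_that("selective reporting inflates the Type 1 error as 1-(1-p)^k", {
  d0 <- design_null()
  expect_equal(selective_reporting_rejection(d0, 1),
               ztest_rejection_prob(d0))
  expect_lt(abs(selective_reporting_rejection(d0, 8) - 0.3366), 1e-4)
  expect_lt(
    abs(selective_reporting_rejection(design_null(alpha = 0.005), 8) - 0.0393),
    1e-4
  )
  # power inflation at d > 0 follows the same product form
  de <- design_effect(0.5)
  p1 <- ztest_rejection_prob(de)
  expect_equal(selective_reporting_rejection(de, 4), 1 - (1 - p1)^4)
})

test_that("multiple-measures rejection reduces to independence at rho = 0", {
  for (d in c(0, 0.5)) {
    for (k in c(1, 4, 10)) {
      expect_equal(
        multiple_measures_rejection(design_effect(d), measure_battery(k, 0)),
        selective_reporting_rejection(design_effect(d), k),
        tolerance = 1e-6
      )
    }
  }
})

test_that("equicorrelated orthant quadrature agrees with mvtnorm", {
  # independent library route as cross-check of the one-factor reduction
  cases <- expand.grid(k = c(3, 6, 10), rho = c(0.2, 0.8), d = c(0, 0.5))
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; rho <- cases$rho[i]; d <- cases$d[i]
    ds <- design_effect(d)
    S <- matrix(rho, k, k); diag(S) <- 1
    delta <- d * sqrt(20 / 2)
    cc <- critical_value(0.05, "one_sided")
    set.seed(42)
    ref <- 1 - mvtnorm::pmvnorm(upper = rep(cc, k), mean = rep(delta, k),
                                corr = S,
                                algorithm = mvtnorm::GenzBretz(
                                  abseps = 1e-6, maxpts = 1e6))
    expect_lt(
      abs(multiple_measures_rejection(ds, measure_battery(k, rho)) - ref),
      5e-5
    )
  }
  # two-sided box probability route
  ds2 <- design_effect(0.3, tails = "two_sided")
  cc2 <- critical_value(0.05, "two_sided")
  S <- matrix(0.2, 5, 5); diag(S) <- 1
  set.seed(42)
  ref2 <- 1 - mvtnorm::pmvnorm(lower = rep(-cc2, 5), upper = rep(cc2, 5),
                               mean = rep(0.3 * sqrt(10), 5), corr = S,
                               algorithm = mvtnorm::GenzBretz(
                                 abseps = 1e-6, maxpts = 1e6))
  expect_lt(
    abs(multiple_measures_rejection(ds2, measure_battery(5, 0.2)) - ref2),
    5e-5
  )
})

test_that("ten measures correlated 0.2 inflate a one-sided 5% test to ~34%", {
  p <- multiple_measures_rejection(design_null(), measure_battery(10, 0.2))
  expect_equal(p, 0.34, tolerance = 0.01)
})

test_that("measure redundancy shrinks the inflation toward one test", {
  d0 <- design_null()
  p_rho <- vapply(c(0, 0.2, 0.5, 0.8, 0.95, 0.999), function(r) {
    multiple_measures_rejection(d0, measure_battery(6, r))
  }, 0)
  expect_true(all(diff(p_rho) <= 1e-10))
  expect_lt(abs(p_rho[length(p_rho)] - ztest_rejection_prob(d0)), 0.005)
})

test_that("data peeking with one look equals the single fixed-n test", {
  ds <- design_effect(0.5)
  p_fix <- ztest_rejection_prob(study_design(n_per_group = 30,
                                             effect_size = 0.5))
  expect_equal(data_peeking_rejection(ds, peek_schedule(30)), p_fix,
               tolerance = 1e-9)
})

test_that("five looks at n=10..50 inflate a two-sided 5% test to ~14.3%", {
  p <- data_peeking_rejection(design_null(tails = "two_sided"),
                              peek_preset("steps-of-10"))
  expect_lt(abs(p - 0.143), 0.005)
})

test_that("sequential recursion agrees with mvtnorm box probabilities", {
  # deterministic Miwa algorithm as the independent library route
  ns <- c(10, 20, 30, 40, 50)
  R <- outer(ns, ns, function(a, b) sqrt(pmin(a, b) / pmax(a, b)))
  cc <- critical_value(0.05, "two_sided")
  ref <- 1 - mvtnorm::pmvnorm(lower = rep(-cc, 5), upper = rep(cc, 5),
                              corr = R,
                              algorithm = mvtnorm::Miwa(steps = 1024))
  expect_lt(
    abs(data_peeking_rejection(design_null(tails = "two_sided"),
                               peek_schedule(ns)) - ref),
    1e-5
  )
  # one-sided, noncentral, eight looks
  ns8 <- seq(10, 45, 5)
  R8 <- outer(ns8, ns8, function(a, b) sqrt(pmin(a, b) / pmax(a, b)))
  delta <- 0.2 * sqrt(ns8 / 2)
  cc1 <- critical_value(0.05, "one_sided")
  ref8 <- 1 - mvtnorm::pmvnorm(upper = rep(cc1, 8), mean = delta, corr = R8,
                               algorithm = mvtnorm::Miwa(steps = 512))
  expect_lt(
    abs(data_peeking_rejection(design_effect(0.2),
                               peek_preset("steps-of-5")) - ref8),
    1e-4
  )
})

test_that("peek schedules must be strictly increasing", {
  expect_error(peek_schedule(c(10, 10, 20)), class = "qrprates_domain_error")
  expect_error(peek_schedule(c(20, 10)), class = "qrprates_domain_error")
  expect_error(peek_schedule(integer(0)), class = "qrprates_domain_error")
  expect_error(measure_battery(3, 1), class = "qrprates_domain_error")
})

test_that("rejection probability is nondecreasing in k and d per strategy", {
  for (d in c(0, 0.5)) {
    ds <- design_effect(d)
    sel <- vapply(1:8, function(k) selective_reporting_rejection(ds, k), 0)
    mm <- vapply(1:8, function(k) {
      multiple_measures_rejection(ds, measure_battery(k, 0.2))
    }, 0)
    pk <- vapply(1:8, function(k) {
      data_peeking_rejection(ds, peek_preset("steps-of-5", k))
    }, 0)
    expect_true(all(diff(sel) >= -1e-10))
    expect_true(all(diff(mm) >= -1e-10))
    expect_true(all(diff(pk) >= -1e-10))
  }
  dd <- c(0, 0.2, 0.5, 0.8)
  for (make in list(
    function(ds) selective_reporting_rejection(ds, 4),
    function(ds) multiple_measures_rejection(ds, measure_battery(4, 0.2)),
    function(ds) data_peeking_rejection(ds, peek_preset("steps-of-5", 4))
  )) {
    p <- vapply(dd, function(d) make(design_effect(d)), 0)
    expect_true(all(diff(p) >= -1e-10))
  }
})

test_that("effective rates bundle the d=0 and d>0 evaluations", {
  ds <- design_effect(0.5)
  er <- effective_rates(qrp_selective_reporting(1), ds)
  expect_equal(er$alpha_eff, 0.05, tolerance = 1e-10)
  expect_equal(er$power_eff, ztest_rejection_prob(ds))
  er8 <- effective_rates(qrp_selective_reporting(8), ds)
  expect_lt(abs(er8$alpha_eff - 0.3366), 1e-4)
  erp <- effective_rates(qrp_data_peeking(peek_preset("steps-of-10")),
                         design_effect(0.5, tails = "two_sided"))
  expect_lt(abs(erp$alpha_eff - 0.143), 0.005)
  # plugged into the replication-rate formula at pi = 1, every strategy
  # converges to the replication power
  for (er_i in list(er, er8, erp)) {
    expect_equal(replication_rate(scenario_params(
      1, er_i$alpha_eff, er_i$power_eff, 0.05, 0.9)), 0.9)
  }
})

test_that("good-practice references are the single pre-planned analysis", {
  ds <- design_effect(0.5)
  gp <- good_practice_reference(qrp_selective_reporting(8), ds)
  expect_equal(gp$alpha_eff, 0.05, tolerance = 1e-10)
  expect_equal(gp$power_eff, ztest_rejection_prob(ds))
  # peeking reference: fixed n at the schedule's final look
  gpp <- good_practice_reference(
    qrp_data_peeking(peek_preset("steps-of-5", 3)), ds)
  expect_equal(gpp$power_eff,
               ztest_rejection_prob(study_design(n_per_group = 20,
                                                 effect_size = 0.5)))
})
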