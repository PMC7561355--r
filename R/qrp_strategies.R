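#' Schedule of interim looks for a data-peeking researcher
#'
#' The per-group sample sizes at which a data-peeker tests for
#' significance, stopping at the first significant look.
#'
#' @param sample_sizes Strictly increasing positive integers, length
#'   \eqn{\ge 1}.
#' @return An object of class `peek_schedule`.
#' @seealso [peek_preset()] for the two schedules used as benchmarks.
#' @export
#' @examples
#' peek_schedule(c(10, 15, 20))
peek_schedule <- function(sample_sizes) {
  if (length(sample_sizes) < 1L || !is.numeric(sample_sizes) ||
      anyNA(sample_sizes) || any(sample_sizes != round(sample_sizes)) ||
      any(sample_sizes < 1)) {
    stop_domain("`sample_sizes` must be positive integers")
  }
  if (length(sample_sizes) > 1L && any(diff(sample_sizes) <= 0)) {
    stop_domain("`sample_sizes` must be strictly increasing")
  }
  structure(list(sample_sizes = as.integer(sample_sizes)),
            class = "peek_schedule")
}

#' Named peeking schedules
#'
#' Two benchmark schedules: `"steps-of-5"` peeks after 10, 15, 20, ..., 45
#' observations per group (up to 8 looks); `"steps-of-10"` peeks after 10,
#' 20, 30, 40, 50 observations per group (up to 5 looks), the schedule
#' under which naive sequential testing at a two-sided 5% level inflates
#' the Type 1 error rate to about 14%.
#'
#' @param name `"steps-of-5"` or `"steps-of-10"`.
#' @param k Number of looks to keep (a prefix of the schedule). Defaults
#'   to the full schedule.
#' @return A [peek_schedule()].
#' @export
#' @examples
#' peek_preset("steps-of-10")
#' peek_preset("steps-of-5", k = 3)
peek_preset <- function(name = c("steps-of-5", "steps-of-10"), k = NULL) {
  name <- match.arg(name)
  sizes <- switch(name,
    "steps-of-5" = seq(10L, 45L, by = 5L),
    "steps-of-10" = seq(10L, 50L, by = 10L)
  )
  if (!is.null(k)) {
    k <- check_count(k, "k")
    if (k > length(sizes)) {
      stop_domain(sprintf("preset '%s' has only %d looks", name, length(sizes)))
    }
    sizes <- sizes[seq_len(k)]
  }
  peek_schedule(sizes)
}

#' Battery of correlated dependent measures
#'
#' `k` dependent measures with a common pairwise correlation `rho`
#' (equicorrelation). The study is reported as significant if any single
#' measure reaches significance.
#'
#' @param k Number of dependent measures, an integer \eqn{\ge 1}.
#' @param rho Pairwise correlation between measures, in \eqn{[0, 1)}.
#' @return An object of class `measure_battery`.
#' @export
#' @examples
#' measure_battery(k = 10, rho = 0.2)
measure_battery <- function(k, rho = 0.2) {
  k <- check_count(k, "k")
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho >= 1) {
    stop_domain("`rho` must lie in [0, 1)")
  }
  structure(list(k = k, rho = rho), class = "measure_battery")
}

#' Rejection probability under selective reporting of studies
#'
#' A researcher runs up to `k` independent studies of the same hypothesis
#' and publishes if any one is significant, so
#' \deqn{\Pr(\mathrm{reject}) = 1 - \prod_{i=1}^{k} \Pr(Z_i \le c)
#'                            = 1 - (1 - p_1)^k}
#' with \eqn{p_1} the single-study rejection probability. At `d = 0` this
#' is the inflated effective Type 1 error rate (about 0.34 for k = 8 at a
#' one-sided 5% level); at `d > 0` it is the inflated effective power.
#'
#' @param design A [study_design()].
#' @param k Maximum number of studies attempted, an integer \eqn{\ge 1}.
#' @return A probability.
#' @export
#' @examples
#' selective_reporting_rejection(study_design(alpha = 0.05), k = 8)
selective_reporting_rejection <- function(design, k) {
  stopifnot(inherits(design, "study_design"))
  k <- check_count(k, "k")
  1 - (1 - ztest_rejection_prob(design))^k
}

#' Rejection probability when only significant measures are reported
#'
#' A single study records `k` equicorrelated dependent measures and is
#' reported as significant if any one of them is, so
#' \deqn{\Pr(\mathrm{reject}) = 1 - P(Z_1 \le c, \ldots, Z_k \le c)}
#' for an equicorrelated multivariate normal (two-sided designs use the
#' box probability \eqn{P(|Z_i| \le c\ \forall i)}). The orthant
#' probability is evaluated by deterministic one-factor quadrature. At
#' `rho = 0` this reduces to the independent product of
#' [selective_reporting_rejection()]; as `rho` grows the measures become
#' redundant and the inflation shrinks toward the single-test level.
#'
#' @param design A [study_design()].
#' @param battery A [measure_battery()].
#' @return A probability.
#' @export
#' @examples
#' # 10 measures correlated 0.2 inflate a one-sided 5% test to about 34%
#' multiple_measures_rejection(study_design(), measure_battery(10, 0.2))
multiple_measures_rejection <- function(design, battery) {
  stopifnot(inherits(design, "study_design"),
            inherits(battery, "measure_battery"))
  cc <- critical_value(design$alpha, design$tails)
  lo <- if (design$tails == "one_sided") -Inf else -cc
  delta <- noncentrality(design)
  1 - equicorr_box_prob(lo, cc, delta, battery$k, battery$rho)
}

#' Rejection probability under data peeking
#'
#' A researcher tests the accumulating data at each per-group sample size
#' in `schedule`, stopping at the first significant look; data collection
#' is abandoned if the final look is not significant. All observations
#' used at look \eqn{i} are reused at look \eqn{j > i}, so the sequential
#' z statistics satisfy \eqn{\mathrm{Corr}(Z_i, Z_j) = \sqrt{n_i/n_j}}
#' and
#' \deqn{\Pr(\mathrm{reject}) = 1 - P(Z_1 \le c, \ldots, Z_k \le c),}
#' evaluated by a deterministic Markov-chain recursion that exploits the
#' sequential dependence structure. The `n_per_group` field of `design`
#' is ignored in favour of the schedule.
#'
#' @param design A [study_design()]; its `n_per_group` is ignored.
#' @param schedule A [peek_schedule()].
#' @return A probability.
#' @export
#' @examples
#' # five looks at n = 10, 20, ..., 50 inflate a two-sided 5% test to ~14%
#' data_peeking_rejection(
#'   study_design(alpha = 0.05, tails = "two_sided"),
#'   peek_preset("steps-of-10")
#' )
data_peeking_rejection <- function(design, schedule) {
  stopifnot(inherits(design, "study_design"),
            inherits(schedule, "peek_schedule"))
  ns <- schedule$sample_sizes
  cc <- critical_value(design$alpha, design$tails)
  lo <- if (design$tails == "one_sided") -Inf else -cc
  means <- noncentrality(design, n = ns)
  1 - sequential_box_prob(ns, means, lo, cc)
}

# ---- strategy objects --------------------------------------------------

new_qrp_strategy <- function(subclass, fields) {
  structure(fields, class = c(subclass, "qrp_strategy"))
}

#' P-hacking strategy constructors
#'
#' Build a strategy object describing one questionable research practice,
#' for use with [rejection_prob()], [effective_rates()],
#' [good_practice_reference()], the Monte-Carlo oracle, and
#' [evaluate_grid()].
#'
#' * `qrp_selective_reporting(k)`: run up to `k` independent studies,
#'   publish the first significant one.
#' * `qrp_multiple_measures(k, rho)`: record `k` dependent measures with
#'   pairwise correlation `rho`, report any significant one.
#' * `qrp_data_peeking(schedule)`: test the accumulating sample at each
#'   look of a [peek_schedule()].
#' * `qrp_outlier_removal(sequence, ...)`: re-analyse one data set under a
#'   sequence of outlier-exclusion rules (see [outlier_sim_config()];
#'   `...` is passed on to it). Its rejection probabilities are estimated
#'   by simulation, not computed analytically.
#'
#' @param k Number of studies or dependent measures.
#' @param rho Pairwise correlation between dependent measures.
#' @param schedule A [peek_schedule()].
#' @param sequence Ordered subset of
#'   `c("sd3", "sd2.5", "sd2", "tukey_fences", "rank_sum")`.
#' @param ... For `qrp_outlier_removal`, further arguments to
#'   [outlier_sim_config()] (e.g. `n_reps`, `seed`,
#'   `contamination_rate`).
#' @return An object of class `qrp_strategy`.
#' @name qrp_strategy
#' @export
qrp_selective_reporting <- function(k) {
  new_qrp_strategy("qrp_selective_reporting",
                   list(k = check_count(k, "k")))
}

#' @rdname qrp_strategy
#' @export
qrp_multiple_measures <- function(k, rho = 0.2) {
  b <- measure_battery(k, rho)
  new_qrp_strategy("qrp_multiple_measures", list(k = b$k, rho = b$rho))
}

#' @rdname qrp_strategy
#' @export
qrp_data_peeking <- function(schedule) {
  stopifnot(inherits(schedule, "peek_schedule"))
  new_qrp_strategy("qrp_data_peeking", list(schedule = schedule))
}

#' @rdname qrp_strategy
#' @export
qrp_outlier_removal <- function(sequence = c("sd3", "sd2.5", "sd2",
                                             "tukey_fences", "rank_sum"),
                                ...) {
  new_qrp_strategy("qrp_outlier_removal",
                   list(sequence = sequence, config_args = list(...)))
}

#' Rejection probability of a strategy applied to a study design
#'
#' Dispatches to the analytic computation for selective reporting,
#' multiple measures, and data peeking, and to the Monte-Carlo estimate
#' for selective outlier removal.
#'
#' @param strategy A [qrp_strategy] object.
#' @param design A [study_design()].
#' @param ... Passed on to the outlier simulation (`n_reps`, `seed`).
#' @return A probability (for outlier removal, a simulation estimate).
#' @export
rejection_prob <- function(strategy, design, ...) {
  UseMethod("rejection_prob")
}

#' @export
rejection_prob.qrp_selective_reporting <- function(strategy, design, ...) {
  selective_reporting_rejection(design, strategy$k)
}

#' @export
rejection_prob.qrp_multiple_measures <- function(strategy, design, ...) {
  multiple_measures_rejection(design,
                              measure_battery(strategy$k, strategy$rho))
}

#' @export
rejection_prob.qrp_data_peeking <- function(strategy, design, ...) {
  data_peeking_rejection(design, strategy$schedule)
}

#' @export
rejection_prob.qrp_outlier_removal <- function(strategy, design, ...) {
  cfg <- outlier_config_for(strategy, design, ...)
  estimate_rejection_prob(cfg)$estimate
}

# build an outlier_sim_config from a strategy + design, with strategy
# config_args and call-time ... overriding defaults
outlier_config_for <- function(strategy, design, ...) {
  args <- utils::modifyList(strategy$config_args, list(...))
  base <- list(
    test_form = design$test_form,
    n_per_group = design$n_per_group,
    effect_size = design$effect_size,
    alpha = design$alpha,
    analysis_sequence = strategy$sequence
  )
  do.call(outlier_sim_config, utils::modifyList(base, args))
}

#' Effective Type 1 error rate and power of a p-hacked study
#'
#' Evaluates the strategy's rejection probability twice: at `d = 0`
#' (the effective Type 1 error rate) and at the design's effect size
#' (the effective power). These are the quantities that enter the
#' replication-rate and false-positive-rate formulas in place of the
#' nominal \eqn{\alpha_1} and \eqn{1-\beta_1}.
#'
#' @param strategy A [qrp_strategy] object.
#' @param design A [study_design()]; its `effect_size` is the alternative
#'   at which power is evaluated.
#' @param ... Passed on to the outlier simulation (`n_reps`, `seed`).
#' @return A list with components `alpha_eff` and `power_eff`.
#' @export
#' @examples
#' effective_rates(qrp_selective_reporting(8),
#'                 study_design(effect_size = 0.5))
effective_rates <- function(strategy, design, ...) {
  stopifnot(inherits(strategy, "qrp_strategy"),
            inherits(design, "study_design"))
  null_design <- design
  null_design$effect_size <- 0
  list(
    alpha_eff = rejection_prob(strategy, null_design, ...),
    power_eff = rejection_prob(strategy, design, ...)
  )
}

#' Effective rates of the matching good-practice researcher
#'
#' The comparison standard against which each strategy's inflation is
#' judged: a researcher who runs a single pre-planned analysis. For
#' selective reporting and multiple measures this is one study/measure at
#' the design's sample size; for data peeking it is a single fixed-n test
#' at the schedule's final (largest) sample size, a conservative
#' comparison; for outlier removal it is the sequence truncated to its
#' first analysis. These reference rates do not depend on k.
#'
#' @inheritParams effective_rates
#' @return A list with components `alpha_eff` and `power_eff`.
#' @export
good_practice_reference <- function(strategy, design, ...) {
  UseMethod("good_practice_reference")
}

#' @export
good_practice_reference.qrp_selective_reporting <- function(strategy, design,
                                                            ...) {
  effective_rates(qrp_selective_reporting(1L), design)
}

#' @export
good_practice_reference.qrp_multiple_measures <- function(strategy, design,
                                                          ...) {
  effective_rates(qrp_multiple_measures(1L, strategy$rho), design)
}

#' @export
good_practice_reference.qrp_data_peeking <- function(strategy, design, ...) {
  ns <- strategy$schedule$sample_sizes
  d2 <- design
  d2$n_per_group <- ns[length(ns)]
  effective_rates(qrp_data_peeking(peek_schedule(ns[length(ns)])), d2)
}

#' @export
good_practice_reference.qrp_outlier_removal <- function(strategy, design,
                                                        ...) {
  s1 <- strategy
  s1$sequence <- strategy$sequence[1L]
  effective_rates(s1, design, ...)
}
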