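#' Replication-scenario parameters
#'
#' Bundles the five probabilities that determine the fate of a published
#' significant result: the base rate \eqn{\pi} with which tested hypotheses
#' are true effects, the *effective* Type 1 error probability and power of
#' the original study (which may exceed their nominal values when the
#' original researcher p-hacked), and the nominal Type 1 error probability
#' and power of an unbiased replication study.
#'
#' @param base_rate Probability \eqn{\pi \in [0,1]} that a tested hypothesis
#'   is a true effect ("pre-study probability", "prior odds").
#' @param alpha1_eff Effective Type 1 error probability of the original
#'   study, in \eqn{[0,1]}. May exceed the nominal level when inflated by a
#'   questionable research practice.
#' @param power1_eff Effective power \eqn{1-\beta_1} of the original study,
#'   in \eqn{[0,1]}.
#' @param alpha2 Type 1 error probability of the replication study, in
#'   \eqn{(0,1)}. Default 0.05.
#' @param power2 Power \eqn{1-\beta_2} of the replication study, in
#'   \eqn{(0,1)}. Default 0.90, a high-powered replication project.
#'
#' @return An object of class `scenario_params` (a named list).
#' @seealso [replication_rate()], [false_positive_rate()]
#' @export
#' @examples
#' scenario_params(base_rate = 0.1, alpha1_eff = 0.05, power1_eff = 0.9)
scenario_params <- function(base_rate, alpha1_eff, power1_eff,
                            alpha2 = 0.05, power2 = 0.90) {
  check_prob(base_rate, "base_rate")
  check_prob(alpha1_eff, "alpha1_eff")
  check_prob(power1_eff, "power1_eff")
  check_prob(alpha2, "alpha2", open_lower = TRUE, open_upper = TRUE)
  check_prob(power2, "power2", open_lower = TRUE, open_upper = TRUE)
  structure(
    list(base_rate = base_rate, alpha1_eff = alpha1_eff,
         power1_eff = power1_eff, alpha2 = alpha2, power2 = power2),
    class = "scenario_params"
  )
}

#' Design of a single original study
#'
#' Describes one study testing a standardized mean difference with a z-test
#' of known variance: one-sample (a single group against zero) or
#' two-sample (independent experimental and control groups of equal size).
#'
#' @param test_form `"two_sample"` (default) or `"one_sample"`.
#' @param n_per_group Observations per group, an integer \eqn{\ge 2}.
#'   Default 20, a group size typical of experimental psychology.
#' @param effect_size True standardized mean difference \eqn{d \ge 0};
#'   `0` encodes a true null hypothesis.
#' @param alpha Nominal significance level in \eqn{(0,1)}. Default 0.05.
#' @param tails `"one_sided"` (default) or `"two_sided"`.
#'
#' @return An object of class `study_design` (a named list).
#' @export
#' @examples
#' study_design(n_per_group = 20, effect_size = 0.5)
study_design <- function(test_form = c("two_sample", "one_sample"),
                         n_per_group = 20, effect_size = 0,
                         alpha = 0.05,
                         tails = c("one_sided", "two_sided")) {
  test_form <- match.arg(test_form)
  tails <- match.arg(tails)
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      is.na(effect_size) || effect_size < 0) {
    stop_domain("`effect_size` must be a single number >= 0")
  }
  check_prob(alpha, "alpha", open_lower = TRUE, open_upper = TRUE)
  structure(
    list(test_form = test_form, n_per_group = n_per_group,
         effect_size = effect_size, alpha = alpha, tails = tails),
    class = "study_design"
  )
}

# noncentral mean of the z statistic: d*sqrt(n) one-sample, d*sqrt(n/2)
# two-sample (equal group sizes, known unit variance)
noncentrality <- function(design, n = design$n_per_group,
                          d = design$effect_size) {
  switch(design$test_form,
    one_sample = d * sqrt(n),
    two_sample = d * sqrt(n / 2)
  )
}

#' Critical value of a z-test
#'
#' Returns the cutoff `c` such that a standard normal exceeds `c`
#' (one-sided) or falls outside `[-c, c]` (two-sided) with probability
#' `alpha`.
#'
#' @param alpha Significance level in \eqn{(0,1)}.
#' @param tails `"one_sided"` or `"two_sided"`.
#' @return The critical z value (e.g. 1.96 for a two-sided 5% test).
#' @export
#' @examples
#' critical_value(0.05, "two_sided")  # 1.96
#' critical_value(0.05, "one_sided")  # 1.64
critical_value <- function(alpha, tails = c("one_sided", "two_sided")) {
  tails <- match.arg(tails)
  check_prob(alpha, "alpha", open_lower = TRUE, open_upper = TRUE)
  if (tails == "one_sided") qnorm(1 - alpha) else qnorm(1 - alpha / 2)
}

#' Rejection probability of a single z-test
#'
#' Probability that one study with the given design rejects its null
#' hypothesis. Equals the nominal `alpha` when `effect_size = 0` and the
#' statistical power otherwise. Two-sided tests include the (typically
#' negligible) lower-tail rejection region exactly.
#'
#' @param design A [study_design()].
#' @return A probability.
#' @export
#' @examples
#' ztest_rejection_prob(study_design(effect_size = 0.8))  # power at d = 0.8
ztest_rejection_prob <- function(design) {
  stopifnot(inherits(design, "study_design"))
  cc <- critical_value(design$alpha, design$tails)
  delta <- noncentrality(design)
  if (design$tails == "one_sided") {
    pnorm(cc - delta, lower.tail = FALSE)
  } else {
    pnorm(cc - delta, lower.tail = FALSE) + pnorm(-cc - delta)
  }
}

#' Replication rate of initially significant results
#'
#' The probability that an unbiased replication study of a published
#' significant result is itself significant:
#' \deqn{RR = \frac{\pi (1-\beta_1)(1-\beta_2) + (1-\pi)\alpha_1\alpha_2}
#'                 {\pi (1-\beta_1) + (1-\pi)\alpha_1}}
#' where \eqn{\alpha_1} and \eqn{1-\beta_1} are the original study's
#' *effective* Type 1 error probability and power. RR runs from
#' \eqn{\alpha_2} at \eqn{\pi = 0} to \eqn{1-\beta_2} at \eqn{\pi = 1}.
#'
#' @param s A [scenario_params()] object.
#' @return The replication rate, a probability.
#' @export
#' @examples
#' replication_rate(scenario_params(0.1, 0.05, 0.9))
replication_rate <- function(s) {
  stopifnot(inherits(s, "scenario_params"))
  p <- s$base_rate
  denom <- p * s$power1_eff + (1 - p) * s$alpha1_eff
  if (denom <= 0) {
    stop_undefined_rate(
      "replication rate undefined: no significant original results occur"
    )
  }
  # endpoint limits evaluated exactly: only false positives at pi = 0,
  # only true positives at pi = 1
  if (p == 0) return(s$alpha2)
  if (p == 1) return(s$power2)
  (p * s$power1_eff * s$power2 + (1 - p) * s$alpha1_eff * s$alpha2) / denom
}

#' False positive rate among significant results
#'
#' The proportion of false positives among all significant original
#' results (the false discovery rate of a research field):
#' \deqn{FPR = \frac{(1-\pi)\alpha_1}{(1-\pi)\alpha_1 + \pi(1-\beta_1)}}
#'
#' @param base_rate Base rate \eqn{\pi} of true effects, in \eqn{[0,1]}.
#' @param alpha1_eff Effective Type 1 error probability of the original
#'   study.
#' @param power1_eff Effective power of the original study.
#' @return The false positive rate, a probability: 1 at \eqn{\pi = 0},
#'   0 at \eqn{\pi = 1}.
#' @export
#' @examples
#' false_positive_rate(0.5, 0.05, 0.9)
false_positive_rate <- function(base_rate, alpha1_eff, power1_eff) {
  check_prob(base_rate, "base_rate")
  check_prob(alpha1_eff, "alpha1_eff")
  check_prob(power1_eff, "power1_eff")
  fp <- (1 - base_rate) * alpha1_eff
  denom <- fp + base_rate * power1_eff
  if (denom <= 0) {
    stop_undefined_rate(
      "false positive rate undefined: no significant results occur"
    )
  }
  fp / denom
}

#' Probability that k independent studies are all significant
#'
#' With single-study rejection probability `single_power`, the chance that
#' a series of `k` independent studies all reject is `single_power^k`.
#' A published multi-experiment series that is "too good to be true" (e.g.
#' five significant results at power 0.36, probability 0.006) suggests
#' unreported failed attempts.
#'
#' @param single_power Per-study rejection probability, in \eqn{[0,1]}.
#' @param k Number of studies, an integer \eqn{\ge 1}.
#' @return `single_power^k`.
#' @export
#' @examples
#' all_significant_prob(0.36, 5)  # 0.006
all_significant_prob <- function(single_power, k) {
  check_prob(single_power, "single_power")
  k <- check_count(k, "k")
  single_power^k
}

#' Probability of at least one significant test among m independent tests
#'
#' Under a global null, cherry-picking any of `m` independent effects (for
#' instance the seven testable effects of a three-factor ANOVA) rejects
#' with probability \eqn{1 - (1-\alpha)^m}.
#'
#' @param alpha Per-test significance level, in \eqn{(0,1)}.
#' @param m Number of independent tests, an integer \eqn{\ge 1}.
#' @return `1 - (1 - alpha)^m`.
#' @export
#' @examples
#' any_of_m_effects_prob(0.05, 7)  # about 0.30
any_of_m_effects_prob <- function(alpha, m) {
  check_prob(alpha, "alpha", open_lower = TRUE, open_upper = TRUE)
  m <- check_count(m, "m")
  1 - (1 - alpha)^m
}
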