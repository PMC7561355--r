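# Agent-level Monte-Carlo oracle: every analytic rejection probability,
# replication rate, and false positive rate in the package can be
# re-derived here by directly simulating researchers' raw data and
# stopping rules.  Correlation structures are realized by construction
# (shared factor for correlated measures, literal data reuse for
# peeking), never by drawing from an assembled covariance matrix.

# logical vector of n simulated study outcomes under the strategy's
# stopping-and-testing rule; consumes the current RNG stream
oracle_sig_draws <- function(strategy, design, n) {
  switch(class(strategy)[1L],
    qrp_selective_reporting = oracle_selective(strategy, design, n),
    qrp_multiple_measures = oracle_measures(strategy, design, n),
    qrp_data_peeking = oracle_peeking(strategy, design, n),
    qrp_outlier_removal = oracle_outlier(strategy, design, n),
    stop_domain("unknown strategy class")
  )
}

oracle_exceeds <- function(Z, design) {
  cc <- critical_value(design$alpha, design$tails)
  if (design$tails == "one_sided") Z > cc else abs(Z) > cc
}

oracle_selective <- function(strategy, design, n) {
  delta <- noncentrality(design)
  Z <- matrix(rnorm(n * strategy$k, mean = delta), nrow = n)
  rowSums(oracle_exceeds(Z, design)) > 0
}

oracle_measures <- function(strategy, design, n) {
  # one shared factor realizes the exact equicorrelation matrix:
  # Z_i = sqrt(rho) U + sqrt(1-rho) eps_i + delta
  delta <- noncentrality(design)
  U <- rnorm(n)
  eps <- matrix(rnorm(n * strategy$k), nrow = n)
  Z <- sqrt(strategy$rho) * U + sqrt(1 - strategy$rho) * eps + delta
  rowSums(oracle_exceeds(Z, design)) > 0
}

oracle_peeking <- function(strategy, design, n) {
  # incremental sums: observations used at look j are literally reused at
  # look j+1, so Corr(Z_i, Z_j) = sqrt(n_i/n_j) holds by construction
  ns <- strategy$schedule$sample_sizes
  deltas <- noncentrality(design, n = ns)
  S <- rep(0, n)
  sig <- rep(FALSE, n)
  n_prev <- 0
  for (j in seq_along(ns)) {
    S <- S + sqrt(ns[j] - n_prev) * rnorm(n)
    Zj <- S / sqrt(ns[j]) + deltas[j]
    sig <- sig | oracle_exceeds(Zj, design)
    n_prev <- ns[j]
  }
  sig
}

oracle_outlier <- function(strategy, design, n) {
  cfg <- outlier_config_for(strategy, design)
  dat <- outlier_draw_data(cfg, n_reps = n)
  as.logical(outlier_reject_matrix(dat$E, dat$C, cfg))
}

#' Simulate a single original study under a p-hacking strategy
#'
#' Draws raw data for one study (k replicate studies, k correlated
#' measures via a shared factor, incrementally peeked samples, or a
#' contaminated sample re-analysed under outlier rules) and applies the
#' strategy's stopping-and-testing rule. Uses the current RNG state.
#'
#' @param strategy A [qrp_strategy] object.
#' @param design A [study_design()]; its `effect_size` is used when
#'   `truth = "effect"`.
#' @param truth `"null"` (effect size forced to 0) or `"effect"`.
#' @return Logical: did the simulated study report significance?
#' @export
#' @examples
#' set.seed(1)
#' simulate_original_study(qrp_selective_reporting(4),
#'                         study_design(effect_size = 0.5), "effect")
simulate_original_study <- function(strategy, design,
                                    truth = c("null", "effect")) {
  truth <- match.arg(truth)
  if (truth == "null") design$effect_size <- 0
  as.logical(oracle_sig_draws(strategy, design, 1L))
}

#' Monte-Carlo estimate of a strategy's rejection probability
#'
#' Brute-force counterpart of [rejection_prob()]: simulates `n_reps`
#' studies at the design's effect size and reports the rejection
#' frequency with its binomial standard error. Used to verify every
#' analytic value in the package.
#'
#' @param strategy A [qrp_strategy] object.
#' @param design A [study_design()].
#' @param n_reps Number of simulated studies.
#' @param seed Optional integer seed; when supplied the estimate is fully
#'   reproducible.
#' @return A list with `estimate`, `mc_se`, and `n_reps`.
#' @export
#' @examples
#' oracle_rejection_prob(qrp_selective_reporting(8), study_design(),
#'                       n_reps = 1e4, seed = 1)
oracle_rejection_prob <- function(strategy, design, n_reps = 1e5,
                                  seed = NULL) {
  stopifnot(inherits(strategy, "qrp_strategy"),
            inherits(design, "study_design"))
  n_reps <- check_count(n_reps, "n_reps", min = 1000L)
  if (!is.null(seed)) set.seed(seed)
  sig <- oracle_sig_draws(strategy, design, n_reps)
  est <- mean(sig)
  list(estimate = est, mc_se = sqrt(est * (1 - est) / n_reps),
       n_reps = n_reps)
}

#' Simulate the full replication pipeline
#'
#' Per replicate: a hypothesis is a true effect with probability
#' `base_rate`; the original study is simulated at the raw-data level
#' under the strategy; if it is significant, replication success is drawn
#' as Bernoulli with probability `power2` (true effect) or `alpha2`
#' (null), the abstraction under which a replication study is
#' characterised entirely by its two error probabilities. Returns the
#' Monte-Carlo replication rate (success frequency among significant
#' originals) and false positive rate (share of nulls among significant
#' originals), each with a binomial standard error.
#'
#' @param strategy A [qrp_strategy] object.
#' @param design A [study_design()] with the effect size that holds when
#'   a hypothesis is true.
#' @param base_rate Base rate \eqn{\pi} of true effects.
#' @param alpha2,power2 Type 1 error probability and power of the
#'   replication study.
#' @param n_reps Number of simulated original studies.
#' @param seed Optional integer seed.
#' @return A list with `rr_hat`, `rr_se`, `fpr_hat`, `fpr_se`,
#'   `n_significant`, and `n_reps`.
#' @export
#' @examples
#' simulate_replication_pipeline(qrp_selective_reporting(4),
#'                               study_design(effect_size = 0.5),
#'                               base_rate = 0.5, n_reps = 1e4, seed = 1)
simulate_replication_pipeline <- function(strategy, design, base_rate,
                                          alpha2 = 0.05, power2 = 0.90,
                                          n_reps = 1e5, seed = NULL) {
  stopifnot(inherits(strategy, "qrp_strategy"),
            inherits(design, "study_design"))
  check_prob(base_rate, "base_rate")
  check_prob(alpha2, "alpha2", open_lower = TRUE, open_upper = TRUE)
  check_prob(power2, "power2", open_lower = TRUE, open_upper = TRUE)
  n_reps <- check_count(n_reps, "n_reps", min = 1000L)
  if (!is.null(seed)) set.seed(seed)

  truth <- rbinom(n_reps, 1L, base_rate) == 1L
  sig <- logical(n_reps)
  if (any(truth)) {
    sig[truth] <- oracle_sig_draws(strategy, design, sum(truth))
  }
  if (any(!truth)) {
    null_design <- design
    null_design$effect_size <- 0
    sig[!truth] <- oracle_sig_draws(strategy, null_design, sum(!truth))
  }
  n_sig <- sum(sig)
  if (n_sig == 0L) {
    stop_undefined_rate(
      "no simulated original study was significant; rates undefined"
    )
  }
  p_succ <- ifelse(truth[sig], power2, alpha2)
  success <- runif(n_sig) < p_succ
  rr <- mean(success)
  fpr <- mean(!truth[sig])
  list(
    rr_hat = rr, rr_se = sqrt(rr * (1 - rr) / n_sig),
    fpr_hat = fpr, fpr_se = sqrt(fpr * (1 - fpr) / n_sig),
    n_significant = n_sig, n_reps = n_reps
  )
}
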