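# shared fixtures: the default study conditions (two-sample z-test,
# n = 20 per group, one-sided)
design_null <- function(alpha = 0.05, tails = "one_sided") {
  study_design(test_form = "two_sample", n_per_group = 20,
               effect_size = 0, alpha = alpha, tails = tails)
}

design_effect <- function(d = 0.5, alpha = 0.05, tails = "one_sided") {
  study_design(test_form = "two_sample", n_per_group = 20,
               effect_size = d, alpha = alpha, tails = tails)
}

# direct Monte-Carlo rejection frequency for a single z-test; an oracle
# independent of ztest_rejection_prob's closed form
mc_single_ztest <- function(design, n_draws = 2e5) {
  delta <- switch(design$test_form,
    one_sample = design$effect_size * sqrt(design$n_per_group),
    two_sample = design$effect_size * sqrt(design$n_per_group / 2)
  )
  cc <- critical_value(design$alpha, design$tails)
  z <- rnorm(n_draws, mean = delta)
  if (design$tails == "one_sided") mean(z > cc) else mean(abs(z) > cc)
}
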