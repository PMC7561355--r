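#' Evaluate replication and false-positive rates over a parameter grid
#'
#' For every combination of nominal alpha level, effect size, and extent
#' of p-hacking `k`, computes the strategy's effective Type 1 error rate
#' and power, the matching good-practice reference rates, and then — for
#' every base rate \eqn{\pi} — the false positive rate and replication
#' rate for both the p-hacked and the good-practice researcher, plus the
#' shrinkage `RR_good - RR_hacked`. This materialises, as a long-format
#' table, the curves relating replication rate to base rate under each
#' questionable research practice.
#'
#' The meaning of `k` depends on the strategy: number of studies
#' (selective reporting), number of dependent measures (multiple
#' measures), number of looks taken from the base peeking schedule (data
#' peeking, `k` must not exceed `length(schedule_base$sample_sizes)`), or
#' number of analyses from the canonical outlier sequence (outlier
#' removal, `k <= 5`).
#'
#' @param strategy `"selective_reporting"`, `"multiple_measures"`,
#'   `"data_peeking"`, or `"outlier_removal"`.
#' @param pi_values Base rates to evaluate; default 0 to 1 in steps of
#'   0.05.
#' @param k_values Extents of p-hacking; default `c(1, 2, 4, 6, 8)`
#'   (truncated to 5 for outlier removal).
#' @param d_values True effect sizes; default `c(0.2, 0.5, 0.8)`.
#' @param alpha_values Nominal significance levels of the original study;
#'   default `c(0.005, 0.05)`.
#' @param n_per_group Per-group sample size of the original study;
#'   default 20.
#' @param rho Intercorrelation of dependent measures; default 0.2.
#' @param schedule_base Base [peek_schedule()] whose first `k` looks a
#'   peeker uses; default `peek_preset("steps-of-5")`.
#' @param alpha2,power2 Replication study's Type 1 error probability and
#'   power; defaults 0.05 and 0.90.
#' @param test_form,tails Passed to [study_design()].
#' @param n_reps,seed Simulation size and seed for the outlier-removal
#'   strategy (ignored by the analytic strategies).
#' @return A tibble with columns `strategy`, `pi`, `k`, `d`, `alpha1`,
#'   `alpha_eff`, `power_eff`, `fpr_hacked`, `fpr_good`, `rr_hacked`,
#'   `rr_good`, `shrinkage`, and `note` (non-`NA` where a rate was
#'   undefined and the row was annotated rather than computed).
#' @export
#' @examples
#' evaluate_grid("selective_reporting", pi_values = c(0.1, 0.5, 0.9),
#'               k_values = c(1, 4), d_values = 0.5)
evaluate_grid <- function(strategy = c("selective_reporting",
                                       "multiple_measures",
                                       "data_peeking",
                                       "outlier_removal"),
                          pi_values = seq(0, 1, by = 0.05),
                          k_values = c(1L, 2L, 4L, 6L, 8L),
                          d_values = c(0.2, 0.5, 0.8),
                          alpha_values = c(0.005, 0.05),
                          n_per_group = 20,
                          rho = 0.2,
                          schedule_base = peek_preset("steps-of-5"),
                          alpha2 = 0.05, power2 = 0.90,
                          test_form = "two_sample",
                          tails = "one_sided",
                          n_reps = 10000, seed = 1) {
  strategy <- match.arg(strategy)
  canonical_seq <- c("sd3", "sd2.5", "sd2", "tukey_fences", "rank_sum")
  if (strategy == "outlier_removal" && missing(k_values)) {
    k_values <- seq_along(canonical_seq)
  }
  make_strategy <- function(k) {
    switch(strategy,
      selective_reporting = qrp_selective_reporting(k),
      multiple_measures = qrp_multiple_measures(k, rho),
      data_peeking = {
        ns <- schedule_base$sample_sizes
        if (k > length(ns)) {
          stop_domain(sprintf("k = %d exceeds the %d looks of the schedule",
                              k, length(ns)))
        }
        qrp_data_peeking(peek_schedule(ns[seq_len(k)]))
      },
      outlier_removal = {
        if (k > length(canonical_seq)) {
          stop_domain(sprintf("k = %d exceeds the %d outlier analyses",
                              k, length(canonical_seq)))
        }
        qrp_outlier_removal(canonical_seq[seq_len(k)],
                            n_reps = n_reps, seed = seed)
      }
    )
  }

  rows <- list()
  for (alpha1 in alpha_values) {
    for (d in d_values) {
      design <- study_design(test_form = test_form,
                             n_per_group = n_per_group,
                             effect_size = d, alpha = alpha1,
                             tails = tails)
      for (k in k_values) {
        strat <- make_strategy(k)
        eff <- effective_rates(strat, design)
        good <- good_practice_reference(strat, design)
        for (p in pi_values) {
          row <- tibble::tibble(
            strategy = strategy, pi = p, k = as.integer(k), d = d,
            alpha1 = alpha1,
            alpha_eff = eff$alpha_eff, power_eff = eff$power_eff,
            fpr_hacked = NA_real_, fpr_good = NA_real_,
            rr_hacked = NA_real_, rr_good = NA_real_,
            shrinkage = NA_real_, note = NA_character_
          )
          res <- tryCatch({
            list(
              fpr_hacked = false_positive_rate(p, eff$alpha_eff,
                                               eff$power_eff),
              fpr_good = false_positive_rate(p, good$alpha_eff,
                                             good$power_eff),
              rr_hacked = replication_rate(scenario_params(
                p, eff$alpha_eff, eff$power_eff, alpha2, power2)),
              rr_good = replication_rate(scenario_params(
                p, good$alpha_eff, good$power_eff, alpha2, power2))
            )
          }, qrprates_undefined_rate_error = function(e) {
            conditionMessage(e)
          })
          if (is.character(res)) {
            row$note <- res
          } else {
            row[names(res)] <- res
            row$shrinkage <- row$rr_good - row$rr_hacked
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$strategy, out$alpha1, out$d, out$k, out$pi), ]
}

#' Write and read a rate table
#'
#' `write_rate_table()` writes a grid produced by [evaluate_grid()] as
#' CSV (RFC-4180 quoting) or as an array of JSON records, with the
#' deterministic row order produced by [evaluate_grid()] (strategy,
#' alpha1, d, k, pi); numeric values round-trip at full double precision.
#' `read_rate_table()` reads it back.
#'
#' @param table A rate table (data frame).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; `read_rate_table()` infers it from
#'   the file extension when not given.
#' @return `write_rate_table()` returns `path` invisibly;
#'   `read_rate_table()` returns a tibble.
#' @export
write_rate_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_domain("`table` must be a nonempty data frame; nothing written")
  }
  table <- table[order(table$strategy, table$alpha1, table$d,
                       table$k, table$pi), ]
  if (format == "csv") {
    write.csv(table, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  out <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  if (!"note" %in% names(out)) out$note <- NA_character_
  out$note <- as.character(out$note)
  tibble::as_tibble(out)
}
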