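#!/usr/bin/env Rscript
# Core result: correlation (waveform-shape) decoding of the visual scene,
# within one session and across sessions, per electrode; peak-to-peak
# amplitude decoding as the contrast; paired permutation tests.
#
# Output: results/exp1/decoding_{within,between,amplitude}.csv,
#         results/exp1/decoding_summary.csv, results/exp1/permutation_tests.csv

source("analysis/00_common.R")
study <- get_exp1_study()

within <- decode_study(study, mode = "correlation", pairing = "within_session")
between <- decode_study(study, mode = "correlation", pairing = "between_session")
amplitude <- decode_study(study, mode = "amplitude", pairing = "within_session")

write_result(within, "decoding_within")
write_result(between, "decoding_between")
write_result(amplitude, "decoding_amplitude")

summary_tbl <- rbind(
  cbind(analysis = "within_session", summarize_decoding(within, by = "electrode")),
  cbind(analysis = "between_session", summarize_decoding(between, by = "electrode")),
  cbind(analysis = "amplitude_within", summarize_decoding(amplitude, by = "electrode"))
)
write_result(summary_tbl, "decoding_summary")
message("group mean accuracy, within-session: ",
        sprintf("%.1f%%", summarize_decoding(within)$mean_accuracy))
message("group mean accuracy, between-session: ",
        sprintf("%.1f%%", summarize_decoding(between)$mean_accuracy))
message("group mean accuracy, amplitude decoding: ",
        sprintf("%.1f%%", summarize_decoding(amplitude)$mean_accuracy))

# robustness to eye blinks and movement: with vs without artifact rejection
within_rej <- decode_study(study, mode = "correlation",
                           pairing = "within_session", reject = TRUE)
rej_tbl <- tibble::tibble(
  analysis = c("no_rejection", "with_rejection"),
  mean_accuracy = c(summarize_decoding(within)$mean_accuracy,
                    summarize_decoding(within_rej)$mean_accuracy)
)
write_result(rej_tbl, "rejection_comparison")
message(sprintf("artifact rejection moves within-session accuracy by %.2f pp",
                diff(rej_tbl$mean_accuracy)))

per_part <- function(res) {
  agg <- aggregate(accuracy ~ participant, as.data.frame(res), mean)
  setNames(agg$accuracy, agg$participant)
}
pt_session <- permutation_test(per_part(within), per_part(between),
                               n_reps = 100000, seed = SEED)
pt_mode <- permutation_test(per_part(within), per_part(amplitude),
                            n_reps = 100000, seed = SEED + 1)
perms <- tibble::tibble(
  comparison = c("within_vs_between", "correlation_vs_amplitude"),
  observed_diff = c(pt_session$observed_diff, pt_mode$observed_diff),
  z = c(pt_session$z, pt_mode$z),
  p = c(pt_session$p, pt_mode$p)
)
write_result(perms, "permutation_tests")
message(sprintf("within vs between: diff %.1f pp, Z = %.2f, p = %.2g",
                pt_session$observed_diff, pt_session$z, pt_session$p))
message(sprintf("correlation vs amplitude: diff %.1f pp, Z = %.2f, p = %.2g",
                pt_mode$observed_diff, pt_mode$z, pt_mode$p))
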