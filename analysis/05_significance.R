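#!/usr/bin/env Rscript
# Significance machinery: simulated null thresholds for both experimental
# designs and the correlation between decoding score and the distance of the
# individual alpha frequency from the 10 Hz flicker.
#
# Output: results/exp1/null_thresholds.csv, results/exp1/iaf_correlation.csv

source("analysis/00_common.R")
study <- get_exp1_study()

nd1 <- simulate_null(20, 6, 5, n_electrodes = 1, alpha_family = 0.05,
                     n_tests = 8, n_reps = 100000, seed = SEED)
nd2 <- simulate_null(20, 3, 2, n_electrodes = 6, alpha_family = 0.05,
                     n_tests = 3, n_reps = 100000, seed = SEED + 1)
thresholds <- tibble::tibble(
  design = c("exp1: 20x6x5, 1 electrode, alpha 0.05/8",
             "exp2: 20x3x2, 6 electrodes, alpha 0.05/3"),
  threshold_percent = c(nd1$threshold_percent, nd2$threshold_percent),
  null_mean = c(nd1$null_mean, nd2$null_mean),
  null_sd = c(nd1$null_sd, nd2$null_sd),
  alpha_corrected = c(nd1$alpha_corrected, nd2$alpha_corrected)
)
write_result(thresholds, "null_thresholds")
message(sprintf("significance thresholds: %.2f%% (design 1), %.2f%% (design 2)",
                nd1$threshold_percent, nd2$threshold_percent))

# decoding score vs |IAF - flicker frequency|, session 1
iaf <- iaf_table(study)
s1 <- iaf[iaf$session == 1, ]
within <- decode_study(study, mode = "correlation", pairing = "within_session")
agg <- aggregate(accuracy ~ participant, as.data.frame(within), mean)
score <- setNames(agg$accuracy, agg$participant)[s1$participant]
ct <- tryCatch(correlate_scores(abs(s1$iaf_hz - 10), score),
               error = function(e) list(r = NA_real_, p = NA_real_))
write_result(tibble::tibble(predictor = "abs(IAF - 10 Hz)", session = 1,
                            r = ct$r, p = ct$p, n = length(score)),
             "iaf_correlation")
message(sprintf("decoding vs IAF distance: r = %.2f, p = %.2g", ct$r, ct$p))
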