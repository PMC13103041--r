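#!/usr/bin/env Rscript
# How much flicker time is needed, and where in the spectrum the scene
# information lives: duration sweep and harmonic band-pass sweep.
#
# Output: results/exp1/duration_sweep.csv, results/exp1/band_sweep.csv

source("analysis/00_common.R")
study <- get_exp1_study()

durations <- c(15, 10, 5, 4, 3, 2, 1, seq(0.9, 0.1, by = -0.1))
dsw <- duration_sweep(study, durations, mode = "correlation",
                      pairing = "within_session")
write_result(dsw, "duration_sweep")
dacc <- sapply(split(dsw$accuracy, dsw$duration), mean)
message("mean accuracy by duration (s):")
print(round(dacc, 1))

centers <- seq(10, 120, by = 10) # up to the Nyquist limit of this dataset
bsw <- band_sweep(study, centers, half_width = 1, mode = "correlation",
                  pairing = "within_session")
write_result(bsw, "band_sweep")
bacc <- sapply(split(bsw$accuracy, bsw$center), mean)
unfiltered <- mean(bsw$accuracy[is.na(bsw$center)])
message(sprintf("unfiltered accuracy: %.1f%%", unfiltered))
message("mean accuracy by band centre (Hz):")
print(round(bacc, 1))
message(sprintf("best single band: %s Hz (%.1f%%); broadband is %s",
                names(which.max(bacc)), max(bacc),
                if (unfiltered >= max(bacc)) "at least as good" else "worse"))
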