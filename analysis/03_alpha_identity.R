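#!/usr/bin/env Rscript
# Secondary decoders: endogenous alpha power from the pre-flicker baseline
# (weak by construction) and participant identity from SSVEP shape.
#
# Output: results/exp1/alpha_power.csv, results/exp1/identity.csv

source("analysis/00_common.R")
study <- get_exp1_study()

alpha <- decode_study(study, mode = "alpha_power", pairing = "within_session")
write_result(alpha, "alpha_power")
message(sprintf("alpha-power decoding, group mean: %.1f%% (pairwise chance 50%%)",
                summarize_decoding(alpha)$mean_accuracy))

ident <- identity_decode_study(study)
write_result(ident, "identity")
message(sprintf(
  "participant-identity decoding: %.1f%% mean across scenes/electrodes (chance %.1f%%)",
  mean(ident$accuracy), ident$chance[1]
))
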