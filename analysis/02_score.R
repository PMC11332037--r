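#!/usr/bin/env Rscript
# Phasic scoring of the simulated cohort: band-pass filter (0.0159-5 Hz),
# epoch around cue and heat onsets (-2 to +6 s), downsample to 100 Hz,
# jack-knife outlier exclusion (4.89 SD), peak-to-peak EDA with the 0.02 uS
# floor and ln(1+x) transform, and the windowed maximum of the facial
# pain-expression composite.

library(dyadsynch)
library(data.table)

SEED <- 1L
cfg <- generator_config(n_sessions = 36L)
sessions <- simulate_cohort(cfg, seed = SEED)

scores <- rbindlist(lapply(sessions, score_session))
dyadsynch:::write_num_csv(scores, "results/scores.csv")

cat(sprintf("Scored %d trial-outcome rows.\n", nrow(scores)))
excl <- scores[outcome %in% c("EDA_cue", "EDA_heat"),
               .(excluded = sum(excluded)), by = participant]
cat(sprintf("Jack-knife exclusions: %.2f trials per participant on average.\n",
            mean(excl$excluded)))
cat("Mean transformed scores by cue and outcome (G2/G3 demonstrators):\n")
print(scores[role == "dem" & generation %in% c("G2", "G3") &
               excluded == FALSE,
             .(mean = round(mean(transformed), 3)), by = .(outcome, cue)])
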