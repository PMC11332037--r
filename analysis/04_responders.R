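#!/usr/bin/env Rscript
# Monte-Carlo permutation classification of every demonstrator: 10,000
# relabelings of the 12 pain ratings preserving the 6/6 cue split; a Tx-NT
# difference in the upper 95% of the null marks a responder, the lower tail a
# reverse-responder. The G2-vs-G3 responder proportions are compared with a
# continuity-uncorrected chi-square and Cramer's V.

library(dyadsynch)
library(data.table)

SEED <- 1L
cfg <- generator_config(n_sessions = 36L)
sessions <- simulate_cohort(cfg, seed = SEED)
ratings <- ratings_table(sessions)

responders <- responder_table(ratings, n_perm = 10000L, seed = SEED + 1L)
dyadsynch:::write_num_csv(responders, "results/responders.csv")

cat("Responder classes by generation:\n")
print(dcast(responders, generation ~ class, fun.aggregate = length))

tab <- as.matrix(dcast(
  responders[generation %in% c("G2", "G3")],
  generation ~ (class == "responder"), fun.aggregate = length)[, -1])
res <- responder_proportions_test(tab)
cat(sprintf("\nG2 vs G3 responder proportions: chi2(%d, N = %d) = %.3f, p = %.3f, Cramer's V = %.3f\n",
            res$df, res$n, res$chisq, res$p, res$cramers_v))
cat("A small statistic indicates receptivity to the manipulation does not\n")
cat("change down the chain.\n")
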