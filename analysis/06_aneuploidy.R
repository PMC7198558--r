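#!/usr/bin/env Rscript
# Fraction of genome aneuploid, 39-arm event calls, aneuploidy scores and
# per-arm Fisher comparisons between resistant and sensitive primaries.

library(tgctsig)

profiles <- read_seg("results/cohort/profiles.seg.tsv")
samples <- read.delim("results/cohort/samples.tsv")
g <- tgct_genome()

keep <- samples$sample[samples$purity >= 0.4]
events <- do.call(rbind, lapply(profiles[keep], call_arm_events, genome = g))
scores <- data.frame(
  sample = keep,
  fga = sapply(profiles[keep], fraction_genome_aneuploid),
  score = sapply(split(events, events$sample)[keep], aneuploidy_score)
)
write.table(events, "results/arm_events.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(scores, "results/aneuploidy_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Aneuploidy over %d tumours (purity >= 0.4): median FGA %.2f, median score %d\n",
            nrow(scores), median(scores$fga), median(scores$score)))

prim <- samples[samples$stage == "primary" & samples$sample %in% keep, ]
groups <- setNames(prim$response, prim$sample)
tests <- event_frequency_tests(events[events$sample %in% prim$sample, ],
                               groups)
write.table(tests, "results/arm_frequency_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Arms at nominal p < 0.05 (resistant vs sensitive): %d/39\n",
            sum(tests$followup)))
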