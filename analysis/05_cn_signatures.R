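#!/usr/bin/env Rscript
# Copy-number feature extraction, 36-component posterior encoding, NMF rank
# survey against a permuted null and signature matching to the generative
# reference. This is the core copy-number signature analysis.

library(tgctsig)

profiles <- read_seg("results/cohort/profiles.seg.tsv")
samples <- read.delim("results/cohort/samples.tsv")
truth <- read.delim("results/cohort/truth_exposures.tsv")
model <- default_component_model()
W <- synthetic_cn_signatures()

enc <- encode_cohort(profiles, model, min_purity = 0.4)
cat(sprintf("Encoded %d profiles (%d excluded at purity < 0.4)\n",
            nrow(enc), length(attr(enc, "excluded"))))
write.table(data.frame(sample = rownames(enc), enc),
            "results/cn_encodings.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

survey <- select_rank(enc, ranks = 2:8, seed = 42)
write.table(survey$measures, "results/cn_rank_survey.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Rank survey over 2..8: chosen rank = %s\n", survey$chosen))
# On full segmentation-derived encodings the survey is conservative (event
# interactions blur the planted structure); the recovery comparison below is
# made at the generative rank
fit <- nmf_decompose(enc, 5, n_restarts = 10, seed = 43)
ref <- reference_encodings(W, model, ploidy = 3, n_events = 60,
                           n_samples = 30, seed = 44)
m <- match_signatures(fit$weights, ref)
print(m)

pres <- signature_presence(fit$exposures)
cat("Per-signature presence (> 5% exposure):",
    paste(sprintf("%.2f", pres), collapse = " "), "\n")

truth_expo <- as.matrix(truth[match(sub("_T.*", "", rownames(enc)),
                                    truth$case), -1])
perm <- match(m$b, rownames(ref))
r <- sapply(seq_len(nrow(enc)), function(i) {
  cor(fit$norm_exposures[i, m$a], truth_expo[i, perm])
})
cat(sprintf("Per-sample exposure recovery vs truth: median r = %.3f\n",
            median(r, na.rm = TRUE)))
write.table(data.frame(sample = rownames(enc), fit$norm_exposures),
            "results/cn_exposures.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
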