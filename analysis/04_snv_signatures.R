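#!/usr/bin/env Rscript
# 96-channel spectra and reference-signature fits, pooled by histology and
# platinum response (sample-level fits only at >= 50 SNVs).

library(tgctsig)

samples <- read.delim("results/cohort/samples.tsv")
calls <- read.delim("results/variants_filtered.tsv")
sigs <- synthetic_snv_signatures()

spectra <- t(sapply(samples$sample, function(s) {
  as.numeric(build_spectrum(calls[calls$sample == s, ]))
}))
colnames(spectra) <- sig_channels()

grp <- interaction(samples$histology, samples$response, drop = TRUE)
fits <- pool_and_fit(spectra, grp, sigs)

expo <- t(sapply(fits$group, function(f) c(f$weights, residual = f$residual)))
write.table(data.frame(group = rownames(expo), expo, check.names = FALSE),
            "results/snv_signature_exposures.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Group-level signature exposures (top 3 per group):\n")
for (g in rownames(expo)) {
  top <- sort(expo[g, 1:30], decreasing = TRUE)[1:3]
  cat(sprintf("  %-28s %s\n", g,
              paste(sprintf("%s=%.2f", names(top), top), collapse = "  ")))
}
cat(sprintf("Samples with >= 50 SNVs fit individually: %d\n",
            length(fits$sample)))
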