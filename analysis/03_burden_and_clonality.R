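#!/usr/bin/env Rscript
# Tumour mutation burden per megabase with covariate-adjusted comparison of
# resistant vs sensitive disease (linear model + permutation check), mutation
# multiplicity/clonality for the planted driver genes, and pathway assignment.

library(tgctsig)

samples <- read.delim("results/cohort/samples.tsv")
calls <- read.delim("results/variants_filtered.tsv")
profiles <- read_seg("results/cohort/profiles.seg.tsv")
capture_bases <- 30e6

tmb <- compute_tmb(calls, capture_bases, samples = samples$sample)
d <- merge(samples, tmb, by = "sample")
write.table(tmb, "results/tmb.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

prim <- d[d$stage == "primary", ]
fit <- fit_glm(tmb_nonsyn ~ response + histology + dataset, prim,
               family = "gaussian")
print(fit$coefficients)
perm <- permutation_lm(tmb_nonsyn ~ response + histology, prim,
                       n_perm = 2000, seed = 41)
print(perm)

# clonality of driver mutations
drv <- calls[calls$gene %in% c("KIT", "KRAS", "TP53", "CTNNB1"), ]
mult <- do.call(rbind, lapply(split(drv, drv$sample), function(v) {
  variant_multiplicity(v, profiles[[v$sample[1]]])
}))
write.table(mult, "results/driver_multiplicity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Driver mutations: %d; clonal (multiplicity > 0.8): %.0f%%\n",
            nrow(mult), 100 * mean(mult$clonal)))

calls$pathway <- assign_pathway(calls$gene)
print(table(calls$pathway))
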