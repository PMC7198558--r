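#!/usr/bin/env Rscript
# Simulate the synthetic multi-cohort TGCT-like study population used by the
# downstream analyses: 300 cases with clinical covariates, planted gene
# effects, copy-number signature exposures, serial tumours and per-site read
# counts. Writes the cohort tables under results/cohort/.

library(tgctsig)

cfg <- cohort_config(n_cases = 300, seed = 20260927)
cohort <- generate_cohort(cfg)
dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

cat(sprintf("Simulated %d tumours from %d cases (%d resistant, %d seminoma)\n",
            nrow(cohort$samples), length(unique(cohort$samples$case)),
            sum(cohort$samples$response[!duplicated(cohort$samples$case)] ==
                  "resistant"),
            sum(cohort$samples$histology[!duplicated(cohort$samples$case)] ==
                  "seminoma")))
cat(sprintf("Variant calls (incl. caller false positives): %d\n",
            nrow(cohort$variants)))
cat("Cohort written to results/cohort/\n")
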