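#!/usr/bin/env Rscript
# Serial-tumour analyses: force-calling presence/absence, truncal/private
# classification, Jaccard concordance, minimum-event CN phylogenies rooted at
# a diploid outgroup, and CN events against months since diagnosis.

library(tgctsig)

samples <- read.delim("results/cohort/samples.tsv")
fc <- read.delim("results/cohort/force_calls.tsv")
profiles <- read_seg("results/cohort/profiles.seg.tsv")

fc$status <- force_call(fc$alt, fc$depth)
multi <- names(which(table(samples$case[!duplicated(samples$sample)]) >= 2))
fc <- fc[fc$case %in% multi, ]
sharing <- classify_sharing(fc)
write.table(sharing, "results/sharing_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(table(sharing$class))

# Jaccard concordance between tumours of each case
jac <- unlist(lapply(multi, function(cs) {
  ids <- unique(fc$sample[fc$case == cs])
  sets <- lapply(ids, function(s) {
    fc$variant_id[fc$sample == s & fc$status == "present"]
  })
  if (length(sets) < 2) return(NULL)
  m <- jaccard_matrix(setNames(sets, ids))
  m[upper.tri(m)]
}))
cat(sprintf("Inter-tumour Jaccard over %d pairs: range %.0f-%.0f, median %.0f\n",
            length(jac), min(jac), max(jac), median(jac)))

# phylogeny for one three-sample case, if present
tri <- names(which(table(samples$case) >= 3))
if (length(tri)) {
  cs <- tri[1]
  ids <- samples$sample[samples$case == cs]
  m <- cn_distance_matrix(profiles[ids])
  tree <- build_tree(m)
  ape::write.tree(tree, "results/example_tree.nwk")
  cat("Example phylogeny (", cs, "):",
      ape::write.tree(tree), "\n")
}

# CN events vs months since diagnosis in metastases
met <- samples[samples$stage == "metastasis", ]
ev_count <- sapply(profiles[met$sample], function(p) nrow(p$segments) - 22)
fit <- events_vs_time(ev_count, met$months_since_diagnosis)
cat(sprintf("CN events vs months: slope %.2f, r^2 = %.2f, p = %.3g\n",
            fit$slope, fit$r_squared, fit$p))
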