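test_that("identical config and seed give identical cohorts", {
  cfg <- cohort_config(n_cases = 8, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(n_cases = 8, seed = 8))
  expect_false(identical(c1$variants, c3$variants))
})

test_that("configuration validation catches invalid prevalences", {
  expect_error(cohort_config(p_resistant = 1.2), "configuration error")
  expect_error(cohort_config(samples_per_case = c("1" = 0.7, "2" = 0.7)),
               "sum to 1")
  expect_error(cohort_config(exposure_alpha = rep(1, 3)), "exposure_alpha")
})

test_that("truncal fraction 1 gives Jaccard 100 between a case's tumours", {
  cfg <- cohort_config(n_cases = 6, seed = 3, truncal_fraction = 1,
                       caller_fpr = 0)
  coh <- generate_cohort(cfg)
  multi <- names(which(table(coh$samples$case) >= 2))
  expect_gt(length(multi), 0)
  for (cs in multi) {
    ids <- coh$samples$sample[coh$samples$case == cs]
    sets <- lapply(ids, function(s) {
      coh$variants$variant_id[coh$variants$sample == s]
    })
    if (any(lengths(sets) == 0)) next
    for (i in 2:length(sets)) {
      expect_equal(jaccard_index(sets[[1]], sets[[i]]), 100)
    }
  }
})

test_that("VAF follows the multiplicity model at high depth", {
  # clonal variant, purity p, CN 2, multiplicity 1: expected VAF = p/2
  cfg <- cohort_config(n_cases = 40, seed = 11, depth_mean = 400,
                       clonal_fraction = 1, caller_fpr = 0,
                       ploidy_mean = 2, ploidy_sd = 0)
  coh <- generate_cohort(cfg)
  v <- merge(coh$variants, coh$samples[, c("sample", "purity")], by = "sample")
  v <- v[v$true_multiplicity == 1, ]
  cn <- mapply(function(s, ch, pos) {
    tgctsig:::lookup_total_cn(coh$profiles[[s]], ch, pos)
  }, v$sample, v$chrom, v$pos)
  v <- v[!is.na(cn) & abs(cn - 2) < 1e-9, ]
  expect_gt(nrow(v), 100)
  expected <- v$purity / 2
  z <- (v$vaf - expected) / sqrt(expected * (1 - expected) / v$depth)
  # binomial sampling error: standardised residuals ~ N(0,1)
  expect_lt(abs(mean(z)), 0.2)
  expect_lt(mean(abs(z) > 3), 0.01)
})

test_that("caller consensus retention matches the closed-form binomial", {
  sens <- c(strelka = 0.9, mutect = 0.9, mutect2 = 0.9)
  det <- with_seed(5, simulate_caller_calls(4000, sens, fpr = 0))
  n_callers <- lengths(strsplit(det$callers, ","))
  retained <- mean(n_callers >= 2)
  p2of3 <- 3 * 0.9^2 * 0.1 + 0.9^3  # P(>= 2 of 3) = 0.972
  expect_lt(abs(retained - p2of3), 3 * sqrt(p2of3 * (1 - p2of3) / 4000))
  # boundary sensitivities
  all3 <- with_seed(1, simulate_caller_calls(50, c(a = 1, b = 1, c = 1)))
  expect_true(all(all3$callers == "a,b,c"))
  none <- with_seed(1, simulate_caller_calls(50, c(a = 0, b = 0, c = 0)))
  expect_true(all(none$callers == ""))
})

test_that("generated profiles tile the genome without gaps or overlaps", {
  g <- tgct_genome()
  prof <- generate_cn_profile(c(0.3, 0.3, 0.2, 0.1, 0.1), ploidy = 3.2,
                              n_events = 80, seed = 13)
  segs <- prof$segments
  for (i in seq_len(nrow(g))) {
    s <- segs[segs$chrom == g$chrom[i], ]
    expect_equal(s$start[1], 1)
    expect_equal(s$end[nrow(s)], g$length[i])
    if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)] + 1)
  }
  expect_true(all(segs$major >= segs$minor))
  expect_true(all(segs$minor >= 0))
  expect_equal(segs$total, segs$major + segs$minor)
})

test_that("zero events give whole-chromosome segments at the ploidy", {
  prof <- generate_cn_profile(rep(0.2, 5), ploidy = 2, n_events = 0, seed = 1)
  expect_equal(nrow(prof$segments), 22)
  expect_true(all(prof$segments$total == 2))
  expect_error(generate_cn_profile(c(0.5, 0.5), seed = 1), "signatures")
})

test_that("pure-signature profiles re-encode closest to their own signature", {
  W <- synthetic_cn_signatures()
  model <- default_component_model()
  g <- tgct_genome()
  ref <- reference_encodings(W, model, g, ploidy = 3, n_events = 60,
                             n_samples = 15, seed = 21)
  with_seed(22, {
    for (k in 1:5) {
      enc <- rowMeans(sapply(1:15, function(i) {
        p <- generate_cn_profile(as.numeric(1:5 == k), W, model, g,
                                 ploidy = 3, n_events = 60)
        encode_sample(extract_features(p, g), model)$encoding
      }))
      cors <- apply(ref, 1, function(w) cor(enc, w))
      expect_equal(unname(which.max(cors)), k)
      expect_gt(cosine_sim(enc, ref[k, ]), 0.9)
    }
  })
})

test_that("direct feature sampling reflects the planted mixture", {
  W <- synthetic_cn_signatures()
  model <- default_component_model()
  with_seed(31, {
    f <- sample_cn_features(c(1, 0, 0, 0, 0), W, model, n_events = 5000)
    # CN1 is dominated by very large segments
    expect_gt(mean(f$segsize > 50), 0.6)
    f4 <- sample_cn_features(c(0, 0, 0, 1, 0), W, model, n_events = 5000)
    expect_gt(mean(f4$segsize < 2), 0.6)
  })
  expect_error(sample_cn_features(c(2, -1, 0, 0, 0), W, model), "sum to 1")
})

test_that("planted TMB shift and gene effects are recoverable downstream", {
  cfg <- cohort_config(n_cases = 300, seed = 17, caller_fpr = 0)
  coh <- generate_cohort(cfg)
  filt <- filter_variants(coh$variants, apply_artifact_filter = FALSE)
  tmb <- compute_tmb(filt$calls, cfg$capture_mb * 1e6,
                     samples = coh$samples$sample)
  d <- merge(coh$samples, tmb, by = "sample")
  d <- d[d$stage == "primary", ]
  fit <- fit_glm(tmb_nonsyn ~ response + histology, d, family = "gaussian")
  est <- fit$coefficients$estimate[grepl("response", fit$coefficients$term)]
  sgn <- if (grepl("sensitive", fit$coefficients$term[
    grepl("response", fit$coefficients$term)])) -1 else 1
  # planted +0.35/Mb in resistant cases (filtering removes a fraction of
  # calls, so recovery is tested with a generous margin)
  expect_gt(sgn * est, 0.15)
  # KIT mutations planted toward sensitivity: log-OR < 0 for resistance
  kit <- tapply(coh$samples$case, coh$samples$case, function(x) x[1])
  cases <- coh$samples[!duplicated(coh$samples$case), ]
  cases$kit <- cases$case %in% coh$variants$case[coh$variants$gene == "KIT"]
  gfit <- fit_glm(kit ~ response, cases, family = "binomial")
  b <- gfit$coefficients$estimate[2]
  expect_lt(b * ifelse(grepl("sensitive", gfit$coefficients$term[2]), -1, 1),
            0)
})

test_that("cohorts write to plain-text files and variants round-trip", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_config(n_cases = 4, seed = 2))
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "samples.tsv", "variants.tsv", "variants.vcf", "profiles.seg.tsv",
    "force_calls.tsv", "truth_exposures.tsv")))))
  v <- read_maf(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v), nrow(coh$variants))
  profs <- read_seg(file.path(dir, "profiles.seg.tsv"))
  expect_equal(length(profs), length(coh$profiles))
  expect_equal(profs[[1]]$segments$total, coh$profiles[[1]]$segments$total)
  vcf <- readLines(file.path(dir, "variants.vcf"))
  expect_true(startsWith(vcf[1], "##fileformat=VCF"))
  expect_equal(sum(!startsWith(vcf, "#")), nrow(coh$variants))
})
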