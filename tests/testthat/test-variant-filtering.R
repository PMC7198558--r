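test_that("consensus filter retains calls with >= 2 callers and logs empties", {
  calls <- make_calls(
    make_call(callers = "strelka,mutect"),
    make_call(callers = "mutect2"),
    make_call(callers = ""),
    make_call(callers = "strelka,mutect,mutect2")
  )
  out <- consensus_filter(calls)
  expect_equal(nrow(out), 2)
  audit <- attr(out, "audit")
  expect_equal(audit$rule, c("consensus", "empty_caller_set"))
  expect_equal(nrow(consensus_filter(calls[0, ])), 0)
})

test_that("strand/quality thresholds are inclusive and reasons are coded", {
  calls <- make_calls(
    make_call(alt_fwd = 3L, alt_rev = 0L, base_qual = 30, map_qual = 60),
    make_call(alt_fwd = 1L, alt_rev = 1L, base_qual = 26, map_qual = 50),
    make_call(alt_fwd = 2L, alt_rev = 2L, base_qual = 25.9, map_qual = 60),
    make_call(alt_fwd = NA_integer_)
  )
  sq <- strand_quality_filter(calls)
  expect_equal(sq$pass, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(sq$reason,
               c("strand_bias", NA, "low_quality", "missing_fields"))
})

test_that("oxog-only mode exempts non-C>A substitutions", {
  calls <- make_calls(
    make_call(ref = "C", alt = "A", alt_fwd = 3L, alt_rev = 0L),
    make_call(ref = "C", alt = "T", alt_fwd = 3L, alt_rev = 0L)
  )
  sq <- strand_quality_filter(calls, oxog_only_ca = TRUE)
  expect_equal(sq$pass, c(FALSE, TRUE))
})

test_that("hard filter boundaries match the stated rules exactly", {
  calls <- make_calls(
    make_call(class = "SNV", alt_reads = 5L, vaf = 0.05),
    make_call(class = "SNV", alt_reads = 4L, vaf = 0.30),
    make_call(class = "SNV", alt_reads = 10L, vaf = 0.049),
    make_call(class = "indel", alt_reads = 9L, vaf = 0.20),
    make_call(class = "indel", alt_reads = 10L, vaf = 0.05)
  )
  expect_equal(hard_filter(calls), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_error(hard_filter(make_call(class = "SV")), "unknown variant class")
})

test_that("rescue fires on knowledge flags and sibling-tumour passes", {
  calls <- make_calls(
    make_call(alt_reads = 3L, vaf = 0.02, oncokb_driver = TRUE),
    make_call(alt_reads = 3L, vaf = 0.02, cosmic_count = 49L),
    make_call(alt_reads = 3L, vaf = 0.02, cosmic_count = 50L),
    # failing call in primary; identical variant passes in the metastasis
    make_call(pos = 555L, sample = "s1", alt_reads = 3L, vaf = 0.02),
    make_call(pos = 555L, sample = "s2", alt_reads = 7L, vaf = 0.10),
    # same position but different case: no sibling rescue
    make_call(pos = 555L, sample = "s9", case = "c9", alt_reads = 3L,
              vaf = 0.02)
  )
  hp <- hard_filter(calls)
  r <- rescue(calls, hp)
  expect_equal(r, c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("dataset artifact rule removes 10%/1% genes at both granularities", {
  mk <- function(gene, case, dataset, pos = 1000L) {
    make_call(gene = gene, case = case, sample = paste0(case, "_t"),
              dataset = dataset, pos = pos)
  }
  # gene ART: 2/10 cases (20%) in A, 0 in B/C -> removed
  # gene OK12: 12% in A but 2/40 = 5% in B -> kept
  # boundary: 9.9% (not >= 10%) -> kept
  calls <- rbind(
    mk("ART", "a1", "A"), mk("ART", "a2", "A"),
    mk("OK12", "a3", "A", pos = 2000L), mk("OK12", "b1", "B", pos = 2000L),
    mk("KEEP", "b2", "B", pos = 3000L)
  )
  sizes <- c(A = 10, B = 40, C = 20)
  out <- dataset_artifact_filter(calls, dataset_sizes = sizes)
  expect_equal(out$removed_genes, "ART")
  expect_false("OK12" %in% out$removed_genes)
  expect_true(all(out$calls$gene != "ART"))
  # boundary 9.9%: 99/1000 cases in A
  many <- do.call(rbind, lapply(1:99, function(i) mk("EDGE", paste0("x", i), "A")))
  out2 <- dataset_artifact_filter(rbind(many, mk("other", "b9", "B")),
                                  dataset_sizes = c(A = 1000, B = 50))
  expect_false("EDGE" %in% out2$removed_genes)
  expect_warning(dataset_artifact_filter(mk("G", "c", "A")), "2 datasets")
})

test_that("capture intersect arithmetic and call restriction", {
  bed_a <- data.frame(chrom = "1", start = 0, end = 100)
  bed_b <- data.frame(chrom = "1", start = 50, end = 150)
  ci <- capture_intersect(NULL, list(bed_a, bed_b))
  expect_equal(ci$intersect$start, 50)
  expect_equal(ci$intersect$end, 100)
  expect_equal(ci$bases, 50)
  calls <- make_calls(make_call(pos = 75L), make_call(pos = 120L))
  ci2 <- capture_intersect(calls, list(bed_a, bed_b))
  expect_equal(nrow(ci2$calls), 1)
  expect_equal(ci2$calls$pos, 75L)
  # identity and empty cases
  self <- capture_intersect(NULL, list(bed_a, bed_a))
  expect_equal(self$bases, 100)
  disjoint <- capture_intersect(calls, list(
    bed_a, data.frame(chrom = "1", start = 500, end = 600)))
  expect_equal(disjoint$bases, 0)
  expect_equal(nrow(disjoint$calls), 0)
})

test_that("capture intersect is commutative and associative", {
  beds <- list(
    data.frame(chrom = c("1", "1", "2"), start = c(0, 200, 10),
               end = c(120, 300, 90)),
    data.frame(chrom = c("1", "2"), start = c(50, 0), end = c(260, 50)),
    data.frame(chrom = c("1", "2"), start = c(100, 20), end = c(250, 80))
  )
  base <- capture_intersect(NULL, beds)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    alt <- capture_intersect(NULL, beds[perm])
    expect_equal(alt$intersect, base$intersect)
  }
  # associativity: ((a ^ b) ^ c) == a ^ b ^ c
  ab <- capture_intersect(NULL, beds[1:2])$intersect
  abc <- capture_intersect(NULL, list(ab, beds[[3]]))$intersect
  expect_equal(abc, base$intersect)
})

test_that("read_bed rejects malformed lines with a line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t0\t100", "1\tfoo\t200"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("track name=x", "1\t0\t100"), path)
  expect_equal(read_bed(path)$end, 100)
})

test_that("filtering is monotone in caller support and order-insensitive", {
  set.seed(11)
  calls <- do.call(rbind, lapply(1:60, function(i) {
    make_call(
      pos = 1000L + i,
      sample = sample(c("s1", "s2"), 1), case = "c1",
      dataset = sample(c("A", "B"), 1),
      class = sample(c("SNV", "indel"), 1),
      alt_reads = sample(3:15, 1), vaf = round(runif(1, 0.01, 0.4), 3),
      alt_fwd = sample(0:5, 1), alt_rev = sample(0:5, 1),
      base_qual = round(runif(1, 24, 36), 1),
      map_qual = round(runif(1, 45, 60), 1),
      callers = paste(sample(c("strelka", "mutect", "mutect2"),
                             sample(0:3, 1)), collapse = ","),
      oncokb_driver = runif(1) < 0.1,
      cosmic_count = sample(c(0L, 49L, 50L, 120L), 1)
    )
  }))
  res <- filter_variants(calls)
  # monotone: adding a caller never removes a retained call
  more <- calls
  add_one <- function(cs) {
    have <- strsplit(cs, ",")[[1]]
    miss <- setdiff(c("strelka", "mutect", "mutect2"), have)
    if (length(miss)) paste(c(have, miss[1]), collapse = ",") else cs
  }
  more$callers <- vapply(more$callers, add_one, character(1))
  res_more <- filter_variants(more)
  key <- function(d) paste(d$sample, d$pos)
  expect_true(all(key(res$calls) %in% key(res_more$calls)))
  # order-insensitivity: retained set is a pure function of the rules
  perm <- sample(nrow(calls))
  res_perm <- filter_variants(calls[perm, ])
  expect_setequal(key(res_perm$calls), key(res$calls))
})
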