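test_that("a flat diploid genome yields the trivial feature set", {
  g <- toy_genome()
  prof <- toy_profile(list(c("1", 1, 2e8, 2), c("2", 1, 1.5e8, 2)))
  f <- extract_features(prof, g)
  expect_equal(length(f$segsize), 2)
  expect_true(all(f$bp10MB == 0))
  expect_equal(length(f$bp10MB), ceiling(2e8 / 1e7) + ceiling(1.5e8 / 1e7))
  expect_length(f$changepoint, 0)
  expect_equal(f$copynumber, c(2, 2))
  expect_true(all(f$bpchrarm == 0))
  expect_length(f$bpchrarm, 4)  # toy genome: 2 chromosomes, p+q each
  expect_length(f$osCN, 0)
})

test_that("change-points, windows and arms count the same junctions", {
  g <- toy_genome()
  prof <- toy_profile(list(
    c("1", 1, 5e7, 2), c("1", 5e7 + 1, 1.2e8, 4.5), c("1", 1.2e8 + 1, 2e8, 2),
    c("2", 1, 1.5e8, 3)
  ))
  f <- extract_features(prof, g)
  expect_equal(sort(f$changepoint), c(2.5, 2.5))
  expect_equal(sum(f$bp10MB), 2)
  expect_equal(sum(f$bpchrarm), 2)
  # junction positions: window 5 on chr1 (50 Mb) and window 12 (120 Mb)
  expect_equal(which(f$bp10MB > 0), c(5, 12))
})

test_that("junctions with equal rounded copy number are not breakpoints", {
  g <- toy_genome()
  prof <- toy_profile(list(c("1", 1, 1e8, 2.1), c("1", 1e8 + 1, 2e8, 2.4),
                           c("2", 1, 1.5e8, 2)))
  f <- extract_features(prof, g)
  expect_equal(sum(f$bp10MB), 0)  # round(2.1) == round(2.4)
  expect_equal(f$changepoint, 0.3, tolerance = 1e-9)  # still a change-point
})

test_that("oscillating chain detection matches the example and the oracle", {
  g <- toy_genome()
  prof <- toy_profile(list(
    c("1", 1, 1e7, 2), c("1", 1e7 + 1, 2e7, 3), c("1", 2e7 + 1, 3e7, 2),
    c("1", 3e7 + 1, 4e7, 3), c("1", 4e7 + 1, 2e8, 2),
    c("2", 1, 1.5e8, 2)
  ))
  f <- extract_features(prof, g)
  expect_equal(f$osCN, 5)
  # exhaustive scan over all rounded CN sequences of length <= 6, states 1..3
  for (len in 3:6) {
    grid <- as.matrix(expand.grid(rep(list(1:3), len)))
    for (i in seq_len(nrow(grid))) {
      states <- grid[i, ]
      expect_equal(sort(tgctsig:::oscillating_chains(states)),
                   oscillation_oracle(states),
                   info = paste(states, collapse = ","))
    }
  }
  # seeded random sequences of length 7-8 over 4 states
  set.seed(404)
  for (i in 1:2000) {
    states <- sample(1:4, sample(7:8, 1), replace = TRUE)
    expect_equal(sort(tgctsig:::oscillating_chains(states)),
                 oscillation_oracle(states),
                 info = paste(states, collapse = ","))
  }
})

test_that("unsorted or overlapping segments are rejected", {
  segs <- data.frame(chrom = "1", start = c(1, 50), end = c(100, 120),
                     major = 1, minor = 1, total = 2)
  expect_error(cn_profile("s", segs), "overlapping")
})

test_that("encoding sums posteriors to the observation counts per feature", {
  model <- default_component_model()
  g <- tgct_genome()
  prof <- with_seed(8, generate_cn_profile(rep(0.2, 5), ploidy = 3,
                                           n_events = 40))
  f <- extract_features(prof, g)
  enc <- encode_sample(f, model)
  expect_length(enc$encoding, 36)
  for (feat in cn_feature_names()) {
    block <- sum(enc$encoding[model$component[model$feature == feat]])
    expect_equal(block, unname(enc$counts[feat]), tolerance = 1e-6)
  }
})

test_that("one observation at a lone component's mean encodes to exactly 1", {
  model <- default_component_model()
  lone <- model[model$feature == "segsize", ][1, , drop = FALSE]
  lone$weight <- 1
  class(lone) <- c("cn_component_model", "data.frame")
  f <- structure(list(segsize = lone$p1, bp10MB = numeric(0),
                      changepoint = numeric(0), copynumber = numeric(0),
                      bpchrarm = numeric(0), osCN = numeric(0)),
                 class = "cn_features")
  enc <- encode_sample(f, lone)
  expect_equal(unname(enc$encoding), 1)
})

test_that("features are invariant to the stored order of segments", {
  g <- toy_genome()
  rows <- list(
    c("1", 1, 5e7, 2), c("1", 5e7 + 1, 1.1e8, 3), c("1", 1.1e8 + 1, 2e8, 2),
    c("2", 1, 7e7, 4), c("2", 7e7 + 1, 1.5e8, 2)
  )
  f1 <- extract_features(toy_profile(rows), g)
  f2 <- extract_features(toy_profile(rev(rows)), g)
  expect_equal(f1, f2)
})

test_that("mixture fitting recovers well-separated components", {
  set.seed(12)
  x_norm <- c(rnorm(400, 2, 0.3), rnorm(400, 10, 1))
  x_pois <- c(rpois(400, 0.5), rpois(400, 8))
  fs <- list(structure(list(
    segsize = x_norm, bp10MB = x_pois,
    changepoint = rnorm(200, 1, 0.2), copynumber = rnorm(200, 3, 0.3),
    bpchrarm = rpois(200, 2), osCN = rpois(200, 1)
  ), class = "cn_features"))
  m <- fit_component_model(fs, n_components = c(
    segsize = 2, bp10MB = 2, changepoint = 1, copynumber = 1,
    bpchrarm = 1, osCN = 1))
  seg <- m[m$feature == "segsize", ]
  expect_equal(seg$p1, c(2, 10), tolerance = 0.15)
  bp <- m[m$feature == "bp10MB", ]
  expect_equal(bp$p1, c(0.5, 8), tolerance = 0.3)
  expect_equal(nrow(m), 8)
  # single-valued Poisson data: one component at that rate
  fs2 <- fs
  fs2[[1]]$bpchrarm <- rep(3, 100)
  m2 <- fit_component_model(fs2, n_components = c(
    segsize = 2, bp10MB = 2, changepoint = 1, copynumber = 1,
    bpchrarm = 1, osCN = 1))
  expect_equal(m2$p1[m2$feature == "bpchrarm"], 3)
  expect_error(
    fit_component_model(fs, n_components = c(
      segsize = 1000, bp10MB = 2, changepoint = 1, copynumber = 1,
      bpchrarm = 1, osCN = 1)),
    "fewer observations")
})

test_that("requested component counts sum as configured (36 by default)", {
  m <- default_component_model()
  expect_equal(nrow(m), 36)
  counts <- table(m$feature)
  expect_equal(unname(counts[cn_feature_names()]),
               c(10, 3, 7, 8, 5, 3), ignore_attr = TRUE)
  w <- tapply(m$weight, m$feature, sum)
  expect_true(all(abs(w - 1) < 1e-8))
})

test_that("component model round-trips through TSV", {
  m <- default_component_model()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_component_model(m, path)
  m2 <- read_component_model(path)
  expect_equal(m2$p1, m$p1)
  expect_equal(m2$weight, m$weight, tolerance = 1e-9)
})
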