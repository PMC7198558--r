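test_that("force-calling matches the full truth table over alt x depth", {
  for (alt in c(0L, 1L, 2L, 5L)) {
    for (depth in c(30L, 49L, 50L, 51L, 100L)) {
      expected <- if (alt >= 2) "present"
                  else if (depth >= 50) "absent"
                  else "indeterminate"
      expect_equal(force_call(alt, depth), expected,
                   info = sprintf("alt=%d depth=%d", alt, depth))
    }
  }
  expect_error(force_call(-1, 10), "non-negative")
})

test_that("sharing classes follow the presence pattern across tumours", {
  presence <- data.frame(
    case = "c1",
    variant = rep(c("v_truncal", "v_prim", "v_met", "v_ind"), each = 3),
    sample = rep(c("t1", "t2", "t3"), 4),
    status = c("present", "present", "present",
               "present", "absent", "absent",
               "absent", "present", "present",
               "indeterminate", "present", "absent"),
    stage = rep(c("primary", "metastasis", "metastasis"), 4),
    stringsAsFactors = FALSE
  )
  out <- classify_sharing(presence)
  cls <- setNames(out$class, out$variant)
  expect_equal(unname(cls["v_truncal"]), "truncal")
  expect_equal(unname(cls["v_prim"]), "primary_only")
  expect_equal(unname(cls["v_met"]), "metastasis_only")
  # indeterminate primary excluded from the denominator: the two informative
  # metastases (present + absent) confine the variant to the metastases
  expect_equal(unname(cls["v_ind"]), "metastasis_only")
  # with a single informative site the pattern is unclassifiable
  two <- data.frame(case = "c2", variant = "v", sample = c("t1", "t2"),
                    status = c("indeterminate", "present"),
                    stage = c("primary", "metastasis"))
  expect_equal(classify_sharing(two)$class, "other")
  strict <- classify_sharing(presence, indeterminate = "strict")
  expect_equal(strict$class[strict$variant == "v_ind"], "other")
  # truncal under exclusion: indeterminate site dropped from the denominator
  p2 <- presence[presence$variant == "v_ind", ]
  p2$status <- c("indeterminate", "present", "present")
  expect_equal(classify_sharing(p2)$class, "truncal")
  expect_equal(classify_sharing(p2, "strict")$class, "other")
  # single-tumour cases are skipped
  single <- presence[presence$sample == "t1", ]
  expect_null(classify_sharing(single))
})

test_that("Jaccard index arithmetic and bounds", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 100)
  expect_equal(jaccard_index("a", "b"), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 50)
  expect_message(j0 <- jaccard_index(character(0), character(0)), "empty")
  expect_equal(j0, 0)
  # monotone under adding shared variants
  a <- c("a", "b", "c"); b <- c("b", "x")
  expect_gt(jaccard_index(c(a, "z"), c(b, "z")), jaccard_index(a, b))
  m <- jaccard_matrix(list(s1 = a, s2 = b))
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(s1 = 100, s2 = 100))
})

test_that("profiles are re-segmented to the union breakpoint grid", {
  a <- toy_profile(list(c("1", 1, 100, 2), c("1", 101, 400, 3)))
  b <- toy_profile(list(c("1", 1, 200, 2), c("1", 201, 400, 4)))
  al <- align_profiles(list(a, b))
  expect_equal(al[[1]]$segments$start, c(1, 101, 201))
  expect_equal(al[[1]]$segments$total, c(2, 3, 3))
  expect_equal(al[[2]]$segments$total, c(2, 2, 4))
})

test_that("minimum-event distance: identities, single event, LOH asymmetry", {
  a <- allele_profile(c(2, 2, 2))
  b <- allele_profile(c(3, 3, 2))
  expect_equal(cn_event_distance(a, a), 0)
  expect_equal(cn_event_distance(a, b), 1)
  # regaining a lost allele is impossible: minor 0 -> 1 is infinite one way
  lost <- toy_profile(list(c("1", 1, 100, 1)))
  lost$segments$minor <- 0; lost$segments$major <- 1
  dip <- toy_profile(list(c("1", 1, 100, 2)))
  dip$segments$minor <- 1; dip$segments$major <- 1
  expect_equal(cn_event_distance(lost, dip, symmetric = FALSE), Inf)
  expect_equal(cn_event_distance(dip, lost, symmetric = FALSE), 1)
  expect_equal(cn_event_distance(dip, lost), Inf)  # symmetrised by max
  expect_error(cn_event_distance(a, allele_profile(c(2, 2))), "grids")
})

test_that("minimum-event distance equals the BFS oracle (length <= 3 here)", {
  skip_if_not_installed("Matrix")
  for (len in 1:3) {
    oracle <- bfs_distance_matrix(len, cap = 4)
    got <- vapply(seq_len(nrow(oracle$states)), function(j) {
      closed_form_to_target(oracle$states, oracle$states[j, ])
    }, numeric(nrow(oracle$states)))
    expect_equal(got, oracle$d, ignore_attr = TRUE)
    # spot-check that the vectorised form agrees with the scalar one
    set.seed(len)
    for (rep in 1:50) {
      i <- sample.int(nrow(oracle$states), 2)
      expect_equal(
        tgctsig:::allele_event_distance(oracle$states[i[1], ],
                                        oracle$states[i[2], ]),
        oracle$d[i[1], i[2]])
    }
  }
})

test_that("distance matrix appends a diploid root and symmetrises", {
  profs <- list(
    p1 = toy_profile(list(c("1", 1, 100, 2), c("1", 101, 200, 3))),
    p2 = toy_profile(list(c("1", 1, 200, 2)))
  )
  for (nm in names(profs)) profs[[nm]]$sample <- nm
  m <- cn_distance_matrix(profs)
  expect_equal(dim(m), c(3, 3))
  expect_true("diploid" %in% rownames(m))
  expect_true(isSymmetric(m))
  expect_equal(diag(m), setNames(c(0, 0, 0), rownames(m)))
  # p2 is diploid everywhere: distance 0 to the root
  expect_equal(m["p2", "diploid"], 0)
})

test_that("NJ reproduces the closed-form 3-taxon additive tree", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "diploid"),
                              c("a", "b", "diploid")))
  tr <- build_tree(d)
  expect_s3_class(tr, "phylo")
  # closed form: edge(a) = (d_ab + d_ac - d_bc)/2 = 1, edge(b) = 2, edge(c) = 4
  tip_edges <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                             tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(tip_edges["a"]), 1)
  expect_equal(unname(tip_edges["b"]), 2)
  expect_equal(unname(tip_edges["diploid"]), 4)
  expect_warning(build_tree(d[1:2, 1:2]), "trivial")
})

test_that("identical samples form a zero-length cherry", {
  profs <- list(
    p1 = toy_profile(list(c("1", 1, 200, 3))),
    p2 = toy_profile(list(c("1", 1, 200, 3))),
    p3 = toy_profile(list(c("1", 1, 200, 4)))
  )
  for (nm in names(profs)) profs[[nm]]$sample <- nm
  m <- cn_distance_matrix(profs)
  expect_equal(m["p1", "p2"], 0)
  tr <- build_tree(m)
  d_tree <- ape::cophenetic.phylo(tr)
  expect_equal(d_tree["p1", "p2"], 0)
})

test_that("metastases sharing a precursor form a clade", {
  set.seed(99)
  ok <- replicate(20, {
    # focal gain/neutral signature mixture: private homozygous losses make
    # the minimum-event distance infinite (allele regain), and whole-arm
    # events repeatedly overwrite the shared precursor events that carry the
    # phylogenetic signal, so the simulation plants the two focal copy-gain
    # signatures
    cfg <- cohort_config(n_cases = 1, seed = sample.int(1e6, 1),
                         samples_per_case = c("3" = 1),
                         exposure_alpha = c(0, 0, 1, 0, 1),
                         mean_cn_events = 40, met_event_rate = 0.8,
                         met_shared_fraction = 0.4)
    coh <- generate_cohort(cfg)
    m <- cn_distance_matrix(coh$profiles)
    tr <- build_tree(m)
    mets <- grep("T[23]$", rownames(m), value = TRUE)
    sub <- ape::extract.clade(tr, ape::getMRCA(tr, mets))
    setequal(sub$tip.label, mets)
  })
  expect_gte(mean(ok), 0.95)
})

test_that("events accumulate linearly with months since diagnosis", {
  fit <- suppressWarnings(events_vs_time(c(10, 20, 30, 40), c(5, 10, 15, 20)))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  flat <- events_vs_time(c(10, 10.1, 9.9, 10), c(5, 10, 15, 20))
  expect_lt(abs(flat$slope), 0.05)
  set.seed(3)
  months <- runif(30, 6, 48)
  ev <- 2 * months + rnorm(30, 0, 5)
  f <- events_vs_time(ev, months)
  ci <- confint(f$fit)["months", ]
  expect_true(ci[1] <= 2 && 2 <= ci[2])
  expect_error(events_vs_time(1:2, 1:2), "at least 3")
})
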