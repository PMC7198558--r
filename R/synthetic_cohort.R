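#' Synthetic cohort configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. Defaults
#' emulate the structure of a multi-cohort germ-cell tumour study: ~39%
#' platinum-resistant cases, ~33% seminomas, ~7.5% extragonadal primaries,
#' four WES datasets of unequal size, hyperploid genomes (80% of samples with
#' ploidy > 2.5), mean sequencing depth 130x, a ~30 Mb capture intersect, a
#' mean nonsynonymous burden of ~0.33 mutations/Mb with a planted
#' +0.35 /Mb shift in resistant cases, and per-case copy-number signature
#' exposures drawn flat on the simplex (giving each signature >5% exposure in
#' roughly 80% of samples).
#'
#' @param n_cases Number of cases.
#' @param seed Integer seed; a fixed seed gives byte-identical cohorts.
#' @param samples_per_case Named probability vector over per-case sample
#'   counts (names "1", "2", ...); cases with >= 2 samples get one primary
#'   plus metastases.
#' @param p_resistant,p_seminoma,p_extragonadal Covariate prevalences.
#' @param datasets Named probability vector over dataset labels.
#' @param purity_shape Beta shape parameters for purity.
#' @param ploidy_mean,ploidy_sd Truncated-normal ploidy parameters.
#' @param exposure_alpha Dirichlet concentration for true CN-signature
#'   exposures (length = number of CN signatures).
#' @param mean_cn_events Copy-number events per sample (fixed total,
#'   split between case-truncal and sample-private events by
#'   `truncal_fraction`).
#' @param truncal_fraction Fraction of a case's variants (and CN events)
#'   shared by all its tumours.
#' @param tmb_base Mean nonsynonymous mutations/Mb in sensitive cases.
#' @param tmb_resistant_shift Planted additive shift (mutations/Mb) in
#'   resistant cases.
#' @param syn_rate Synonymous/noncoding mutations per Mb.
#' @param capture_mb Capture intersect size (Mb).
#' @param depth_mean Mean read depth (Poisson).
#' @param clonal_fraction Fraction of variants that are clonal
#'   (multiplicity 1).
#' @param caller_sensitivity Named per-caller detection sensitivities
#'   (3 callers).
#' @param caller_fpr Expected false-positive calls per sample per caller.
#' @param planted_gene_effects `data.frame(gene, covariate, log_or,
#'   intercept)`: per-gene mutation log-odds models over case covariates
#'   (`covariate` one of "resistant", "seminoma", "extragonadal").
#' @param met_event_rate Extra CN events per month in metastases.
#' @param met_shared_fraction Events carried by the common metastatic
#'   precursor clone (shared by all of a case's metastases), as a fraction of
#'   `mean_cn_events`.
#' @param cn_signatures Signature-by-component matrix for CN generation.
#' @param component_model A `cn_component_model`.
#' @param snv_signatures Reference SNV signature matrix (rows sum to 1).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 50,
                          seed = 1,
                          samples_per_case = c("1" = 0.6, "2" = 0.25, "3" = 0.15),
                          p_resistant = 0.39,
                          p_seminoma = 0.33,
                          p_extragonadal = 0.075,
                          datasets = c(ICR1 = 0.07, ICR2 = 0.10,
                                       DFCI = 0.23, TCGA = 0.60),
                          purity_shape = c(7, 3),
                          ploidy_mean = 3.0, ploidy_sd = 0.6,
                          exposure_alpha = rep(1, 5),
                          mean_cn_events = 60,
                          truncal_fraction = 0.5,
                          tmb_base = 0.33,
                          tmb_resistant_shift = 0.35,
                          syn_rate = 0.10,
                          capture_mb = 30,
                          depth_mean = 130,
                          clonal_fraction = 0.85,
                          caller_sensitivity = c(strelka = 0.97, mutect = 0.95,
                                                 mutect2 = 0.90),
                          caller_fpr = 0.5,
                          planted_gene_effects = default_gene_effects(),
                          met_event_rate = 1.0,
                          met_shared_fraction = 0.3,
                          cn_signatures = synthetic_cn_signatures(),
                          component_model = default_component_model(),
                          snv_signatures = synthetic_snv_signatures()) {
  cfg <- as.list(environment())
  probs <- c(p_resistant, p_seminoma, p_extragonadal, samples_per_case,
             datasets, truncal_fraction, clonal_fraction, caller_sensitivity)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  if (abs(sum(samples_per_case) - 1) > 1e-8 || abs(sum(datasets) - 1) > 1e-8) {
    stop("configuration error: samples_per_case and datasets must sum to 1")
  }
  if (length(caller_sensitivity) != 3) {
    stop("configuration error: exactly 3 named callers are required")
  }
  if (length(exposure_alpha) != nrow(cn_signatures)) {
    stop("configuration error: exposure_alpha length must match signatures")
  }
  if (n_cases < 1 || mean_cn_events < 0 || tmb_base < 0 || capture_mb <= 0) {
    stop("configuration error: sizes and rates must be positive")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Default planted gene-covariate effects
#'
#' Log-odds models for driver-gene mutation probability against case
#' covariates: KIT mutation associated with platinum sensitivity, KRAS with
#' seminoma, TP53 and CTNNB1 (WNT pathway) with resistance.
#'
#' @return `data.frame(gene, covariate, log_or, intercept)`.
#' @export
default_gene_effects <- function() {
  data.frame(
    gene = c("KIT", "KRAS", "TP53", "CTNNB1"),
    covariate = c("resistant", "seminoma", "resistant", "resistant"),
    log_or = c(log(1 / 3), log(4), log(2.2), log(2)),
    intercept = stats::qlogis(c(0.18, 0.06, 0.05, 0.03)),
    stringsAsFactors = FALSE
  )
}

#' Draw a 96-channel spectrum from a signature mixture
#'
#' Multinomial draw of `n` mutations from the 96-channel distribution obtained
#' by mixing reference signatures with weights `mix`.
#'
#' @param mix Non-negative mixture weights over the reference signatures,
#'   summing to 1.
#' @param n Number of mutations (>= 0).
#' @param signatures Reference matrix signatures x 96, rows summing to 1.
#' @return An `snv_spectrum` (named integer vector of length 96).
#' @export
generate_spectrum <- function(mix, n, signatures = synthetic_snv_signatures()) {
  if (n < 0) stop("n must be >= 0")
  if (length(mix) != nrow(signatures)) stop("mixture/signature size mismatch")
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("mix must be non-negative and sum to 1")
  }
  p <- as.numeric(mix %*% signatures)
  counts <- if (n == 0) integer(96) else
    as.integer(stats::rmultinom(1, n, p))
  structure(stats::setNames(counts, sig_channels()), label = NULL,
            skipped = 0L, class = "snv_spectrum")
}

#' Simulate multi-caller detection
#'
#' Each true variant is detected independently by each of three named callers
#' with the stated sensitivity; false positives are injected per caller at the
#' stated expected rate (Poisson).
#'
#' @param n_variants Number of true variants.
#' @param sensitivities Named numeric vector of 3 per-caller sensitivities.
#' @param fpr Expected false-positive calls per caller.
#' @return List with `callers` (length-`n_variants` character vector of
#'   comma-separated caller sets, possibly empty) and `n_false_positives`
#'   (named integer vector per caller).
#' @export
simulate_caller_calls <- function(n_variants, sensitivities, fpr = 0) {
  if (length(sensitivities) != 3 || is.null(names(sensitivities))) {
    stop("exactly 3 named callers are required")
  }
  det <- vapply(sensitivities, function(s) {
    stats::rbinom(n_variants, 1, s) == 1
  }, logical(n_variants))
  det <- matrix(det, nrow = n_variants,
                dimnames = list(NULL, names(sensitivities)))
  callers <- apply(det, 1, function(row) {
    paste(names(sensitivities)[row], collapse = ",")
  })
  if (n_variants == 0) callers <- character(0)
  list(callers = as.character(callers),
       n_false_positives = stats::setNames(
         stats::rpois(3, fpr), names(sensitivities)))
}

# Dirichlet draw (one vector).
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Sample copy-number events from a signature mixture
#'
#' Draws `n` copy-number events attributed to signatures in proportion to the
#' exposure vector. Each event takes its segment size from the signature's
#' segment-size component mixture and its absolute copy number from the
#' signature's copy-number component mixture; events land uniformly within
#' chromosome arms, with the number of distinct arms per signature set so that
#' breakpoints-per-arm matches the signature's breakpoint mixture mean.
#' Signatures with high oscillation weight expand events into alternating
#' copy-number trains.
#'
#' @param n Number of events.
#' @param exposures Non-negative exposure vector summing to 1.
#' @param signatures Signature-by-component matrix (see
#'   [synthetic_cn_signatures()]).
#' @param model The matching `cn_component_model`.
#' @param genome Genome model.
#' @param background Background total copy number (used as the alternate state
#'   of oscillating trains).
#' @return `data.frame(chrom, start, end, total, signature)`; oscillating
#'   trains contribute several rows.
#' @export
sample_cn_events <- function(n, exposures, signatures, model, genome,
                             background = 2) {
  if (length(exposures) != nrow(signatures)) {
    stop("exposure vector length must equal the number of signatures")
  }
  if (any(exposures < 0) || abs(sum(exposures) - 1) > 1e-6) {
    stop("exposures must be non-negative and sum to 1")
  }
  if (n == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), total = numeric(0),
                      signature = integer(0)))
  }
  arms <- genome_arms(genome)
  sig_of <- sample.int(nrow(signatures), n, replace = TRUE, prob = exposures)
  rows <- list()
  for (k in unique(sig_of)) {
    nk <- sum(sig_of == k)
    w <- signatures[k, ]
    blk <- function(f) {
      i <- model$feature == f
      list(w = w[i] / sum(w[i]), p1 = model$p1[i], p2 = model$p2[i])
    }
    size_b <- blk("segsize"); cn_b <- blk("copynumber")
    arm_b <- blk("bpchrarm"); osc_b <- blk("osCN")
    # segment sizes (Mb -> bp), truncated positive
    comp <- sample.int(length(size_b$w), nk, replace = TRUE, prob = size_b$w)
    size_mb <- pmax(stats::rnorm(nk, size_b$p1[comp], size_b$p2[comp]), 0.05)
    comp <- sample.int(length(cn_b$w), nk, replace = TRUE, prob = cn_b$w)
    cn <- pmax(stats::rnorm(nk, cn_b$p1[comp], cn_b$p2[comp]), 0)
    # clustering: target breakpoints per affected arm = mixture mean
    lambda_arm <- sum(arm_b$w * arm_b$p1)
    n_arms <- max(1, min(nrow(arms), round(2 * nk / max(lambda_arm, 0.5))))
    arm_idx <- sample.int(nrow(arms), n_arms, prob = arms$end - arms$start)
    ev_arm <- arm_idx[sample.int(n_arms, nk, replace = TRUE)]
    # oscillation propensity: weight on components with rate >= 2
    p_osc <- sum(osc_b$w[osc_b$p1 >= 2])
    lambda_osc <- sum(osc_b$w * osc_b$p1)
    a <- arms[ev_arm, , drop = FALSE]
    size <- pmin(round(size_mb * 1e6), a$end - a$start)
    st <- floor(stats::runif(nk, a$start, pmax(a$start + 1, a$end - size)))
    en <- pmin(st + size - 1, a$end)
    oscil <- stats::runif(nk) < p_osc
    plain <- which(!oscil)
    if (length(plain)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = a$chrom[plain], start = st[plain], end = en[plain],
        total = cn[plain], signature = k, stringsAsFactors = FALSE)
    }
    for (j in which(oscil)) {
      k_seg <- min(11, max(3, stats::rpois(1, lambda_osc)))
      bounds <- round(seq(st[j], en[j] + 1, length.out = k_seg + 1))
      keep <- diff(bounds) >= 1
      tot <- rep(c(cn[j], background), length.out = k_seg)[keep]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = a$chrom[j], start = bounds[-length(bounds)][keep],
        end = (bounds[-1] - 1)[keep], total = tot, signature = k,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a copy-number profile from a signature mixture
#'
#' Forward-generates a segmented absolute copy-number profile: a background at
#' the sample ploidy tiles each chromosome, and copy-number events sampled
#' from the signature mixture (see [sample_cn_events()]) are overlaid in
#' order. Segments always tile each chromosome without gaps or overlaps.
#'
#' @param exposures Signature-mixture vector (non-negative, sums to 1).
#' @param signatures Signature-by-component matrix.
#' @param model The matching `cn_component_model`.
#' @param genome Genome model.
#' @param ploidy Background total copy number.
#' @param n_events Number of events planted (allocated to signatures
#'   multinomially in proportion to exposures; a fixed total keeps exposures
#'   identifiable as event-count shares).
#' @param purity Purity recorded on the profile.
#' @param sample Sample id.
#' @param events Optional pre-sampled event table (from [sample_cn_events()]);
#'   overrides `n_events`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used (as
#'   inside [generate_cohort()]).
#' @return A [cn_profile()].
#' @export
generate_cn_profile <- function(exposures,
                                signatures = synthetic_cn_signatures(),
                                model = default_component_model(),
                                genome = tgct_genome(), ploidy = 2,
                                n_events = 60, purity = 1,
                                sample = "sample", events = NULL,
                                seed = NULL) {
  gen <- function() {
    if (is.null(events)) {
      events <- sample_cn_events(round(n_events), exposures, signatures,
                                 model, genome, background = ploidy)
    }
    build_profile_from_events(events, genome, ploidy, purity, sample)
  }
  if (!is.null(seed)) with_seed(seed, gen()) else gen()
}

# Overlay events on a ploidy background; returns a cn_profile. Events later
# in the table overwrite earlier ones where they overlap. Each chromosome is
# cut at the union of event boundaries and every atomic interval takes the
# copy number of the last event covering it.
build_profile_from_events <- function(events, genome, ploidy, purity, sample) {
  minor_bg <- floor(ploidy / 2)
  out <- do.call(rbind, lapply(seq_len(nrow(genome)), function(gi) {
    ch <- genome$chrom[gi]
    len <- genome$length[gi]
    ev <- if (!is.null(events) && nrow(events)) {
      events[events$chrom == ch & events$start <= len, , drop = FALSE]
    } else NULL
    if (is.null(ev) || !nrow(ev)) {
      return(data.frame(chrom = ch, start = 1, end = len, total = ploidy,
                        stringsAsFactors = FALSE))
    }
    ev$end <- pmin(ev$end, len)
    bounds <- sort(unique(c(1, len + 1, ev$start, ev$end + 1)))
    bounds <- bounds[bounds >= 1 & bounds <= len + 1]
    a_start <- bounds[-length(bounds)]
    a_end <- bounds[-1] - 1
    total <- rep(ploidy, length(a_start))
    for (j in seq_len(nrow(ev))) {  # last covering event wins
      hit <- a_start >= ev$start[j] & a_end <= ev$end[j]
      total[hit] <- ev$total[j]
    }
    keep <- c(TRUE, abs(diff(total)) > 1e-9)
    grp <- cumsum(keep)
    data.frame(chrom = ch,
               start = as.numeric(tapply(a_start, grp, min)),
               end = as.numeric(tapply(a_end, grp, max)),
               total = total[keep], stringsAsFactors = FALSE)
  }))
  # allele split from the rounded total: homozygous loss (minor 0) only when
  # the rounded copy number falls to <= 1
  out$minor <- pmin(floor(round(out$total) / 2), minor_bg, out$total / 2)
  out$major <- out$total - out$minor
  cn_profile(sample, out[, c("chrom", "start", "end", "major", "minor",
                             "total")],
             purity = purity, ploidy = ploidy)
}


# Default COSMIC-mixture per histology/response group: HR-deficiency-like
# signature 3 dominates; signature 1 (deamination clock) is absent in
# platinum-sensitive seminomas and reduced signature 3 marks resistance.
cosmic_mix_for <- function(seminoma, resistant, n_signatures = 30) {
  mix <- numeric(n_signatures)
  if (seminoma && !resistant) {
    mix[c(3, 19, 5, 8)] <- c(0.60, 0.15, 0.15, 0.10)
  } else if (seminoma && resistant) {
    mix[c(1, 3, 19, 5, 8)] <- c(0.20, 0.30, 0.15, 0.20, 0.15)
  } else if (!seminoma && !resistant) {
    mix[c(1, 3, 19, 5, 8)] <- c(0.15, 0.45, 0.10, 0.20, 0.10)
  } else {
    mix[c(1, 3, 19, 5, 8)] <- c(0.30, 0.15, 0.15, 0.25, 0.15)
  }
  mix
}

# Context string for a pyrimidine-convention channel label "A[C>A]A".
channel_to_variant <- function(channel) {
  five <- substr(channel, 1, 1)
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  three <- substr(channel, 7, 7)
  list(ref = ref, alt = alt, context = paste0(five, ref, three))
}

#' Generate a synthetic multi-sample tumour cohort
#'
#' Produces a seed-reproducible cohort carrying every statistical structure
#' the downstream analyses assume, with ground truth: clinical covariates with
#' planted gene-mutation log-odds and a planted TMB shift; per-case
#' copy-number signature exposures realised as segmented profiles; 96-channel
#' mutation spectra drawn from group-specific reference-signature mixtures;
#' multiplicity-model VAFs (`VAF = m p / (p CNt + 2(1 - p))`) with binomial
#' read sampling at Poisson depth; multi-caller detection; truncal/private
#' variant sharing across serial tumours with per-site force-call read counts;
#' and extra metastatic CN events accruing linearly with months since
#' diagnosis.
#'
#' @param config A [cohort_config()].
#' @return List with `samples` (per-tumour metadata), `variants` (MAF-like
#'   calls including injected caller false positives), `profiles` (named list
#'   of [cn_profile()]), `force_calls` (per variant x sample read counts for
#'   multi-sample cases) and `truth` (exposures, per-variant sharing class and
#'   multiplicity, planted effects, group spectra mixtures).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  genome <- tgct_genome()
  n_sig <- nrow(cfg$cn_signatures)
  callers <- names(cfg$caller_sensitivity)
  samples <- list(); variants <- list(); profiles <- list()
  force_calls <- list(); truth_expo <- list()

  for (ci in seq_len(cfg$n_cases)) {
    case <- sprintf("case%03d", ci)
    resistant <- stats::runif(1) < cfg$p_resistant
    seminoma <- stats::runif(1) < cfg$p_seminoma
    extragonadal <- stats::runif(1) < cfg$p_extragonadal
    dataset <- sample(names(cfg$datasets), 1, prob = cfg$datasets)
    material <- if (dataset %in% c("ICR2", "DFCI")) "FFPE" else "fresh"
    n_samp <- as.integer(sample(names(cfg$samples_per_case), 1,
                                prob = cfg$samples_per_case))
    stages <- c("primary", rep("metastasis", n_samp - 1))
    ploidy <- min(4.8, max(1.5, stats::rnorm(1, cfg$ploidy_mean, cfg$ploidy_sd)))
    exposures <- rdirichlet1(cfg$exposure_alpha)
    months <- sort(stats::runif(n_samp, 6, 48))

    # --- copy-number events: case-truncal, metastasis-shared, private
    n_events <- round(cfg$mean_cn_events)
    n_trunc <- round(n_events * cfg$truncal_fraction)
    ev_trunc <- sample_cn_events(n_trunc, exposures, cfg$cn_signatures,
                                 cfg$component_model, genome, ploidy)
    ev_met <- NULL
    if (n_samp >= 3) {  # shared metastatic-precursor events
      ev_met <- sample_cn_events(
        round(cfg$mean_cn_events * cfg$met_shared_fraction), exposures,
        cfg$cn_signatures, cfg$component_model, genome, ploidy)
    }

    # --- small variants at case level
    tmb <- cfg$tmb_base + cfg$tmb_resistant_shift * resistant
    n_nonsyn <- stats::rpois(1, tmb * cfg$capture_mb)
    n_syn <- stats::rpois(1, cfg$syn_rate * cfg$capture_mb)
    mix <- cosmic_mix_for(seminoma, resistant, nrow(cfg$snv_signatures))
    # planted driver mutations (case-level, truncal, clonal)
    drv <- cfg$planted_gene_effects
    cov_val <- c(resistant = resistant, seminoma = seminoma,
                 extragonadal = extragonadal)
    drv_mut <- stats::runif(nrow(drv)) <
      stats::plogis(drv$intercept + drv$log_or * cov_val[drv$covariate])
    n_var <- n_nonsyn + n_syn + sum(drv_mut)
    var_tbl <- NULL
    if (n_var > 0) {
      chan_idx <- sample.int(96, n_var, replace = TRUE,
                             prob = as.numeric(mix %*% cfg$snv_signatures))
      cv <- channel_to_variant(sig_channels()[chan_idx])
      chrom <- sample(genome$chrom, n_var, replace = TRUE,
                      prob = genome$length)
      pos <- floor(stats::runif(n_var, 1,
                                genome$length[match(chrom, genome$chrom)]))
      gene <- sprintf("GENE%04d", sample.int(5000, n_var, replace = TRUE))
      consequence <- c(rep("nonsynonymous", n_nonsyn),
                       rep("synonymous", n_syn),
                       rep("nonsynonymous", sum(drv_mut)))
      if (sum(drv_mut)) {
        gene[(n_nonsyn + n_syn + 1):n_var] <- drv$gene[drv_mut]
      }
      is_driver <- gene %in% drv$gene
      clonal <- stats::runif(n_var) < cfg$clonal_fraction | is_driver
      mult <- ifelse(clonal, 1, stats::runif(n_var, 0.15, 0.8))
      truncal <- stats::runif(n_var) < cfg$truncal_fraction | is_driver
      owner <- sample.int(n_samp, n_var, replace = TRUE)  # for private vars
      var_tbl <- data.frame(
        variant_id = sprintf("%s_v%04d", case, seq_len(n_var)),
        chrom = chrom, pos = pos, ref = cv$ref, alt = cv$alt,
        context = cv$context, class = "SNV", consequence = consequence,
        gene = gene, case = case, true_multiplicity = mult,
        true_truncal = truncal, owner = owner,
        oncokb_driver = is_driver & stats::runif(n_var) < 0.8,
        cosmic_count = stats::rpois(n_var, ifelse(is_driver, 120, 0.3)),
        hotspot = is_driver & stats::runif(n_var) < 0.5,
        stringsAsFactors = FALSE)
    }

    for (si in seq_len(n_samp)) {
      samp <- sprintf("%s_T%d", case, si)
      purity <- stats::rbeta(1, cfg$purity_shape[1], cfg$purity_shape[2])
      extra <- NULL
      if (stages[si] == "metastasis") {
        n_extra <- stats::rpois(1, cfg$met_event_rate * months[si])
        extra <- sample_cn_events(n_extra, exposures, cfg$cn_signatures,
                                  cfg$component_model, genome, ploidy)
      }
      n_priv <- n_events - n_trunc
      ev_priv <- sample_cn_events(n_priv, exposures, cfg$cn_signatures,
                                  cfg$component_model, genome, ploidy)
      ev <- rbind(ev_trunc,
                  if (stages[si] == "metastasis") ev_met else NULL,
                  extra, ev_priv)
      prof <- build_profile_from_events(ev, genome, ploidy, purity, samp)
      profiles[[samp]] <- prof
      samples[[samp]] <- data.frame(
        sample = samp, case = case, dataset = dataset,
        histology = if (seminoma) "seminoma" else "nonseminoma",
        stage = stages[si],
        site = if (extragonadal) "extragonadal" else "testis",
        response = if (resistant) "resistant" else "sensitive",
        purity = purity, ploidy = ploidy, material = material,
        capture = "exome", months_since_diagnosis = months[si],
        stringsAsFactors = FALSE)

      if (!is.null(var_tbl)) {
        present <- var_tbl$true_truncal | var_tbl$owner == si
        depth <- stats::rpois(n_var, cfg$depth_mean)
        cnt <- lookup_total_cn(prof, var_tbl$chrom, var_tbl$pos)
        cnt[is.na(cnt)] <- round(ploidy)
        vaf_true <- pmin(1, var_tbl$true_multiplicity * purity /
                           (purity * cnt + 2 * (1 - purity)))
        p_read <- ifelse(present, vaf_true, 0.001)
        alt <- stats::rbinom(n_var, depth, p_read)
        force_calls[[samp]] <- data.frame(
          variant_id = var_tbl$variant_id, case = case, sample = samp,
          stage = stages[si], alt = alt, depth = depth,
          stringsAsFactors = FALSE)
        det <- simulate_caller_calls(sum(present),
                                     cfg$caller_sensitivity, cfg$caller_fpr)
        v <- var_tbl[present, , drop = FALSE]
        idx <- which(present)
        v$sample <- samp
        v$dataset <- dataset
        v$alt_reads <- alt[idx]
        v$depth <- depth[idx]
        v$vaf <- ifelse(depth[idx] > 0, alt[idx] / depth[idx], 0)
        v$alt_fwd <- stats::rbinom(length(idx), v$alt_reads, 0.5)
        v$alt_rev <- v$alt_reads - v$alt_fwd
        v$base_qual <- round(stats::rnorm(length(idx), 33, 2.5), 1)
        v$map_qual <- round(pmin(60, stats::rnorm(length(idx), 58, 3)), 1)
        v$callers <- det$callers
        # injected caller false positives
        fp_rows <- NULL
        n_fp <- det$n_false_positives
        if (sum(n_fp) > 0) {
          fp_n <- sum(n_fp)
          fp_chrom <- sample(genome$chrom, fp_n, replace = TRUE,
                             prob = genome$length)
          bases <- c("A", "C", "G", "T")
          fp_ref <- sample(bases, fp_n, replace = TRUE)
          fp_alt <- vapply(fp_ref, function(r) sample(setdiff(bases, r), 1),
                           character(1))
          fp_depth <- stats::rpois(fp_n, cfg$depth_mean)
          fp_alt_reads <- pmax(1, stats::rbinom(fp_n, fp_depth, 0.03))
          fp_fwd <- stats::rbinom(fp_n, fp_alt_reads, 0.5)
          fp_rows <- data.frame(
            variant_id = sprintf("%s_fp%03d", samp, seq_len(fp_n)),
            chrom = fp_chrom,
            pos = floor(stats::runif(fp_n, 1,
                                     genome$length[match(fp_chrom,
                                                         genome$chrom)])),
            ref = fp_ref, alt = fp_alt,
            context = paste0(sample(bases, fp_n, TRUE), fp_ref,
                             sample(bases, fp_n, TRUE)),
            class = "SNV", consequence = "nonsynonymous",
            gene = sprintf("GENE%04d", sample.int(5000, fp_n, TRUE)),
            case = case, true_multiplicity = NA_real_, true_truncal = NA,
            owner = NA_integer_, oncokb_driver = FALSE,
            cosmic_count = stats::rpois(fp_n, 0.1), hotspot = FALSE,
            sample = samp, dataset = dataset, alt_reads = fp_alt_reads,
            depth = fp_depth,
            vaf = ifelse(fp_depth > 0, fp_alt_reads / fp_depth, 0),
            alt_fwd = fp_fwd, alt_rev = fp_alt_reads - fp_fwd,
            base_qual = round(stats::rnorm(fp_n, 29, 3), 1),
            map_qual = round(pmin(60, stats::rnorm(fp_n, 55, 5)), 1),
            callers = rep(names(n_fp), n_fp),
            stringsAsFactors = FALSE)
        }
        variants[[samp]] <- rbind(v, fp_rows)
      }
    }
    truth_expo[[case]] <- exposures
  }

  samples <- do.call(rbind, samples)
  variants <- do.call(rbind, variants)
  force_calls <- do.call(rbind, force_calls)
  rownames(samples) <- rownames(variants) <- rownames(force_calls) <- NULL
  expo <- do.call(rbind, truth_expo)
  colnames(expo) <- rownames(cfg$cn_signatures)
  truth <- list(
    exposures = expo,
    variant_truth = if (!is.null(variants)) unique(
      variants[, c("variant_id", "case", "gene", "true_multiplicity",
                   "true_truncal")]) else NULL,
    gene_effects = cfg$planted_gene_effects,
    tmb = c(base = cfg$tmb_base, resistant_shift = cfg$tmb_resistant_shift)
  )
  list(samples = samples, variants = variants, profiles = profiles,
       force_calls = force_calls, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Writes the cohort as plain-text tables: `samples.tsv`, `variants.tsv`
#' (MAF-like), `variants.vcf` (minimal VCF 4.2), `profiles.seg.tsv`
#' (SEG-like), `force_calls.tsv` and `truth_exposures.tsv`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(cohort$samples, "samples.tsv")
  w(cohort$variants, "variants.tsv")
  w(cohort$force_calls, "force_calls.tsv")
  w(data.frame(case = rownames(cohort$truth$exposures),
               cohort$truth$exposures), "truth_exposures.tsv")
  write_seg(cohort$profiles, file.path(dir, "profiles.seg.tsv"))
  write_variants_vcf(cohort$variants, file.path(dir, "variants.vcf"))
  invisible(dir)
}

#' Write variants as a minimal VCF 4.2
#'
#' @param variants Variant `data.frame` (as from [generate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Tumour sample\">",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Detecting callers\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (!is.null(variants) && nrow(variants)) {
    o <- order(suppressWarnings(as.numeric(variants$chrom)), variants$pos)
    v <- variants[o, ]
    writeLines(sprintf(
      "%s\t%d\t%s\t%s\t%s\t.\t.\tSAMPLE=%s;CALLERS=%s",
      v$chrom, as.integer(v$pos), v$variant_id, v$ref, v$alt, v$sample,
      gsub(",", "|", v$callers)), con)
  }
  invisible(path)
}

#' Read a MAF-like variant TSV written by [write_cohort()]
#' @param path TSV path.
#' @return Variant `data.frame`.
#' @export
read_maf <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  v$chrom <- as.character(v$chrom)
  v
}

#' Sample copy-number feature values directly from a signature mixture
#'
#' The direct generative inverse of the posterior encoding: for each feature,
#' observation values are drawn i.i.d. from that feature's mixture components
#' weighted by the exposure-blended signature rows (`exposures %*% signatures`,
#' renormalised within the feature block). Observation counts follow the scale
#' of a segmented genome: `n_events` segment sizes, copy numbers and
#' change-points, one breakpoint count per 10 Mb window and per scored arm,
#' and one oscillating-chain length per chromosome. Unlike
#' [generate_cn_profile()] (which realises an actual segmentation, introducing
#' interactions between co-occurring events), the expected encoding of these
#' draws is exactly linear in the exposures, which is the regime in which
#' factorisation rank and exposure recovery are well defined.
#'
#' @param exposures Non-negative exposure vector summing to 1.
#' @param signatures Signature-by-component matrix.
#' @param model Matching `cn_component_model`.
#' @param n_events Number of copy-number events (sets the segment-level
#'   observation counts).
#' @param genome Genome model (sets window/arm/chromosome counts).
#' @return A `cn_features` object.
#' @export
sample_cn_features <- function(exposures, signatures = synthetic_cn_signatures(),
                               model = default_component_model(),
                               n_events = 60, genome = tgct_genome()) {
  if (length(exposures) != nrow(signatures)) {
    stop("exposure vector length must equal the number of signatures")
  }
  if (any(exposures < 0) || abs(sum(exposures) - 1) > 1e-6) {
    stop("exposures must be non-negative and sum to 1")
  }
  mix <- as.numeric(exposures %*% signatures)
  n_windows <- sum(ceiling(genome$length / 1e7))
  n_arms <- sum(genome_arms(genome)$scored)
  n_obs <- c(segsize = n_events, bp10MB = n_windows, changepoint = n_events,
             copynumber = n_events, bpchrarm = n_arms,
             osCN = nrow(genome))
  out <- lapply(cn_feature_names(), function(f) {
    i <- model$feature == f
    w <- mix[i] / sum(mix[i])
    n <- n_obs[[f]]
    comp <- sample.int(sum(i), n, replace = TRUE, prob = w)
    p1 <- model$p1[i][comp]
    if (model$family[i][1] == "norm") {
      pmax(stats::rnorm(n, p1, model$p2[i][comp]), 0)
    } else {
      stats::rpois(n, p1)
    }
  })
  names(out) <- cn_feature_names()
  structure(out, class = "cn_features")
}

#' Expected encoding of each signature under the direct feature sampler
#'
#' Monte Carlo estimate of the component-space profile of each signature: the
#' mean [encode_sample()] vector over pure-signature draws from
#' [sample_cn_features()]. This is the natural reference against which
#' factorised signature weights are matched.
#'
#' @inheritParams sample_cn_features
#' @param n_samples Monte Carlo replicates per signature.
#' @param seed Integer seed.
#' @return Matrix signatures x components.
#' @export
expected_encodings <- function(signatures = synthetic_cn_signatures(),
                               model = default_component_model(),
                               n_events = 60, genome = tgct_genome(),
                               n_samples = 50, seed = 1) {
  with_seed(seed, {
    out <- t(vapply(seq_len(nrow(signatures)), function(k) {
      e <- as.numeric(seq_len(nrow(signatures)) == k)
      rowMeans(vapply(seq_len(n_samples), function(i) {
        encode_sample(sample_cn_features(e, signatures, model, n_events,
                                         genome), model)$encoding
      }, numeric(nrow(model))))
    }, numeric(nrow(model))))
    rownames(out) <- rownames(signatures)
    colnames(out) <- model$component
    out
  })
}
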