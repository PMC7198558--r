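#' Extract the six copy-number feature distributions from a profile
#'
#' Computes, per sample, the genome-wide distributions of the six copy-number
#' features used for signature analysis:
#' \enumerate{
#'   \item `segsize` — per-segment length in Mb;
#'   \item `bp10MB` — breakpoint count in non-overlapping 10 Mb windows tiled
#'     from the start of each chromosome (all windows reported, zeros
#'     included);
#'   \item `changepoint` — absolute copy-number difference at each
#'     adjacent-segment junction (non-integer CN);
#'   \item `copynumber` — per-segment absolute total copy number;
#'   \item `bpchrarm` — breakpoint count per scored chromosome arm (all 39
#'     arms reported, zeros included);
#'   \item `osCN` — lengths (in segments) of maximal chains of contiguous
#'     segments alternating between exactly two integer-rounded copy-number
#'     states (chains of length >= 3).
#' }
#' A breakpoint is a junction between adjacent segments whose rounded total
#' copy numbers differ; junctions with equal rounded CN are not breakpoints.
#'
#' @param profile A [cn_profile()].
#' @param genome Genome model from [tgct_genome()].
#' @param window_size Window width for `bp10MB`, in bp (default 10 Mb).
#' @return A `cn_features` object: named list of six numeric vectors.
#' @export
extract_features <- function(profile, genome = tgct_genome(),
                             window_size = 1e7) {
  stopifnot(inherits(profile, "cn_profile"))
  segs <- profile$segments
  arms <- genome_arms(genome)
  arms <- arms[arms$scored, , drop = FALSE]

  segsize <- (segs$end - segs$start + 1) / 1e6
  copynumber <- segs$total

  changepoint <- numeric(0)
  bp_chrom <- character(0)
  bp_pos <- numeric(0)
  oscn <- numeric(0)
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1) {
      d <- abs(diff(s$total))
      changepoint <- c(changepoint, d)
      is_bp <- diff(round(s$total)) != 0
      bp_chrom <- c(bp_chrom, rep(ch, sum(is_bp)))
      bp_pos <- c(bp_pos, s$end[-nrow(s)][is_bp])
    }
    oscn <- c(oscn, oscillating_chains(round(s$total)))
  }

  # breakpoints per 10 Mb window, tiled from position 1 of each chromosome
  bp10 <- unlist(lapply(genome$chrom, function(ch) {
    n_win <- ceiling(genome$length[genome$chrom == ch] / window_size)
    counts <- integer(n_win)
    pos <- bp_pos[bp_chrom == ch]
    if (length(pos)) {
      idx <- pmin(n_win, floor((pos - 1) / window_size) + 1)
      tab <- table(idx)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
    counts
  }), use.names = FALSE)

  # breakpoints per scored arm
  bparm <- vapply(seq_len(nrow(arms)), function(i) {
    sum(bp_chrom == arms$chrom[i] &
          bp_pos >= arms$start[i] & bp_pos <= arms$end[i])
  }, numeric(1))

  structure(list(segsize = segsize, bp10MB = bp10, changepoint = changepoint,
                 copynumber = copynumber, bpchrarm = bparm, osCN = oscn),
            class = "cn_features")
}

# Lengths of maximal runs of >=3 contiguous segments alternating between
# exactly two integer CN states (s[k] != s[k+1], s[k+2] == s[k]).
oscillating_chains <- function(states) {
  n <- length(states)
  if (n < 3) return(numeric(0))
  lens <- numeric(0)
  i <- 1
  while (i <= n - 2) {
    if (states[i] != states[i + 1]) {
      j <- i + 1
      while (j + 1 <= n && states[j + 1] == states[j - 1]) j <- j + 1
      if (j - i + 1 >= 3) {
        lens <- c(lens, j - i + 1)
        i <- j  # chains may share at most the pivot segment; restart at end
        next
      }
    }
    i <- i + 1
  }
  lens
}

#' Fit per-feature mixture models (the 36-component model)
#'
#' Pools feature values across a reference cohort and fits, per feature, a
#' univariate mixture: Gaussian (via EM, unequal variances) for `segsize`,
#' `changepoint` and `copynumber`; Poisson (via EM) for `bp10MB`, `bpchrarm`
#' and `osCN`. Component counts are fixed via `n_components`, or selected by
#' lowest BIC over `1:max_components` where an entry is `NA`.
#'
#' @param feature_sets List of `cn_features` (one per sample).
#' @param n_components Named integer vector, one entry per feature (default
#'   the (10, 3, 7, 8, 5, 3) split). `NA` entries trigger BIC selection.
#' @param max_components Upper bound for BIC selection.
#' @return A `cn_component_model`.
#' @export
fit_component_model <- function(feature_sets,
                                n_components = c(segsize = 10, bp10MB = 3,
                                                 changepoint = 7,
                                                 copynumber = 8, bpchrarm = 5,
                                                 osCN = 3),
                                max_components = 10) {
  feats <- cn_feature_names()
  stopifnot(all(feats %in% names(n_components)))
  pooled <- lapply(feats, function(f) {
    unlist(lapply(feature_sets, `[[`, f), use.names = FALSE)
  })
  names(pooled) <- feats
  gaussian <- c("segsize", "changepoint", "copynumber")
  rows <- lapply(feats, function(f) {
    x <- pooled[[f]]
    k <- n_components[[f]]
    if (length(x) < max(k, 2, na.rm = TRUE)) {
      stop("fewer observations than components for feature ", f)
    }
    if (f %in% gaussian) {
      fit <- if (is.na(k)) {
        mclust::Mclust(x, G = 1:max_components, modelNames = "V",
                       verbose = FALSE)
      } else {
        mclust::Mclust(x, G = k, modelNames = if (k == 1) "X" else "V",
                       verbose = FALSE)
      }
      if (is.null(fit)) stop("Gaussian mixture fit failed for feature ", f)
      mean <- as.numeric(fit$parameters$mean)
      sd <- sqrt(rep(as.numeric(fit$parameters$variance$sigmasq),
                     length.out = fit$G))
      o <- order(mean)
      data.frame(feature = f, family = "norm", p1 = mean[o], p2 = sd[o],
                 weight = fit$parameters$pro[o], stringsAsFactors = FALSE)
    } else {
      fit <- if (is.na(k)) {
        fits <- lapply(1:max_components, function(g) poisson_mixture_em(x, g))
        fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
      } else {
        poisson_mixture_em(x, k)
      }
      o <- order(fit$lambda)
      data.frame(feature = f, family = "pois", p1 = fit$lambda[o],
                 p2 = NA_real_, weight = fit$weight[o],
                 stringsAsFactors = FALSE)
    }
  })
  m <- do.call(rbind, rows)
  m <- cbind(component = paste0(m$feature, sequence(rle(m$feature)$lengths)),
             m, stringsAsFactors = FALSE)
  rownames(m) <- NULL
  class(m) <- c("cn_component_model", "data.frame")
  validate_component_model(m)
  m
}

# EM for a univariate Poisson mixture with k components.
poisson_mixture_em <- function(x, k, max_iter = 500, tol = 1e-8) {
  stopifnot(all(x >= 0), k >= 1)
  n <- length(x)
  if (k == 1 || length(unique(x)) == 1) {
    lam <- max(mean(x), 1e-10)
    ll <- sum(stats::dpois(x, lam, log = TRUE))
    return(list(lambda = lam, weight = 1, loglik = ll,
                bic = -2 * ll + log(n)))
  }
  lam <- pmax(stats::quantile(x, probs = seq(0.1, 0.9, length.out = k),
                              names = FALSE) + seq_len(k) * 0.05, 1e-3)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      log(w[j]) + stats::dpois(x, lam[j], log = TRUE)
    }, numeric(n))
    mx <- apply(logd, 1, max)
    ll <- sum(mx + log(rowSums(exp(logd - mx))))
    post <- exp(logd - mx)
    post <- post / rowSums(post)
    nk <- colSums(post)
    w <- nk / n
    lam <- pmax(colSums(post * x) / pmax(nk, 1e-12), 1e-10)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(lambda = lam, weight = w, loglik = ll,
       bic = -2 * ll + (2 * k - 1) * log(n))
}

#' Encode a sample as a 36-component sum-of-posteriors vector
#'
#' For each observation of each feature, computes the posterior probability of
#' the observation under each of that feature's mixture components
#' (proportional to component weight times density/mass) and sums posteriors
#' per component across observations. The sum over a feature's components
#' therefore equals that feature's observation count.
#'
#' @param features A `cn_features` object from [extract_features()].
#' @param model A `cn_component_model`.
#' @return A `sample_encoding`: list with `encoding` (named numeric vector,
#'   one entry per component) and `counts` (observations per feature).
#' @export
encode_sample <- function(features, model = default_component_model()) {
  stopifnot(inherits(features, "cn_features"),
            inherits(model, "cn_component_model"))
  enc <- stats::setNames(numeric(nrow(model)), model$component)
  counts <- stats::setNames(integer(length(cn_feature_names())),
                            cn_feature_names())
  for (f in unique(model$feature)) {
    comps <- model[model$feature == f, , drop = FALSE]
    x <- features[[f]]
    counts[f] <- length(x)
    if (!length(x)) next
    dens <- vapply(seq_len(nrow(comps)), function(j) {
      if (comps$family[j] == "norm") {
        comps$weight[j] * stats::dnorm(x, comps$p1[j], comps$p2[j])
      } else {
        comps$weight[j] * stats::dpois(round(x), comps$p1[j])
      }
    }, numeric(length(x)))
    dens <- matrix(dens, nrow = length(x))
    tot <- rowSums(dens)
    zero <- tot <= 0 | !is.finite(tot)
    if (any(zero)) {
      warning(sum(zero), " observation(s) of feature ", f,
              " had zero density under all components; uniform posterior used")
      dens[zero, ] <- 1
      tot[zero] <- nrow(comps)
    }
    enc[comps$component] <- colSums(dens / tot)
  }
  structure(list(encoding = enc, counts = counts), class = "sample_encoding")
}

#' Build the patient-by-component matrix for a cohort
#'
#' Extracts features and encodes every profile, excluding samples whose purity
#' is below `min_purity` (signature quantification in low-cellularity samples
#' is unreliable).
#'
#' @param profiles Named list of [cn_profile()] objects.
#' @param model A `cn_component_model`.
#' @param genome Genome model.
#' @param min_purity Purity floor (default 0.4).
#' @return Numeric matrix samples x components, with an attribute `excluded`
#'   naming samples dropped by the purity floor.
#' @export
encode_cohort <- function(profiles, model = default_component_model(),
                          genome = tgct_genome(), min_purity = 0.4) {
  purity <- vapply(profiles, `[[`, numeric(1), "purity")
  keep <- purity >= min_purity
  enc <- t(vapply(profiles[keep], function(p) {
    encode_sample(extract_features(p, genome), model)$encoding
  }, numeric(nrow(model))))
  rownames(enc) <- vapply(profiles[keep], `[[`, character(1), "sample")
  attr(enc, "excluded") <- vapply(profiles[!keep], `[[`, character(1), "sample")
  enc
}
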