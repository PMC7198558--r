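#' The 96 trinucleotide substitution channels
#'
#' Channel order is fixed and documented: the six pyrimidine-reference
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G in that order, each
#' expanded over the 16 flanking contexts with the 5' base cycling slowest
#' (A, C, G, T) and the 3' base fastest. Labels follow the
#' `"A[C>A]A"` convention.
#'
#' @return Character vector of length 96.
#' @export
sig_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f, t) {
      paste0(f, "[", s, "]", t)
    })))
  }))
}

#' Synthetic 30-signature SNV reference matrix
#'
#' A deterministic, synthetic stand-in for a 30-signature 96-channel SNV
#' reference catalogue (the real COSMIC v2 matrix is distributed by COSMIC and
#' is not bundled; load one with [read_signature_matrix()] to use it instead).
#' Each synthetic signature is a sparse probability distribution over the 96
#' channels, concentrated on a signature-specific subset of channels so that
#' distinct signatures are well separated (low pairwise cosine similarity).
#' Rows sum to 1. The matrix is identical on every call.
#'
#' @param n_signatures Number of signatures to generate (default 30).
#' @return Numeric matrix `n_signatures x 96`, rownames `"Signature.1"` ...,
#'   colnames from [sig_channels()].
#' @export
synthetic_snv_signatures <- function(n_signatures = 30) {
  with_seed(830441L, {
    ch <- sig_channels()
    m <- matrix(0, n_signatures, 96, dimnames = list(
      paste0("Signature.", seq_len(n_signatures)), ch
    ))
    for (k in seq_len(n_signatures)) {
      # sparse gamma profile: a handful of dominant channels per signature
      w <- stats::rgamma(96, shape = 0.08, rate = 1)
      top <- sample.int(96, 6)
      w[top] <- w[top] + stats::rgamma(6, shape = 3, rate = 1)
      m[k, ] <- w / sum(w)
    }
    m
  })
}

#' Read a signature reference matrix from TSV
#'
#' Reads a channels-by-signatures or signatures-by-channels TSV (for example a
#' COSMIC download) and returns it oriented signatures-by-channels in the
#' package channel order.
#'
#' @param path TSV path; first column or the rownames must contain channel
#'   labels such as `"A[C>A]A"`.
#' @return Numeric matrix signatures x 96.
#' @export
read_signature_matrix <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ch <- sig_channels()
  if (all(ch %in% x[[1]])) {
    rn <- x[[1]]
    x <- as.matrix(x[, -1, drop = FALSE])
    rownames(x) <- rn
    x <- t(x[ch, , drop = FALSE])
  } else if (all(ch %in% rownames(x))) {
    x <- t(as.matrix(x)[ch, , drop = FALSE])
  } else if (all(ch %in% colnames(x))) {
    x <- as.matrix(x)[, ch, drop = FALSE]
  } else {
    stop("could not locate the 96 trinucleotide channels in ", path)
  }
  storage.mode(x) <- "double"
  x / rowSums(x)
}

#' Copy-number feature names
#'
#' The six copy-number features, in fixed order: segment size (`segsize`, Mb),
#' breakpoint count per 10 Mb window (`bp10MB`), absolute copy-number change
#' between adjacent segments (`changepoint`), segment absolute copy number
#' (`copynumber`), breakpoint count per chromosome arm (`bpchrarm`) and length
#' of oscillating copy-number chains (`osCN`, in segments).
#'
#' @return Character vector of length 6.
#' @export
cn_feature_names <- function() {
  c("segsize", "bp10MB", "changepoint", "copynumber", "bpchrarm", "osCN")
}

#' Default 36-component mixture model for the six CN features
#'
#' A fixed, documented component model over the six copy-number features:
#' Gaussian components for segment size, change-point and copy number;
#' Poisson components for the three count features. The per-feature split is
#' (10, 3, 7, 8, 5, 3), summing to 36. This synthetic model plays the role of
#' a reference component catalogue fitted on an external high-quality cohort;
#' refit one from your own cohort with [fit_component_model()].
#'
#' @return A `cn_component_model`: `data.frame` with columns `component`
#'   (e.g. `"segsize3"`), `feature`, `family` (`"norm"`/`"pois"`), `p1`
#'   (mean or rate), `p2` (sd, `NA` for Poisson) and `weight` (per-feature
#'   weights sum to 1).
#' @export
default_component_model <- function() {
  comp <- function(feature, family, p1, p2, weight) {
    data.frame(
      component = paste0(feature, seq_along(p1)),
      feature = feature, family = family, p1 = p1,
      p2 = if (family == "norm") p2 else NA_real_,
      weight = weight / sum(weight), stringsAsFactors = FALSE
    )
  }
  m <- rbind(
    comp("segsize", "norm",
         p1 = c(0.4, 1, 2.5, 5, 10, 20, 35, 60, 95, 140),
         p2 = c(0.15, 0.3, 0.7, 1.2, 2.5, 4, 7, 10, 14, 20),
         weight = c(2, 3, 3, 3, 2.5, 2, 1.5, 1.2, 1, 0.8)),
    comp("bp10MB", "pois",
         p1 = c(0.08, 1.5, 4.5), p2 = NULL, weight = c(6, 2, 1)),
    comp("changepoint", "norm",
         p1 = c(0.25, 0.6, 1.0, 1.6, 2.3, 3.2, 4.5),
         p2 = c(0.08, 0.12, 0.15, 0.22, 0.3, 0.4, 0.6),
         weight = c(2, 2.5, 3, 2, 1.5, 1, 0.7)),
    comp("copynumber", "norm",
         p1 = c(1.0, 2.0, 2.6, 3.1, 3.6, 4.3, 5.5, 7.5),
         p2 = c(0.12, 0.15, 0.16, 0.17, 0.2, 0.25, 0.4, 0.8),
         weight = c(1.5, 3, 3, 3, 2, 1.5, 1, 0.6)),
    comp("bpchrarm", "pois",
         p1 = c(0.3, 2, 5, 10, 18), p2 = NULL, weight = c(5, 3, 2, 1, 0.5)),
    comp("osCN", "pois",
         p1 = c(0.3, 3, 7), p2 = NULL, weight = c(5, 2, 1))
  )
  rownames(m) <- NULL
  class(m) <- c("cn_component_model", "data.frame")
  m
}

#' Synthetic five-signature CN reference
#'
#' A synthetic signature-by-component weight matrix over the 36 components of
#' [default_component_model()], defining five copy-number signatures with the
#' qualitative structure reported for germ-cell and ovarian tumours:
#' \describe{
#'   \item{CN1}{large segments, very few breakpoints per arm (whole-arm /
#'     sub-arm exchanges).}
#'   \item{CN2}{evenly distributed breaks with single-copy (LOH-like)
#'     change-points.}
#'   \item{CN3}{moderate event density with intermediate copy states.}
#'   \item{CN4}{many breakpoints per arm, small segments, short oscillating
#'     runs (chromothripsis-like).}
#'   \item{CN5}{focal high-amplitude amplification: small segments with high
#'     copy number and large change-points.}
#' }
#' Within each feature block the weights sum to 1, so a row is a valid
#' per-feature sampling mixture for [generate_cn_profile()].
#'
#' @param model A `cn_component_model` (defaults to
#'   [default_component_model()]); used for component names/order.
#' @return Numeric matrix 5 x 36 with rownames `CN1..CN5`.
#' @export
synthetic_cn_signatures <- function(model = default_component_model()) {
  stopifnot(inherits(model, "cn_component_model"))
  blocks <- list(
    # per feature: one weight per component, normalised within the block;
    # the five signatures use nearly disjoint size/copy-number components so
    # that they are distinguishable in encoding space
    CN1 = list(segsize    = c(0, 0, 0, 0, 0, 0, 1, 4, 7, 6),
               bp10MB     = c(9, 0.5, 0),
               changepoint = c(0.5, 3, 5, 1, 0.3, 0, 0),
               copynumber = c(0, 1, 2, 3, 4, 5, 0.5, 0),
               bpchrarm   = c(9, 0.5, 0, 0, 0),
               osCN       = c(9.5, 0.2, 0)),
    CN2 = list(segsize    = c(0, 0, 0, 1, 6, 6, 1, 0, 0, 0),
               bp10MB     = c(6, 3, 0.3),
               changepoint = c(0.5, 2, 8, 1, 0, 0, 0),
               copynumber = c(6, 6, 1, 0.3, 0, 0, 0, 0),
               bpchrarm   = c(3, 6, 1, 0, 0),
               osCN       = c(9, 0.8, 0.1)),
    CN3 = list(segsize    = c(0, 0, 4, 7, 3, 0.5, 0, 0, 0, 0),
               bp10MB     = c(4, 5, 1),
               changepoint = c(5, 4, 1, 0.3, 0, 0, 0),
               copynumber = c(0, 1, 5, 5, 2, 0.3, 0, 0),
               bpchrarm   = c(1, 3, 5, 1, 0),
               osCN       = c(8, 1.5, 0.3)),
    CN4 = list(segsize    = c(7, 6, 2, 0.3, 0, 0, 0, 0, 0, 0),
               bp10MB     = c(0.5, 3, 7),
               changepoint = c(4, 5, 2, 0.5, 0, 0, 0),
               copynumber = c(1, 4, 4, 2, 0.5, 0, 0, 0),
               bpchrarm   = c(0, 0.5, 2, 5, 4),
               osCN       = c(1, 5, 4)),
    CN5 = list(segsize    = c(3, 6, 4, 1, 0, 0, 0, 0, 0, 0),
               bp10MB     = c(4, 4, 1.5),
               changepoint = c(0, 0, 0.3, 1, 2.5, 4, 4),
               copynumber = c(0, 0, 0, 0.3, 0.7, 2, 5, 5),
               bpchrarm   = c(1, 5, 3, 0.5, 0),
               osCN       = c(8, 1.5, 0.3))
  )
  feats <- cn_feature_names()
  w <- t(vapply(blocks, function(b) {
    unlist(lapply(feats, function(f) b[[f]] / sum(b[[f]])), use.names = FALSE)
  }, numeric(nrow(model))))
  colnames(w) <- model$component
  w
}

#' Write / read a component model as TSV
#' @param model A `cn_component_model`.
#' @param path File path.
#' @return `read_component_model()` returns a `cn_component_model`.
#' @export
write_component_model <- function(model, path) {
  utils::write.table(as.data.frame(model), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_component_model
#' @export
read_component_model <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("component", "feature", "family", "p1", "p2", "weight")
  if (!all(need %in% names(m))) {
    stop("component model TSV must have columns: ", paste(need, collapse = ", "))
  }
  class(m) <- c("cn_component_model", "data.frame")
  validate_component_model(m)
  m
}

validate_component_model <- function(model) {
  stopifnot(all(model$family %in% c("norm", "pois")))
  w <- tapply(model$weight, model$feature, sum)
  if (any(abs(w - 1) > 1e-6)) stop("per-feature component weights must sum to 1")
  invisible(model)
}

#' Component-space profiles of generative CN signatures
#'
#' The generative signature definitions ([synthetic_cn_signatures()]) are
#' per-feature sampling mixtures; what a factorisation of encoded profiles can
#' recover is each signature's expected *encoding* (which also carries the
#' encoding baseline: background segments, zero-count windows and arms). This
#' helper computes those component-space profiles by Monte Carlo: it generates
#' pure-signature profiles, encodes them and averages.
#'
#' @param signatures Signature-by-component matrix.
#' @param model Matching `cn_component_model`.
#' @param genome Genome model.
#' @param ploidy Background copy number (default 3, hyperploid).
#' @param n_events Events per profile.
#' @param n_samples Monte Carlo samples per signature.
#' @param seed Integer seed.
#' @return Matrix signatures x components (rownames from `signatures`).
#' @export
reference_encodings <- function(signatures = synthetic_cn_signatures(),
                                model = default_component_model(),
                                genome = tgct_genome(), ploidy = 3,
                                n_events = 100, n_samples = 30, seed = 1) {
  with_seed(seed, {
    out <- t(vapply(seq_len(nrow(signatures)), function(k) {
      e <- as.numeric(seq_len(nrow(signatures)) == k)
      rowMeans(vapply(seq_len(n_samples), function(i) {
        p <- generate_cn_profile(e, signatures, model, genome,
                                 ploidy = ploidy, n_events = n_events)
        encode_sample(extract_features(p, genome), model)$encoding
      }, numeric(nrow(model))))
    }, numeric(nrow(model))))
    rownames(out) <- rownames(signatures)
    colnames(out) <- model$component
    out
  })
}
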