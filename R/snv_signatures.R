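#' Build a 96-channel trinucleotide spectrum from SNV calls
#'
#' Bins single-nucleotide variants into the 96 substitution channels of
#' [sig_channels()]. Purine-reference substitutions are reverse-complemented
#' into the pyrimidine convention (e.g. an `A[G>T]C` mutation is counted in
#' the `G[C>A]T` channel). Variants whose context contains `N` (or any
#' non-ACGT base) are skipped and counted in the `skipped` attribute.
#'
#' @param variants `data.frame` with columns `ref`, `alt` (single bases) and
#'   `context` (the 3-mer centred on the variant, reference strand).
#' @param label Optional sample/group label attached to the result.
#' @return Named integer vector of length 96 (class `snv_spectrum`), with
#'   attributes `label` and `skipped`.
#' @export
build_spectrum <- function(variants, label = NULL) {
  ch <- sig_channels()
  counts <- stats::setNames(integer(96), ch)
  skipped <- 0L
  if (nrow(variants)) {
    ref <- toupper(variants$ref)
    alt <- toupper(variants$alt)
    ctx <- toupper(variants$context)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (i in seq_len(nrow(variants))) {
      b <- strsplit(ctx[i], "")[[1]]
      if (length(b) != 3 || !all(b %in% names(comp)) ||
          !(ref[i] %in% names(comp)) || !(alt[i] %in% names(comp)) ||
          b[2] != ref[i] || ref[i] == alt[i]) {
        skipped <- skipped + 1L
        next
      }
      r <- ref[i]; a <- alt[i]; five <- b[1]; three <- b[3]
      if (r %in% c("A", "G")) {  # complement to pyrimidine reference
        r2 <- comp[[r]]; a2 <- comp[[a]]
        f2 <- comp[[three]]; t2 <- comp[[five]]
        r <- r2; a <- a2; five <- f2; three <- t2
      }
      key <- paste0(five, "[", r, ">", a, "]", three)
      counts[key] <- counts[key] + 1L
    }
  }
  structure(counts, label = label, skipped = skipped, class = "snv_spectrum")
}

#' Fit reference SNV signatures to a spectrum
#'
#' Estimates non-negative signature exposures for a 96-channel spectrum by
#' iterative forward selection: signatures are added one at a time, each step
#' choosing the signature whose inclusion (with weights refit by non-negative
#' least squares on the normalised spectrum) most reduces the reconstruction
#' error, until no addition improves the error by more than `tol`. Weights
#' below `cutoff` are zeroed and the remainder refit; the unexplained residual
#' is reported so that weights plus residual sum to 1. Exposures are invariant
#' to positive scaling of the input spectrum.
#'
#' @param spectrum Numeric vector of 96 channel counts (total > 0).
#' @param signatures Reference matrix signatures x 96 (rows sum to 1), e.g.
#'   [synthetic_snv_signatures()] or a loaded COSMIC matrix.
#' @param cutoff Minimum signature weight (default 0.06); smaller fitted
#'   weights are zeroed.
#' @param metric `"sse"` (sum of squared differences on the normalised
#'   96-vector, default) or `"cosine"` (1 - cosine similarity).
#' @param tol Minimum error improvement to accept another signature.
#' @return A `signature_exposure`: list with `weights` (named, length =
#'   number of reference signatures), `residual`, `n_snv`, `error`.
#' @export
fit_cosmic <- function(spectrum, signatures = synthetic_snv_signatures(),
                       cutoff = 0.06, metric = c("sse", "cosine"),
                       tol = 1e-4) {
  metric <- match.arg(metric)
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != ncol(signatures)) stop("spectrum/signature size mismatch")
  total <- sum(spectrum)
  if (total <= 0) stop("zero spectrum: nothing to fit")
  s <- spectrum / total
  err_fun <- function(fit) {
    if (metric == "sse") sum((s - fit)^2) else 1 - cosine_sim(s, fit)
  }
  nsig <- nrow(signatures)
  selected <- integer(0)
  w_sel <- numeric(0)
  err <- err_fun(rep(0, length(s)))
  repeat {
    cand <- setdiff(seq_len(nsig), selected)
    if (!length(cand)) break
    trials <- lapply(cand, function(j) {
      idx <- c(selected, j)
      w <- pracma::lsqnonneg(t(signatures[idx, , drop = FALSE]), s)$x
      list(idx = idx, w = w, err = err_fun(as.numeric(
        t(signatures[idx, , drop = FALSE]) %*% w)))
    })
    best <- trials[[which.min(vapply(trials, `[[`, numeric(1), "err"))]]
    if (err - best$err < tol) break
    selected <- best$idx
    w_sel <- best$w
    err <- best$err
  }
  weights <- stats::setNames(numeric(nsig), rownames(signatures))
  weights[selected] <- w_sel
  # zero sub-cutoff weights and refit on the survivors
  keep <- which(weights >= cutoff)
  if (length(keep) && length(keep) < length(selected)) {
    w <- pracma::lsqnonneg(t(signatures[keep, , drop = FALSE]), s)$x
    weights[] <- 0
    weights[keep] <- w
  } else if (!length(keep)) {
    weights[] <- 0
  }
  weights[weights < cutoff] <- 0
  if (sum(weights) > 1) weights <- weights / sum(weights)
  fit <- as.numeric(t(signatures) %*% weights)
  structure(list(weights = weights, residual = 1 - sum(weights),
                 n_snv = total, error = err_fun(fit)),
            class = "signature_exposure")
}

#' Pool spectra by group and fit signatures
#'
#' Sums sample spectra element-wise within each group and fits the reference
#' signatures to each pooled spectrum. Sample-level fits are additionally
#' returned for samples whose total SNV count meets `min_snv` (default 50;
#' sparser spectra are not fit individually).
#'
#' @param spectra Matrix samples x 96 (rows are per-sample spectra) with
#'   rownames.
#' @param groups Factor/character vector of group labels, one per sample.
#' @param signatures Reference signature matrix.
#' @param min_snv Minimum per-sample SNV count for sample-level fitting.
#' @param ... Passed to [fit_cosmic()].
#' @return List with `group` (named list of `signature_exposure`; empty groups
#'   are skipped with a warning) and `sample` (named list for qualifying
#'   samples).
#' @export
pool_and_fit <- function(spectra, groups, signatures = synthetic_snv_signatures(),
                         min_snv = 50, ...) {
  spectra <- as.matrix(spectra)
  stopifnot(length(groups) == nrow(spectra))
  group_fits <- list()
  for (g in unique(as.character(groups))) {
    pooled <- colSums(spectra[as.character(groups) == g, , drop = FALSE])
    if (sum(pooled) == 0) {
      warning("group ", g, " has no SNVs; skipped")
      next
    }
    group_fits[[g]] <- fit_cosmic(pooled, signatures, ...)
  }
  totals <- rowSums(spectra)
  sample_fits <- lapply(which(totals >= min_snv), function(i) {
    fit_cosmic(spectra[i, ], signatures, ...)
  })
  names(sample_fits) <- rownames(spectra)[totals >= min_snv]
  list(group = group_fits, sample = sample_fits)
}
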