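#' Non-negative matrix factorisation of the patient-by-component matrix
#'
#' Deconvolutes a non-negative patients-by-components matrix `V` into a
#' patient-by-signature exposure matrix `E` and a signature-by-component
#' weight matrix `W` (`V ~ E W`) with multiplicative updates under the
#' Kullback-Leibler (default) or Frobenius objective. The best of `n_restarts`
#' random initialisations (by reconstruction error) is returned. Runs are
#' deterministic given `seed`. After fitting, `W` rows are scaled to sum to 1
#' (the scale is pushed into `E`) and row-normalised exposures are reported
#' alongside the raw ones.
#'
#' @param x Non-negative numeric matrix, samples x components.
#' @param rank Number of signatures (>= 1).
#' @param n_restarts Random restarts (default 10).
#' @param seed Integer seed (mandatory; no hidden global state).
#' @param method `"kl"` or `"frobenius"`.
#' @param max_iter,tol Update iteration cap and relative-change tolerance.
#' @return A `cn_signature_model`: list with `exposures` (raw, samples x rank),
#'   `norm_exposures` (rows sum to 1), `weights` (rank x components, rows sum
#'   to 1), `rank`, `rss`, `kl`, `method`, `connectivity` (samples x samples
#'   0/1 co-clustering of the best run) and `n_iter`.
#' @export
nmf_decompose <- function(x, rank, n_restarts = 10, seed, method = c("kl", "frobenius"),
                          max_iter = 2000, tol = 1e-9) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (any(x < 0)) stop("input matrix must be non-negative")
  if (rank < 1 || rank > min(dim(x))) stop("rank out of range")
  if (missing(seed)) stop("seed is required")
  fits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      nmf_run(x, rank, method, max_iter, tol)
    })
  })
  err <- vapply(fits, `[[`, numeric(1), "objective")
  best <- fits[[which.min(err)]]
  E <- best$E
  W <- best$W
  scale <- rowSums(W)
  scale[scale == 0] <- 1
  W <- W / scale
  E <- sweep(E, 2, scale, `*`)
  rs <- rowSums(E)
  rs[rs == 0] <- 1
  colnames(E) <- rownames(W) <- paste0("S", seq_len(rank))
  rownames(E) <- rownames(x)
  colnames(W) <- colnames(x)
  cl <- apply(E, 1, which.max)
  structure(list(
    exposures = E, norm_exposures = E / rs, weights = W, rank = rank,
    rss = sum((x - E %*% W)^2), kl = kl_div(x, E %*% W), method = method,
    connectivity = outer(cl, cl, `==`) * 1, n_iter = best$n_iter
  ), class = "cn_signature_model")
}

kl_div <- function(v, wh) {
  keep <- v > 0
  sum(v[keep] * log(v[keep] / pmax(wh[keep], 1e-300))) - sum(v) + sum(wh)
}

# One multiplicative-update run from a random start.
nmf_run <- function(x, rank, method, max_iter, tol) {
  n <- nrow(x); m <- ncol(x)
  mu <- mean(x)
  E <- matrix(stats::runif(n * rank, 1e-4, 1), n, rank) * sqrt(mu)
  W <- matrix(stats::runif(rank * m, 1e-4, 1), rank, m) * sqrt(mu)
  eps <- 1e-12
  obj_old <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (method == "kl") {
      WH <- E %*% W + eps
      E <- E * ((x / WH) %*% t(W)) / matrix(rowSums(W), n, rank, byrow = TRUE)
      WH <- E %*% W + eps
      W <- W * (t(E) %*% (x / WH)) / matrix(colSums(E), rank, m)
      if (it %% 10 == 0 || it == max_iter) {
        obj <- kl_div(x, E %*% W)
        if (is.finite(obj_old) && obj_old - obj < tol * (1 + abs(obj_old))) break
        obj_old <- obj
      }
    } else {
      E <- E * (x %*% t(W)) / (E %*% W %*% t(W) + eps)
      W <- W * (t(E) %*% x) / (t(E) %*% E %*% W + eps)
      if (it %% 10 == 0 || it == max_iter) {
        obj <- sum((x - E %*% W)^2)
        if (is.finite(obj_old) && obj_old - obj < tol * (1 + abs(obj_old))) break
        obj_old <- obj
      }
    }
  }
  objective <- if (method == "kl") kl_div(x, E %*% W) else sum((x - E %*% W)^2)
  list(E = E, W = W, objective = objective, n_iter = it)
}

#' Survey candidate NMF ranks against a permuted null
#'
#' For each candidate rank, runs `n_restarts` factorisations of the observed
#' matrix and of `n_perm` column-permuted matrices (each column permuted
#' independently, destroying inter-component structure while preserving
#' marginals), and records four model-selection measures: cophenetic
#' correlation and dispersion of the restart consensus matrix, mean silhouette
#' width of the consensus clustering, and residual sum of squares of the best
#' fit. The chosen rank is the largest rank whose observed cophenetic
#' correlation and dispersion both exceed the corresponding permuted-null 95th
#' percentile and whose relative RSS improvement over the previous rank
#' (improvement divided by the previous rank's RSS, which makes the
#' observed/null comparison scale-free) exceeds the null's relative
#' improvement -- both its 95th percentile and its mean plus three standard
#' deviations, computed pairwise within each permuted replicate; the dual
#' threshold compensates for the sampling noise of a quantile estimated from
#' a modest number of permutations -- and whose successor rank's relative
#' improvement does *not* exceed its null
#' -- i.e. the rank at which the detectable structure is exhausted. The
#' successor condition means the largest candidate rank can never be chosen,
#' so the rank range should extend one beyond the largest plausible rank.
#' Best-fit RSS values come from a chained warm-start sweep over ranks (see
#' Details in the source), which makes the RSS sequence monotone and keeps
#' random-restart noise from inflating apparent improvements at high ranks.
#' If no rank qualifies the survey flags `no_structure`.
#'
#' @param x Non-negative matrix, samples x components.
#' @param ranks Candidate ranks (default `2:8`).
#' @param n_restarts Restarts per factorisation (default 8).
#' @param n_perm Permuted replicates for the consensus measures (default 6).
#' @param n_perm_rss Permuted replicates for the RSS-sweep null (default 16;
#'   sweeps are cheap relative to consensus runs).
#' @param seed Integer seed.
#' @param method NMF objective, see [nmf_decompose()].
#' @return A `rank_survey`: list with `measures` (per-rank data.frame:
#'   observed and null-95th-percentile values), `chosen`, `no_structure`.
#' @export
select_rank <- function(x, ranks = 2:8, n_restarts = 8, n_perm = 6,
                        n_perm_rss = 16, seed, method = "kl") {
  x <- as.matrix(x)
  if (missing(seed)) stop("seed is required")
  if (stats::sd(as.vector(x)) == 0) stop("degenerate matrix: zero variance")
  if (min(ranks) < 2 || max(ranks) > min(dim(x)) - 1) {
    stop("rank range must lie within [2, min(dim) - 1]")
  }
  ranks <- sort(ranks)
  all_ranks <- c(min(ranks) - 1, ranks)  # extra low rank for RSS improvement
  res <- with_seed(seed, {
    perms <- lapply(seq_len(max(n_perm, n_perm_rss)), function(i) {
      apply(x, 2, sample)
    })
    obs <- lapply(ranks, function(r) {
      consensus_measures(x, r, n_restarts, method)
    })
    null <- lapply(ranks, function(r) {
      lapply(perms[seq_len(n_perm)], function(p) {
        consensus_measures(p, r, n_restarts, method)
      })
    })
    obs_rss <- rss_sweep(x, all_ranks, method)
    null_rss <- vapply(perms[seq_len(n_perm_rss)], function(p) {
      rss_sweep(p, all_ranks, method)
    }, numeric(length(all_ranks)))
    list(obs = obs, null = null, obs_rss = obs_rss, null_rss = null_rss)
  })
  get <- function(l, field) vapply(l, `[[`, numeric(1), field)
  obs_coph <- get(res$obs, "cophenetic")
  obs_disp <- get(res$obs, "dispersion")
  obs_sil <- get(res$obs, "silhouette")
  q95 <- function(field) {
    vapply(res$null, function(reps) {
      stats::quantile(get(reps, field), 0.95, names = FALSE)
    }, numeric(1))
  }
  null_coph <- q95("cophenetic")
  null_disp <- q95("dispersion")
  idx <- match(ranks, all_ranks)
  obs_rss <- res$obs_rss
  null_rss05 <- apply(res$null_rss, 1, stats::quantile, 0.05, names = FALSE)
  obs_impr <- (obs_rss[idx - 1] - obs_rss[idx]) / obs_rss[idx - 1]
  null_impr_all <- lapply(idx, function(i) {
    (res$null_rss[i - 1, ] - res$null_rss[i, ]) / res$null_rss[i - 1, ]
  })
  null_impr <- vapply(null_impr_all, stats::quantile, numeric(1),
                      probs = 0.95, names = FALSE)
  null_impr_hi <- vapply(null_impr_all, function(v) {
    mean(v) + 3 * stats::sd(v)
  }, numeric(1))
  measures <- data.frame(
    rank = ranks,
    cophenetic = obs_coph, cophenetic_null95 = null_coph,
    dispersion = obs_disp, dispersion_null95 = null_disp,
    silhouette = obs_sil,
    rss = obs_rss[idx], rss_null05 = null_rss05[idx],
    rel_improvement = obs_impr, rel_improvement_null95 = null_impr,
    rel_improvement_null3sd = null_impr_hi
  )
  impr_pass <- measures$rel_improvement > measures$rel_improvement_null95 &
    measures$rel_improvement > measures$rel_improvement_null3sd
  pass <- measures$cophenetic > measures$cophenetic_null95 &
    measures$dispersion > measures$dispersion_null95 &
    impr_pass
  # structure exhausted: the next rank's improvement gate must fail
  exhausted <- c(!impr_pass[-1], FALSE)
  qualified <- pass & exhausted
  chosen <- if (any(qualified)) max(ranks[qualified]) else NA_integer_
  structure(list(measures = measures, chosen = chosen,
                 no_structure = !any(pass)),
            class = "rank_survey")
}

# Consensus-based quality measures for one rank: cophenetic correlation,
# dispersion and silhouette of the restart consensus matrix.
consensus_measures <- function(x, rank, n_restarts, method) {
  n <- nrow(x)
  runs <- lapply(seq_len(n_restarts), function(i) {
    nmf_run(x, rank, method, max_iter = 300, tol = 1e-7)
  })
  cons <- matrix(0, n, n)
  for (r in runs) {
    cl <- max.col(r$E, ties.method = "first")
    cons <- cons + outer(cl, cl, `==`)
  }
  cons <- cons / n_restarts
  d <- stats::as.dist(1 - cons)
  hc <- stats::hclust(d, method = "average")
  coph <- suppressWarnings(stats::cor(stats::cophenetic(hc), d))
  if (is.na(coph)) coph <- 1  # consensus perfectly crisp: zero variance
  disp <- mean((2 * (cons - 0.5))^2)
  cl <- stats::cutree(hc, k = min(rank, n - 1))
  sil <- silhouette_mean(as.matrix(d), cl)
  list(cophenetic = coph, dispersion = disp, silhouette = sil)
}

# Best residual sum of squares per rank from a chained sweep: each rank runs
# a few random starts plus a warm start grown from the previous rank's best
# factors, which makes the RSS sequence monotone and well converged (random
# restart noise otherwise inflates apparent improvements at high ranks).
rss_sweep <- function(x, ranks_asc, method, n_random = 2, max_iter = 1000,
                      tol = 1e-9) {
  best_prev <- NULL
  out <- numeric(length(ranks_asc))
  for (i in seq_along(ranks_asc)) {
    r <- ranks_asc[i]
    runs <- lapply(seq_len(n_random), function(j) {
      nmf_run(x, r, method, max_iter = max_iter, tol = tol)
    })
    if (!is.null(best_prev)) {
      warm <- list(E = cbind(best_prev$E,
                             matrix(stats::runif(nrow(x), 0, 1e-3), ncol = 1)),
                   W = rbind(best_prev$W,
                             matrix(stats::runif(ncol(x), 0, 1e-3), nrow = 1)))
      runs <- c(runs, list(nmf_refine(x, warm$E, warm$W, method,
                                      max_iter = max_iter, tol = tol)))
    }
    obj <- vapply(runs, `[[`, numeric(1), "objective")
    best_prev <- runs[[which.min(obj)]]
    out[i] <- sum((x - best_prev$E %*% best_prev$W)^2)
  }
  out
}

# Multiplicative updates from given starting factors.
nmf_refine <- function(x, E, W, method, max_iter, tol) {
  n <- nrow(x); m <- ncol(x); rank <- ncol(E)
  eps <- 1e-12
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    if (method == "kl") {
      WH <- E %*% W + eps
      E <- E * ((x / WH) %*% t(W)) / matrix(rowSums(W), n, rank, byrow = TRUE)
      WH <- E %*% W + eps
      W <- W * (t(E) %*% (x / WH)) / matrix(colSums(E), rank, m)
      if (it %% 10 == 0 || it == max_iter) {
        obj <- kl_div(x, E %*% W)
        if (is.finite(obj_old) && obj_old - obj < tol * (1 + abs(obj_old))) break
        obj_old <- obj
      }
    } else {
      E <- E * (x %*% t(W)) / (E %*% W %*% t(W) + eps)
      W <- W * (t(E) %*% x) / (t(E) %*% E %*% W + eps)
      if (it %% 10 == 0 || it == max_iter) {
        obj <- sum((x - E %*% W)^2)
        if (is.finite(obj_old) && obj_old - obj < tol * (1 + abs(obj_old))) break
        obj_old <- obj
      }
    }
  }
  objective <- if (method == "kl") kl_div(x, E %*% W) else sum((x - E %*% W)^2)
  list(E = E, W = W, objective = objective, n_iter = it)
}

silhouette_mean <- function(dmat, cl) {
  n <- length(cl)
  if (length(unique(cl)) < 2) return(0)
  s <- vapply(seq_len(n), function(i) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) mean(dmat[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(dmat[i, cl == g])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Match two signature weight matrices
#'
#' Finds the globally optimal one-to-one assignment between the rows of two
#' signature-by-component matrices, maximising the total Pearson correlation
#' over matched pairs (exhaustive search over assignments; greedy matching can
#' mis-pair correlated signatures). Zero-variance rows are skipped.
#'
#' @param a,b Numeric matrices with identically ordered columns; `a` with s
#'   rows, `b` with t >= s rows.
#' @return `data.frame` with columns `a`, `b` (row names or indices), `r`,
#'   `p` (two-sided Pearson test) and `cosine`.
#' @export
match_signatures <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("component orderings differ")
  if (nrow(a) > nrow(b)) {
    m <- match_signatures(b, a)
    return(m[, c("b", "a", "r", "p", "cosine")] |>
             stats::setNames(c("a", "b", "r", "p", "cosine")))
  }
  ok_a <- apply(a, 1, stats::sd) > 0
  ok_b <- apply(b, 1, stats::sd) > 0
  if (!all(ok_a)) warning("zero-variance rows in 'a' skipped")
  ia <- which(ok_a); ib <- which(ok_b)
  r <- outer(ia, ib, Vectorize(function(i, j) stats::cor(a[i, ], b[j, ])))
  s <- length(ia)
  if (s > 8) stop("exhaustive assignment supports at most 8 signatures")
  best <- NULL; best_val <- -Inf
  for (perm in perms_of(length(ib), s)) {
    val <- sum(r[cbind(seq_len(s), perm)])
    if (val > best_val) {
      best_val <- val
      best <- perm
    }
  }
  pairs <- data.frame(
    a = rname(a, ia), b = rname(b, ib[best]),
    r = r[cbind(seq_len(s), best)],
    p = vapply(seq_len(s), function(i) {
      stats::cor.test(a[ia[i], ], b[ib[best[i]], ])$p.value
    }, numeric(1)),
    cosine = vapply(seq_len(s), function(i) {
      cosine_sim(a[ia[i], ], b[ib[best[i]], ])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  pairs
}

rname <- function(m, i) if (is.null(rownames(m))) i else rownames(m)[i]

# All injective assignments of s items into n slots (list of index vectors).
perms_of <- function(n, s) {
  if (s == 0) return(list(integer(0)))
  out <- list()
  rec <- function(chosen, avail) {
    if (length(chosen) == s) {
      out[[length(out) + 1]] <<- chosen
      return(invisible())
    }
    for (v in avail) rec(c(chosen, v), setdiff(avail, v))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Cosine similarity
#' @param x,y Numeric vectors.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_sim <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Per-signature presence fraction
#'
#' Fraction of samples in which each signature's normalised exposure exceeds
#' `threshold` (strict inequality).
#'
#' @param exposures Samples x signatures matrix; rows are normalised to sum to
#'   1 before thresholding.
#' @param threshold Exposure threshold (default 0.05).
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
signature_presence <- function(exposures, threshold = 0.05) {
  exposures <- as.matrix(exposures)
  rs <- rowSums(exposures)
  rs[rs == 0] <- 1
  colMeans(exposures / rs > threshold)
}
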