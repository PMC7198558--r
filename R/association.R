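#' Covariate-adjusted generalised linear model fit
#'
#' Maximum-likelihood GLM fit (IRLS via [stats::glm()]) on complete cases,
#' with per-term Wald z/t p-values, a convergence flag and a separation flag
#' (divergent coefficients under the binomial family are reported, not
#' silently returned).
#'
#' @param formula Model formula.
#' @param data Data frame; rows with missing model variables are dropped and
#'   counted.
#' @param family `"binomial"` (logit link) or `"gaussian"`.
#' @return A `glm_fit`: list with `coefficients` (`data.frame`: term,
#'   estimate, se, statistic, p), `loglik`, `n`, `n_dropped`, `converged`,
#'   `separation`, `model` (the underlying glm object) and `formula`.
#' @export
fit_glm <- function(formula, data, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("variables not in data: ", paste(missing_vars, collapse = ", "))
  }
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  for (v in vars[-1]) {
    x <- d[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      stop("covariate '", v, "' is constant: singular design")
    }
  }
  fam <- if (family == "binomial") stats::binomial("logit") else stats::gaussian()
  fit <- stats::glm(formula, data = d, family = fam)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      statistic = sm[, 3], p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  separation <- family == "binomial" &&
    (any(abs(coefs$estimate) > 15) || any(coefs$se > 100))
  structure(list(coefficients = coefs, loglik = as.numeric(stats::logLik(fit)),
                 n = nrow(d), n_dropped = sum(!cc),
                 converged = fit$converged, separation = separation,
                 model = fit, formula = formula),
            class = "glm_fit")
}

#' Backward stepwise elimination by Wald p-value
#'
#' Iteratively refits the model, removing the single covariate with the
#' largest (least significant) Wald p-value, until every remaining covariate
#' has p < `alpha`. Covariates named in `protected` (typically the exposure of
#' interest) are never removed. The elimination trace records one removed term
#' per step.
#'
#' @inheritParams fit_glm
#' @param alpha Retention threshold (default 0.05). `alpha = 1` removes
#'   nothing; `alpha = 0` removes every unprotected covariate.
#' @param protected Character vector of covariate names exempt from removal.
#' @return A `glm_fit` for the final model, with an added `trace`
#'   (`data.frame`: step, removed term, its p-value).
#' @export
stepwise_backward <- function(formula, data, family = "binomial",
                              alpha = 0.05, protected = NULL) {
  outcome <- all.vars(formula)[1]
  covars <- attr(stats::terms(formula), "term.labels")
  if (!length(covars)) stop("at least one covariate is required")
  trace <- data.frame(step = integer(0), removed = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (!length(covars)) {
      fit <- fit_glm(stats::reformulate("1", outcome), data, family)
      break
    }
    fit <- fit_glm(stats::reformulate(covars, outcome), data, family)
    # worst covariate = largest minimum p over the covariate's terms
    term_p <- vapply(covars, function(v) {
      rows <- grepl(paste0("^", v), fit$coefficients$term) &
        fit$coefficients$term != "(Intercept)"
      min(fit$coefficients$p[rows])
    }, numeric(1))
    removable <- setdiff(covars, protected)
    if (!length(removable)) break
    worst <- removable[which.max(term_p[removable])]
    if (term_p[worst] <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = worst,
                                     p = term_p[worst]))
    covars <- setdiff(covars, worst)
  }
  fit$trace <- trace
  fit
}

#' Likelihood-ratio test between nested fits
#'
#' Chi-squared test on twice the log-likelihood difference, with degrees of
#' freedom equal to the difference in the number of estimated terms. The
#' reduced model's terms must be a subset of the full model's.
#'
#' @param full,reduced `glm_fit` objects from [fit_glm()].
#' @return List with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  t_full <- full$coefficients$term
  t_red <- reduced$coefficients$term
  if (!all(t_red %in% t_full)) stop("models are not nested")
  df <- length(t_full) - length(t_red)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Permutation linear model
#'
#' Distribution-free p-values for linear-model terms: the outcome is permuted
#' `n_perm` times, the model refit and each term's |t| statistic recomputed;
#' `p = (1 + #permuted >= observed) / (1 + n_perm)`.
#'
#' @param formula Linear model formula.
#' @param data Data frame (complete cases used).
#' @param n_perm Number of permutations (>= 1000 recommended for reporting).
#' @param seed Integer seed (reproducible).
#' @return `data.frame` with columns `term`, `estimate`, `statistic`,
#'   `p_perm`.
#' @export
permutation_lm <- function(formula, data, n_perm = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  vars <- all.vars(formula)
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  outcome <- vars[1]
  obs <- stats::lm(formula, data = d)
  sm <- summary(obs)$coefficients
  terms <- rownames(sm)[rownames(sm) != "(Intercept)"]
  obs_t <- abs(sm[terms, "t value"])
  exceed <- stats::setNames(numeric(length(terms)), terms)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      d2 <- d
      d2[[outcome]] <- sample(d[[outcome]])
      smp <- summary(stats::lm(formula, data = d2))$coefficients
      exceed <- exceed + (abs(smp[terms, "t value"]) >= obs_t)
    }
  })
  data.frame(term = terms, estimate = sm[terms, "Estimate"],
             statistic = obs_t, p_perm = (1 + exceed) / (1 + n_perm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise rank-sum comparisons with BH adjustment
#'
#' Two-sided Wilcoxon rank-sum tests for the requested group comparisons, with
#' Benjamini-Hochberg adjustment across the comparison family. Comparisons
#' involving a group with fewer than 2 observations are skipped with a
#' warning.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param comparisons List of length-2 character vectors (default: all pairs).
#' @return `data.frame` with columns `group1`, `group2`, `n1`, `n2`, `p`,
#'   `p_adj`.
#' @export
group_compare_bh <- function(values, groups, comparisons = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2) stop("at least two groups are required")
  if (is.null(comparisons)) {
    comparisons <- utils::combn(lv, 2, simplify = FALSE)
  }
  rows <- lapply(comparisons, function(cmp) {
    x <- values[groups == cmp[1]]
    y <- values[groups == cmp[2]]
    if (length(x) < 2 || length(y) < 2) {
      warning("comparison ", cmp[1], " vs ", cmp[2],
              " skipped: group size < 2")
      return(NULL)
    }
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    data.frame(group1 = cmp[1], group2 = cmp[2], n1 = length(x),
               n2 = length(y), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
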