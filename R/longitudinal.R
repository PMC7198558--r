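#' Force-calling presence/absence decision
#'
#' Given alt-supporting and total read counts at a site already discovered in
#' a related tumour (counts taken from reads passing unique-pair, base
#' quality >= 20, read quality >= 5 filters upstream), the variant is
#' `present` with at least 2 supporting bases, `absent` with fewer than 2
#' supporting bases at a minimum of 50x depth, and `indeterminate` otherwise
#' (insufficient coverage to assert absence).
#'
#' @param alt,depth Non-negative integer vectors.
#' @param min_alt Supporting-base threshold (default 2).
#' @param min_depth_absent Depth required to call absence (default 50).
#' @return Character vector: `"present"`, `"absent"` or `"indeterminate"`.
#' @export
force_call <- function(alt, depth, min_alt = 2, min_depth_absent = 50) {
  if (any(alt < 0) || any(depth < 0)) stop("counts must be non-negative")
  ifelse(alt >= min_alt, "present",
         ifelse(depth >= min_depth_absent, "absent", "indeterminate"))
}

#' Classify variant sharing across a case's tumours
#'
#' From a per-case presence table, classifies each variant as `truncal`
#' (present in all tumour samples of the case), `primary_only` (confined to
#' primary tumours), `metastasis_only` (confined to metastases) or `other`.
#' Sites with `indeterminate` status are excluded from the denominator by
#' default (`indeterminate = "exclude"`); with `indeterminate = "strict"` any
#' indeterminate site makes the variant unclassifiable (`other`). Cases with a
#' single tumour are skipped.
#'
#' @param presence `data.frame` with columns `case`, `variant`, `sample`,
#'   `status` (from [force_call()]) and `stage` (`"primary"`/`"metastasis"`
#'   per sample).
#' @param indeterminate `"exclude"` or `"strict"`.
#' @return `data.frame` with columns `case`, `variant`, `class`.
#' @export
classify_sharing <- function(presence, indeterminate = c("exclude", "strict")) {
  indeterminate <- match.arg(indeterminate)
  out <- lapply(split(presence, presence$case), function(pc) {
    if (length(unique(pc$sample)) < 2) return(NULL)
    do.call(rbind, lapply(split(pc, pc$variant), function(pv) {
      cls <- sharing_class(pv$status, pv$stage, indeterminate)
      data.frame(case = pv$case[1], variant = pv$variant[1], class = cls,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

sharing_class <- function(status, stage, indeterminate) {
  ind <- status == "indeterminate"
  if (indeterminate == "strict" && any(ind)) return("other")
  status <- status[!ind]
  stage <- stage[!ind]
  # with fewer than two informative tumours the sharing pattern cannot be
  # established (e.g. present in one metastasis, indeterminate in the primary)
  if (length(status) < 2 || !any(status == "present")) return("other")
  pres <- status == "present"
  if (all(pres)) return("truncal")
  if (all(stage[pres] == "primary")) return("primary_only")
  if (all(stage[pres] == "metastasis")) return("metastasis_only")
  "other"
}

#' Jaccard concordance index (percentage)
#'
#' `100 * |A intersect B| / |A union B|`; defined as 0 (with a message) when
#' both sets are empty.
#'
#' @param a,b Vectors of variant identifiers.
#' @return Percentage in \[0, 100\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    message("both variant sets empty; Jaccard defined as 0")
    return(0)
  }
  100 * length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix over variant sets
#' @param sets Named list of variant-identifier vectors.
#' @return Symmetric numeric matrix of percentages (diagonal 100 for
#'   non-empty sets).
#' @export
jaccard_matrix <- function(sets) {
  n <- length(sets)
  m <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- suppressMessages(jaccard_index(sets[[i]], sets[[j]]))
    }
  }
  m
}

#' Re-segment profiles to the union breakpoint grid
#'
#' Splits every profile's segments at the union of all profiles' segment
#' boundaries so that all profiles share an identical segment grid (as
#' produced by joint segmentation).
#'
#' @param profiles List of [cn_profile()] covering identical chromosomes.
#' @return List of `cn_profile` on the common grid.
#' @export
align_profiles <- function(profiles) {
  chroms <- unique(unlist(lapply(profiles, function(p) p$segments$chrom)))
  grids <- lapply(chroms, function(ch) {
    starts <- sort(unique(unlist(lapply(profiles, function(p) {
      s <- p$segments[p$segments$chrom == ch, ]
      c(s$start, s$end + 1)
    }))))
    data.frame(chrom = ch, start = starts[-length(starts)],
               end = starts[-1] - 1, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, grids)
  lapply(profiles, function(p) {
    idx <- vapply(seq_len(nrow(grid)), function(i) {
      hit <- which(p$segments$chrom == grid$chrom[i] &
                     p$segments$start <= grid$start[i] &
                     p$segments$end >= grid$end[i])
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    if (any(is.na(idx))) stop("profiles do not cover a common grid")
    segs <- cbind(grid, p$segments[idx, c("major", "minor", "total")])
    cn_profile(p$sample, segs, purity = p$purity, ploidy = p$ploidy)
  })
}

#' Minimum-event copy-number distance between two profiles
#'
#' Counts the minimum number of segmental events (amplification or deletion of
#' a contiguous run of segments by one copy) transforming profile A into
#' profile B, per allele and chromosome. Allele copy numbers are rounded and
#' capped at `cap` (default 4). With the per-position difference `d = B - A`,
#' positive part `p` and negative part `n`, the count per chromosome and
#' allele is `sum(max(0, p_i - p_{i-1})) + sum(max(0, n_i - n_{i-1}))` with
#' `p_0 = n_0 = 0`. An allele lost to zero copies cannot be regained: any
#' transition requiring `A_i = 0, B_i > 0` has infinite distance.
#'
#' Both profiles must share a segment grid (see [align_profiles()]).
#'
#' @param a,b [cn_profile()] objects on the same grid.
#' @param cap Copy-number cap (default 4).
#' @param symmetric Return `max(d(A,B), d(B,A))` (default) or the directed
#'   distance A -> B.
#' @return Non-negative number (possibly `Inf`).
#' @export
cn_event_distance <- function(a, b, cap = 4, symmetric = TRUE) {
  sa <- a$segments; sb <- b$segments
  if (nrow(sa) != nrow(sb) ||
      any(sa$chrom != sb$chrom | sa$start != sb$start | sa$end != sb$end)) {
    stop("mismatched segment grids; run align_profiles() first")
  }
  directed <- function(sx, sy) {
    total <- 0
    for (ch in unique(sx$chrom)) {
      i <- sx$chrom == ch
      for (allele in c("major", "minor")) {
        vx <- pmin(round(sx[[allele]][i]), cap)
        vy <- pmin(round(sy[[allele]][i]), cap)
        total <- total + allele_event_distance(vx, vy)
      }
    }
    total
  }
  if (!symmetric) return(directed(sa, sb))
  max(directed(sa, sb), directed(sb, sa))
}

# Directed minimum-event count for one allele profile (integer vectors).
allele_event_distance <- function(a, b) {
  if (any(a == 0 & b > 0)) return(Inf)
  d <- b - a
  p <- pmax(d, 0)
  n <- pmax(-d, 0)
  sum(pmax(0, diff(c(0, p)))) + sum(pmax(0, diff(c(0, n))))
}

#' Pairwise minimum-event distance matrix with diploid root
#'
#' Aligns the profiles to a common grid, appends a pure diploid pseudo-sample
#' (major = minor = 1 on every segment, no copy-number changes) and computes
#' the symmetrised pairwise minimum-event distances.
#'
#' Pairs separated by an allele regain have infinite minimum-event distance;
#' for tree building these entries are replaced by the maximum finite
#' distance in the matrix plus `2 * cap` (an effectively-infinite but usable
#' penalty), with a warning.
#'
#' @param profiles Named list of [cn_profile()].
#' @param cap Copy-number cap (default 4).
#' @param root Label for the diploid outgroup (default `"diploid"`).
#' @return Symmetric numeric matrix with the root as final row/column.
#' @export
cn_distance_matrix <- function(profiles, cap = 4, root = "diploid") {
  aligned <- align_profiles(profiles)
  grid <- aligned[[1]]$segments[, c("chrom", "start", "end")]
  dip <- cn_profile(root, cbind(grid, major = 1, minor = 1, total = 2),
                    purity = 1, ploidy = 2)
  aligned <- c(aligned, list(dip))
  ids <- vapply(aligned, `[[`, character(1), "sample")
  n <- length(aligned)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- cn_event_distance(aligned[[i]], aligned[[j]], cap)
    }
  }
  if (any(is.infinite(m))) {
    warning("infinite distances (allele regain) replaced by a large penalty")
    m[is.infinite(m)] <- max(m[is.finite(m)]) + 2 * cap
  }
  m
}

#' Neighbour-joining tree rooted at the diploid outgroup
#'
#' Builds a neighbour-joining topology from a minimum-event distance matrix
#' and roots it at the diploid pseudo-sample. Taxa are ordered by sample id
#' before joining so that ties break deterministically. With fewer than 3 taxa
#' a trivial tree is returned with a warning.
#'
#' @param dist_matrix Symmetric distance matrix (e.g. from
#'   [cn_distance_matrix()]).
#' @param root Outgroup label (default `"diploid"`).
#' @return An [ape::phylo] tree (use [ape::write.tree()] for Newick).
#' @export
build_tree <- function(dist_matrix, root = "diploid") {
  ids <- sort(rownames(dist_matrix))
  dist_matrix <- dist_matrix[ids, ids]
  if (nrow(dist_matrix) < 3) {
    warning("fewer than 3 taxa: returning trivial tree")
    tr <- ape::read.tree(text = paste0("(", paste(ids, collapse = ","), ");"))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(dist_matrix))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (root %in% tr$tip.label) {
    tr <- ape::root(tr, outgroup = root, resolve.root = TRUE)
  }
  tr
}

#' Copy-number events against time since diagnosis
#'
#' Linear fit of per-sample event counts on months since diagnosis.
#'
#' @param events Numeric vector of per-sample CN event counts.
#' @param months Months since initial diagnosis, same length.
#' @return List with `slope`, `intercept`, `r_squared`, `p` (slope Wald
#'   p-value) and the `lm` fit.
#' @export
events_vs_time <- function(events, months) {
  if (length(events) < 3) stop("need at least 3 samples")
  fit <- stats::lm(events ~ months)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients["months", 4] else NA_real_
  list(slope = unname(stats::coef(fit)["months"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared, p = p, fit = fit)
}
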