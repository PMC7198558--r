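#' Fraction of the genome affected by aneuploidy
#'
#' Bases within segments whose rounded total copy number differs from the
#' sample's ploidy rounded to the nearest integer, divided by the total bases
#' across all segments.
#'
#' @param profile A [cn_profile()].
#' @return Fraction in \[0, 1\].
#' @export
fraction_genome_aneuploid <- function(profile) {
  segs <- profile$segments
  if (!nrow(segs)) stop("empty profile")
  baseline <- round(profile$ploidy)
  len <- segs$end - segs$start + 1
  sum(len[round(segs$total) != baseline]) / sum(len)
}

#' Call arm-level copy-number events
#'
#' For each of the 39 scored autosomal arms, computes the segment-length-
#' weighted mean of `log2(total CN / round(ploidy))` over the arm and calls a
#' gain when the mean exceeds `+threshold`, a loss below `-threshold`, and
#' neutral otherwise. Arms with no overlapping segment are neutral with a
#' warning.
#'
#' @param profile A [cn_profile()].
#' @param genome Genome model.
#' @param threshold Presence threshold on the ploidy-corrected log2 ratio
#'   (default 0.1, strict inequality).
#' @return `data.frame` with columns `sample`, `arm`, `log2_ratio`, `status`
#'   (`gain`/`loss`/`neutral`), one row per scored arm.
#' @export
call_arm_events <- function(profile, genome = tgct_genome(), threshold = 0.1) {
  arms <- genome_arms(genome)
  arms <- arms[arms$scored, , drop = FALSE]
  segs <- profile$segments
  baseline <- max(1, round(profile$ploidy))
  ratio <- vapply(seq_len(nrow(arms)), function(i) {
    s <- segs[segs$chrom == arms$chrom[i] & segs$end >= arms$start[i] &
                segs$start <= arms$end[i], , drop = FALSE]
    if (!nrow(s)) {
      warning("no segments overlap arm ", arms$arm_name[i], "; neutral")
      return(0)
    }
    w <- pmin(s$end, arms$end[i]) - pmax(s$start, arms$start[i]) + 1
    lr <- log2(pmax(s$total, 1e-3) / baseline)
    sum(w * lr) / sum(w)
  }, numeric(1))
  status <- ifelse(ratio > threshold, "gain",
                   ifelse(ratio < -threshold, "loss", "neutral"))
  data.frame(sample = profile$sample, arm = arms$arm_name,
             log2_ratio = ratio, status = status, stringsAsFactors = FALSE)
}

#' Arm-level aneuploidy score
#'
#' The number of scored autosomal arms (39: both arms of non-acrocentric
#' autosomes, long arms only of chromosomes 13, 14, 15, 21 and 22) carrying a
#' gain or loss; ranges 0-39.
#'
#' @param arm_events One sample's table from [call_arm_events()].
#' @return Integer in 0..39.
#' @export
aneuploidy_score <- function(arm_events) {
  if (nrow(arm_events) != 39 || anyDuplicated(arm_events$arm)) {
    stop("expected one row for each of the 39 scored arms")
  }
  sum(arm_events$status != "neutral")
}

#' Per-arm event frequency comparison between two groups
#'
#' For each arm, compares the number of samples carrying an event (gain, loss,
#' or either) between two groups with a two-sided Fisher's exact test. Arms
#' reaching `p < alpha` are flagged for follow-up covariate-adjusted modelling.
#'
#' @param arm_events Row-bound [call_arm_events()] tables for many samples.
#' @param groups Named character/factor vector: group label per sample id.
#' @param event `"any"`, `"gain"` or `"loss"`.
#' @param alpha Nominal significance threshold for the `followup` flag.
#' @return `data.frame` with per-arm counts, Fisher `p` and `followup`.
#' @export
event_frequency_tests <- function(arm_events, groups, event = c("any", "gain", "loss"),
                                  alpha = 0.05) {
  event <- match.arg(event)
  groups <- stats::setNames(as.character(groups), names(groups))
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups are required")
  if (any(table(groups) == 0)) stop("empty group")
  hit <- if (event == "any") arm_events$status != "neutral"
         else arm_events$status == event
  g <- groups[as.character(arm_events$sample)]
  if (any(is.na(g))) stop("group label missing for some samples")
  out <- do.call(rbind, lapply(unique(arm_events$arm), function(a) {
    sel <- arm_events$arm == a
    n1 <- sum(sel & g == lv[1]); x1 <- sum(sel & g == lv[1] & hit)
    n2 <- sum(sel & g == lv[2]); x2 <- sum(sel & g == lv[2] & hit)
    p <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2))$p.value
    data.frame(arm = a, events_1 = x1, n_1 = n1, events_2 = x2, n_2 = n2,
               p = p, stringsAsFactors = FALSE)
  }))
  names(out)[2:5] <- c(paste0("events_", lv[1]), paste0("n_", lv[1]),
                       paste0("events_", lv[2]), paste0("n_", lv[2]))
  out$followup <- out$p < alpha
  rownames(out) <- NULL
  out
}
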