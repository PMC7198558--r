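#' Multi-caller consensus filter
#'
#' Retains calls made by at least `min_callers` of the calling algorithms.
#' Calls with an empty caller set are rejected and logged in the `audit`
#' attribute.
#'
#' @param calls Variant `data.frame` with a `callers` column (comma-separated
#'   caller names, subset of strelka/mutect/mutect2).
#' @param min_callers Minimum caller support (default 2).
#' @return The retained rows, with an `audit` attribute naming rejected rows.
#' @export
consensus_filter <- function(calls, min_callers = 2) {
  if (!nrow(calls)) return(calls)
  n <- vapply(strsplit(as.character(calls$callers), ","), function(x) {
    length(x[nzchar(trimws(x))])
  }, integer(1))
  out <- calls[n >= min_callers, , drop = FALSE]
  attr(out, "audit") <- data.frame(
    row = which(n < min_callers),
    rule = ifelse(n[n < min_callers] == 0, "empty_caller_set", "consensus"),
    stringsAsFactors = FALSE
  )
  out
}

#' Strand / quality read-evidence filter
#'
#' Pass requires at least one alternative read on each strand, mean Phred base
#' quality >= 26 and mean mapping quality >= 50 (thresholds inclusive). Calls
#' with missing quality fields fail with reason `missing_fields`.
#'
#' @param calls `data.frame` with columns `alt_fwd`, `alt_rev`, `base_qual`,
#'   `map_qual`.
#' @param min_bq,min_mq Quality thresholds.
#' @param oxog_only_ca If `TRUE`, the filter is applied only to C>A / G>T
#'   candidates (the oxidation-artifact substitution class); other calls pass
#'   unconditionally. Default `FALSE`: applied to all calls.
#' @return `data.frame` with columns `pass` (logical) and `reason`
#'   (`NA` when passing).
#' @export
strand_quality_filter <- function(calls, min_bq = 26, min_mq = 50,
                                  oxog_only_ca = FALSE) {
  fields <- cbind(calls$alt_fwd, calls$alt_rev, calls$base_qual, calls$map_qual)
  missing <- apply(is.na(fields), 1, any)
  pass <- !missing &
    calls$alt_fwd >= 1 & calls$alt_rev >= 1 &
    calls$base_qual >= min_bq & calls$map_qual >= min_mq
  reason <- rep(NA_character_, nrow(calls))
  reason[missing] <- "missing_fields"
  reason[!missing & !pass] <- ifelse(
    (calls$alt_fwd < 1 | calls$alt_rev < 1)[!missing & !pass],
    "strand_bias", "low_quality")
  if (oxog_only_ca) {
    ca <- (toupper(calls$ref) == "C" & toupper(calls$alt) == "A") |
      (toupper(calls$ref) == "G" & toupper(calls$alt) == "T")
    pass[!ca] <- TRUE
    reason[!ca] <- NA_character_
  }
  data.frame(pass = pass & !missing, reason = reason, stringsAsFactors = FALSE)
}

#' Read-support / VAF hard filter
#'
#' SNVs require >= 5 supporting reads, indels >= 10, and both a variant allele
#' frequency >= 0.05 (all thresholds inclusive).
#'
#' @param calls `data.frame` with columns `class` (`"SNV"`/`"indel"`),
#'   `alt_reads`, `vaf`.
#' @param min_alt_snv,min_alt_indel,min_vaf Thresholds.
#' @return Logical vector, `TRUE` where the call passes.
#' @export
hard_filter <- function(calls, min_alt_snv = 5, min_alt_indel = 10,
                        min_vaf = 0.05) {
  cls <- toupper(as.character(calls$class))
  if (!all(cls %in% c("SNV", "INDEL"))) {
    stop("unknown variant class: ",
         paste(unique(cls[!cls %in% c("SNV", "INDEL")]), collapse = ", "))
  }
  min_alt <- ifelse(cls == "SNV", min_alt_snv, min_alt_indel)
  calls$alt_reads >= min_alt & calls$vaf >= min_vaf
}

#' Rescue rules for hard-filter failures
#'
#' A call failing the hard filter is rescued if it is a known driver mutation
#' (OncoKB flag), overlaps a catalogued alteration with count >= 50, or if the
#' identical variant passes the hard filter in another tumour from the same
#' case.
#'
#' @param calls Full variant `data.frame` (all tumours) with columns
#'   `oncokb_driver` (logical), `cosmic_count`, `case`, `sample`, `chrom`,
#'   `pos`, `ref`, `alt` plus the [hard_filter()] columns.
#' @param hard_pass Logical vector from [hard_filter()] over `calls`.
#' @param min_cosmic_count Catalogue count threshold (default 50).
#' @return Logical vector: `TRUE` where a failing call is rescued.
#' @export
rescue <- function(calls, hard_pass = hard_filter(calls),
                   min_cosmic_count = 50) {
  key <- paste(calls$case, calls$chrom, calls$pos, calls$ref, calls$alt,
               sep = ":")
  pass_keys <- unique(key[hard_pass])
  sibling <- key %in% pass_keys
  knowledge <- (!is.na(calls$oncokb_driver) & calls$oncokb_driver) |
    (!is.na(calls$cosmic_count) & calls$cosmic_count >= min_cosmic_count)
  !hard_pass & (knowledge | sibling)
}

#' Dataset-specific artifact filter
#'
#' Removes genes and variants whose mutation frequency is >= 10% of cases in
#' one dataset while simultaneously below 1% in every other dataset (a pattern
#' indicating a dataset-specific artifact). Applied at both gene and variant
#' granularity; the union is removed. With a single dataset the filter is a
#' no-op with a warning.
#'
#' @param calls Variant `data.frame` with columns `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `case`, `dataset`.
#' @param dataset_sizes Optional named vector of cases per dataset; by default
#'   derived from the distinct cases observed in `calls` (an underestimate if
#'   some cases carry no calls).
#' @param high,low Frequency thresholds (defaults 0.10 and 0.01).
#' @return List with `calls` (retained rows), `removed_genes`,
#'   `removed_variants`.
#' @export
dataset_artifact_filter <- function(calls, dataset_sizes = NULL,
                                    high = 0.10, low = 0.01) {
  datasets <- unique(as.character(calls$dataset))
  if (length(datasets) < 2) {
    warning("artifact filter requires >= 2 datasets; no-op")
    return(list(calls = calls, removed_genes = character(0),
                removed_variants = character(0)))
  }
  if (is.null(dataset_sizes)) {
    dataset_sizes <- vapply(datasets, function(d) {
      length(unique(calls$case[calls$dataset == d]))
    }, numeric(1))
  }
  flag_entities <- function(entity) {
    freq <- vapply(datasets, function(d) {
      sub <- calls$dataset == d
      n_mut <- vapply(unique(entity), function(e) {
        length(unique(calls$case[sub & entity == e]))
      }, numeric(1))
      n_mut / dataset_sizes[[d]]
    }, numeric(length(unique(entity))))
    freq <- matrix(freq, ncol = length(datasets),
                   dimnames = list(unique(entity), datasets))
    bad <- apply(freq, 1, function(f) {
      any(f >= high & vapply(seq_along(f), function(i) {
        all(f[-i] < low)
      }, logical(1)))
    })
    rownames(freq)[bad]
  }
  vkey <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  removed_genes <- flag_entities(as.character(calls$gene))
  removed_variants <- flag_entities(vkey)
  drop <- calls$gene %in% removed_genes | vkey %in% removed_variants
  list(calls = calls[!drop, , drop = FALSE],
       removed_genes = removed_genes, removed_variants = removed_variants)
}

#' Read a BED3 file
#'
#' Minimal reader for 3+ column BED (0-based, half-open). Malformed lines
#' raise an error naming the line number.
#'
#' @param path BED file path.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t| +")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3 || is.na(suppressWarnings(as.numeric(p[2]))) ||
        is.na(suppressWarnings(as.numeric(p[3])))) {
      stop("malformed BED line ", i, " in ", path)
    }
  }
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.numeric(vapply(parts, `[`, character(1), 2)),
    end = as.numeric(vapply(parts, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
}

#' Intersect capture interval sets and restrict calls to the intersect
#'
#' Computes the genomic intersection of one or more capture interval sets
#' (each a BED-style `data.frame`, 0-based half-open) and retains the calls
#' whose (1-based) position falls inside it. The intersect size in bases is
#' returned for use as a mutation-burden denominator. Intersection is
#' commutative and associative over interval sets.
#'
#' @param calls Variant `data.frame` with `chrom` and 1-based `pos`; may be
#'   `NULL` to compute the intersect only.
#' @param beds List of BED `data.frame`s (from [read_bed()]).
#' @return List with `calls` (retained rows), `intersect` (merged BED
#'   `data.frame`) and `bases` (total intersect size).
#' @export
capture_intersect <- function(calls, beds) {
  if (!length(beds)) stop("at least one BED interval set is required")
  by_chrom <- lapply(beds, function(bed) {
    lapply(split(bed, bed$chrom), function(b) {
      IRanges::reduce(IRanges::IRanges(start = b$start + 1, end = b$end))
    })
  })
  chroms <- Reduce(intersect, lapply(by_chrom, names))
  inter <- lapply(chroms, function(ch) {
    Reduce(IRanges::intersect, lapply(by_chrom, `[[`, ch))
  })
  names(inter) <- chroms
  inter <- inter[vapply(inter, length, integer(1)) > 0]
  bed_out <- if (length(inter)) {
    do.call(rbind, lapply(names(inter), function(ch) {
      data.frame(chrom = ch, start = IRanges::start(inter[[ch]]) - 1,
                 end = IRanges::end(inter[[ch]]), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  bases <- sum(bed_out$end - bed_out$start)
  kept <- NULL
  if (!is.null(calls)) {
    inside <- vapply(seq_len(nrow(calls)), function(i) {
      ch <- as.character(calls$chrom[i])
      if (!ch %in% names(inter)) return(FALSE)
      any(IRanges::start(inter[[ch]]) <= calls$pos[i] &
            IRanges::end(inter[[ch]]) >= calls$pos[i])
    }, logical(1))
    kept <- calls[inside, , drop = FALSE]
  }
  list(calls = kept, intersect = bed_out, bases = bases)
}

#' Full variant-filtering pipeline
#'
#' Applies, in order: consensus filter (>= 2 callers), strand/quality filter,
#' hard filter with rescue of failures (rescue is evaluated only for calls
#' that failed the hard filter; consensus failures are not rescuable), the
#' dataset artifact filter, and optionally the capture-intersect restriction.
#' An audit log records the rule that removed each call.
#'
#' @param calls Variant `data.frame` (see [consensus_filter()],
#'   [strand_quality_filter()], [hard_filter()], [rescue()] for required
#'   columns).
#' @param beds Optional list of capture BED `data.frame`s.
#' @param apply_artifact_filter Run [dataset_artifact_filter()] (default TRUE
#'   when >= 2 datasets are present).
#' @param ... Passed to [strand_quality_filter()].
#' @return List with `calls` (retained), `audit` (`data.frame`: variant key,
#'   rule fired), `intersect_bases` (or `NA` when no BEDs given).
#' @export
filter_variants <- function(calls, beds = NULL,
                            apply_artifact_filter = TRUE, ...) {
  key <- paste(calls$sample, calls$chrom, calls$pos, calls$ref, calls$alt,
               sep = ":")
  audit <- data.frame(variant = character(0), rule = character(0),
                      stringsAsFactors = FALSE)
  log_drop <- function(keys, rule) {
    if (length(keys)) {
      audit <<- rbind(audit, data.frame(variant = keys, rule = rule,
                                        stringsAsFactors = FALSE))
    }
  }
  cons <- consensus_filter(calls)
  log_drop(setdiff(key, paste(cons$sample, cons$chrom, cons$pos, cons$ref,
                              cons$alt, sep = ":")), "consensus")
  calls <- cons
  if (nrow(calls)) {
    sq <- strand_quality_filter(calls, ...)
    log_drop(with(calls[!sq$pass, , drop = FALSE],
                  paste(sample, chrom, pos, ref, alt, sep = ":")),
             "strand_quality")
    calls <- calls[sq$pass, , drop = FALSE]
  }
  if (nrow(calls)) {
    hp <- hard_filter(calls)
    resc <- rescue(calls, hp)
    drop <- !hp & !resc
    log_drop(with(calls[drop, , drop = FALSE],
                  paste(sample, chrom, pos, ref, alt, sep = ":")),
             "hard_filter")
    calls <- calls[!drop, , drop = FALSE]
  }
  if (apply_artifact_filter && nrow(calls) &&
      length(unique(calls$dataset)) >= 2) {
    af <- dataset_artifact_filter(calls)
    log_drop(with(calls[!rownames(calls) %in% rownames(af$calls), ,
                        drop = FALSE],
                  paste(sample, chrom, pos, ref, alt, sep = ":")),
             "dataset_artifact")
    calls <- af$calls
  }
  intersect_bases <- NA_real_
  if (!is.null(beds) && length(beds)) {
    ci <- capture_intersect(calls, beds)
    log_drop(with(calls[!rownames(calls) %in% rownames(ci$calls), ,
                        drop = FALSE],
                  paste(sample, chrom, pos, ref, alt, sep = ":")),
             "capture_intersect")
    calls <- ci$calls
    intersect_bases <- ci$bases
  }
  list(calls = calls, audit = audit, intersect_bases = intersect_bases)
}
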