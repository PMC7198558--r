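#' Absolute copy-number profile container
#'
#' A per-sample segmented allele-specific absolute copy-number profile.
#' Coordinates are 1-based inclusive (SEG convention). Copy numbers may be
#' non-integer: non-integer values are used throughout (several copy-number
#' features depend on them).
#'
#' @param sample Sample identifier.
#' @param segments `data.frame` with columns `chrom`, `start`, `end`, `major`,
#'   `minor`, `total`. If `total` is missing it is set to `major + minor`.
#' @param purity Tumour purity (cellularity) in (0, 1].
#' @param ploidy Average tumour genome copy number.
#' @return A `cn_profile` object.
#' @export
cn_profile <- function(sample, segments, purity = 1, ploidy = 2) {
  need <- c("chrom", "start", "end", "major", "minor")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(segments$total)) segments$total <- segments$major + segments$minor
  segments$chrom <- as.character(segments$chrom)
  if (any(segments$start > segments$end)) {
    stop("segment start must be <= end")  # 1-based inclusive: 1 bp segments OK
  }
  if (any(segments$minor < 0) || any(segments$major < segments$minor - 1e-9)) {
    stop("segments must satisfy major >= minor >= 0")
  }
  o <- order(suppressWarnings(as.numeric(segments$chrom)), segments$chrom,
             segments$start)
  segments <- segments[o, , drop = FALSE]
  rownames(segments) <- NULL
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping segments on chromosome ", ch)
    }
  }
  structure(list(sample = sample, purity = purity, ploidy = ploidy,
                 segments = segments),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> %s: %d segments, purity %.2f, ploidy %.2f\n",
              x$sample, nrow(x$segments), x$purity, x$ploidy))
  invisible(x)
}

#' Read / write SEG-like copy-number tables
#'
#' SEG-like TSV with columns `sample`, `chrom`, `start`, `end`, `major`,
#' `minor`, `total`, `purity`, `ploidy` (one row per segment).
#'
#' @param profiles List of `cn_profile` objects (writer) / `path` TSV path.
#' @param path File path.
#' @return `read_seg()` returns a named list of `cn_profile`.
#' @export
write_seg <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    cbind(sample = p$sample, p$segments, purity = p$purity, ploidy = p$ploidy)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$chrom <- as.character(x$chrom)
  out <- lapply(split(x, x$sample), function(s) {
    cn_profile(s$sample[1],
               s[, c("chrom", "start", "end", "major", "minor", "total")],
               purity = s$purity[1], ploidy = s$ploidy[1])
  })
  out[unique(x$sample)]
}

# Total CN of the segment overlapping each (chrom, pos); NA when no overlap.
lookup_total_cn <- function(profile, chrom, pos) {
  segs <- profile$segments
  vapply(seq_along(chrom), function(i) {
    hit <- segs$chrom == as.character(chrom[i]) &
      segs$start <= pos[i] & segs$end >= pos[i]
    if (any(hit)) segs$total[which(hit)[1]] else NA_real_
  }, numeric(1))
}
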