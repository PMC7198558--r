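#' Tumour mutation burden per megabase
#'
#' TMB is the number of mutations divided by the number of bases in the
#' capture intersect, expressed per megabase; computed for all mutations and
#' for the nonsynonymous subset.
#'
#' @param calls Variant `data.frame` with columns `sample` and `consequence`
#'   (`"nonsynonymous"` vs anything else).
#' @param intersect_bases Denominator in bases (> 0), e.g. from
#'   [capture_intersect()].
#' @param samples Optional character vector of sample ids to report (samples
#'   with zero calls otherwise drop out); defaults to samples seen in `calls`.
#' @return `data.frame` with columns `sample`, `n_total`, `n_nonsyn`,
#'   `tmb_total`, `tmb_nonsyn`, `bases`.
#' @export
compute_tmb <- function(calls, intersect_bases, samples = NULL) {
  if (is.na(intersect_bases) || intersect_bases <= 0) {
    stop("intersect_bases must be > 0")
  }
  if (is.null(samples)) samples <- unique(as.character(calls$sample))
  mb <- intersect_bases / 1e6
  n_total <- vapply(samples, function(s) sum(calls$sample == s), numeric(1))
  n_nonsyn <- vapply(samples, function(s) {
    sum(calls$sample == s & calls$consequence == "nonsynonymous")
  }, numeric(1))
  data.frame(sample = samples, n_total = n_total, n_nonsyn = n_nonsyn,
             tmb_total = n_total / mb, tmb_nonsyn = n_nonsyn / mb,
             bases = intersect_bases, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mutation multiplicity and clonality
#'
#' The multiplicity of a variant is the number of mutated allele copies per
#' tumour cell: `m = VAF * (purity * CNt + 2 * (1 - purity)) / purity`, where
#' `CNt` is the local total tumour copy number. Multiplicity > 0.8 is taken as
#' likely indicative of a clonal mutation.
#'
#' @param vaf Variant allele fraction(s) in \[0, 1\].
#' @param purity Tumour purity in (0, 1].
#' @param total_cn Local total copy number (> 0).
#' @param clonal_threshold Clonality threshold on multiplicity (default 0.8,
#'   strict `>`).
#' @return `data.frame` with columns `multiplicity` and `clonal`.
#' @export
multiplicity <- function(vaf, purity, total_cn, clonal_threshold = 0.8) {
  if (any(purity <= 0) || any(purity > 1)) stop("purity must be in (0, 1]")
  if (any(total_cn <= 0)) stop("total_cn must be > 0")
  if (any(vaf < 0 | vaf > 1)) stop("vaf must be in [0, 1]")
  m <- vaf * (purity * total_cn + 2 * (1 - purity)) / purity
  data.frame(multiplicity = m, clonal = m > clonal_threshold)
}

#' Per-variant multiplicity against a copy-number profile
#'
#' Looks up the total copy number of the segment overlapping each variant in
#' the sample's profile; variants with no overlapping segment fall back to the
#' profile ploidy rounded to the nearest integer (recorded in `cn_source`).
#'
#' @param calls Variant `data.frame` with `chrom`, `pos`, `vaf`.
#' @param profile The sample's [cn_profile()].
#' @return `calls` with added columns `total_cn`, `cn_source`
#'   (`"segment"`/`"ploidy"`), `multiplicity`, `clonal`.
#' @export
variant_multiplicity <- function(calls, profile) {
  cn <- lookup_total_cn(profile, calls$chrom, calls$pos)
  source <- ifelse(is.na(cn), "ploidy", "segment")
  cn[is.na(cn)] <- round(profile$ploidy)
  m <- multiplicity(calls$vaf, profile$purity, cn)
  cbind(calls, total_cn = cn, cn_source = source, m)
}

#' Pathway gene sets
#'
#' The mutually exclusive driver gene sets used for pathway-level burden:
#' RAS/RAF, PI3K/MTOR and WNT/CTNNB1 signalling, DNA repair and chromatin
#' modification.
#'
#' @return Named list of uppercase gene symbol vectors.
#' @export
pathway_genes <- function() {
  list(
    "RAS/RAF" = c("KRAS", "NRAS", "BRAF", "NF1"),
    "PI3K/MTOR" = c("PIK3CA", "PIK3CB", "PIK3R1", "PIK3R2", "MTOR", "RICTOR",
                    "AKT1", "PTEN"),
    "WNT/CTNNB1" = c("CTNNB1", "APC", "AXIN1", "GSK3B", "FAT1"),
    "DNA repair" = c("BRCA1", "BRCA2", "ATM", "CHEK2", "PALB2", "POLE",
                     "TOP1", "BARD1", "PMS2", "MUTYH", "BAP1", "CDK12"),
    "chromatin modification" = c("CREBBP", "DNMT3A", "NSD1", "EP300", "KMT2A",
                                 "SMARCB1", "SMARCA4", "SETD2", "KMT2C",
                                 "KDM6A", "ASXL1", "ARID1A", "ARID1B",
                                 "ARID2", "PBRM1")
  )
}

#' Assign genes to pathways
#'
#' @param gene Character vector of gene symbols (normalised to uppercase).
#' @return Character vector: the pathway label, or `"none"`.
#' @export
assign_pathway <- function(gene) {
  sets <- pathway_genes()
  lookup <- stats::setNames(rep(names(sets), lengths(sets)),
                            unlist(sets, use.names = FALSE))
  out <- lookup[toupper(gene)]
  out[is.na(out)] <- "none"
  unname(out)
}

#' Driver-gene triage
#'
#' Categorises genes by driver evidence from two significance algorithms
#' (whose statistics are supplied as inputs): `Definitive` requires q < 0.05
#' in both; `Likely` requires q < 0.05 in exactly one; `Putative` requires a
#' nominal p < 0.05 in at least one algorithm AND a recurrent-driver-variant
#' centile >= 95 AND > 50% of the gene's variants being known drivers
#' (jointly by default; set `putative_any = TRUE` for any-of semantics);
#' otherwise `None`. Genes with missing statistics are skipped with a warning.
#'
#' @param stats_df `data.frame` with columns `gene`, `q1`, `q2`, `p1`, `p2`,
#'   `driver_fraction`, `recurrent_centile`.
#' @param q_cut,p_cut Significance thresholds (defaults 0.05).
#' @param putative_any Use any-of semantics for the three Putative criteria.
#' @return `stats_df` with an added `category` column (skipped genes dropped).
#' @export
driver_triage <- function(stats_df, q_cut = 0.05, p_cut = 0.05,
                          putative_any = FALSE) {
  need <- c("gene", "q1", "q2", "p1", "p2", "driver_fraction",
            "recurrent_centile")
  stopifnot(all(need %in% names(stats_df)))
  complete <- stats::complete.cases(stats_df[, setdiff(need, "gene")])
  if (any(!complete)) {
    warning(sum(!complete), " gene(s) skipped for missing statistics: ",
            paste(stats_df$gene[!complete], collapse = ", "))
    stats_df <- stats_df[complete, , drop = FALSE]
  }
  qsig <- (stats_df$q1 < q_cut) + (stats_df$q2 < q_cut)
  put_a <- stats_df$p1 < p_cut | stats_df$p2 < p_cut
  put_b <- stats_df$recurrent_centile >= 95
  put_c <- stats_df$driver_fraction > 0.5
  putative <- if (putative_any) put_a | put_b | put_c else put_a & put_b & put_c
  stats_df$category <- ifelse(qsig == 2, "Definitive",
                              ifelse(qsig == 1, "Likely",
                                     ifelse(putative, "Putative", "None")))
  stats_df
}
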