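#' GRCh37 autosomal karyotype model
#'
#' Returns the bundled genome model used throughout the package: the 22
#' autosomes of build 37 with chromosome lengths, approximate centromere
#' midpoints and acrocentric flags. The X chromosome is excluded from all
#' analyses, and on the five acrocentric autosomes (13, 14, 15, 21, 22) only
#' the long arm is scored, giving 39 scored arms in total.
#'
#' @param path Optional path to a tab-separated karyotype table with columns
#'   `chrom`, `length`, `centromere`, `acrocentric`, overriding the bundled
#'   build-37 table.
#' @return A `data.frame` with columns `chrom` (character), `length` (bp),
#'   `centromere` (bp) and `acrocentric` (logical).
#' @export
#' @examples
#' g <- tgct_genome()
#' sum(genome_arms(g)$scored)  # 39
tgct_genome <- function(path = NULL) {
  if (!is.null(path)) {
    g <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "length", "centromere", "acrocentric")
    if (!all(need %in% names(g))) {
      stop("karyotype table must have columns: ", paste(need, collapse = ", "))
    }
    g$chrom <- as.character(g$chrom)
    g$acrocentric <- as.logical(g$acrocentric)
  } else {
    g <- data.frame(
      chrom = as.character(1:22),
      length = c(
        249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
        171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
        135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
        90354753L, 81195210L, 78077248L, 59128983L, 63025520L,
        48129895L, 51304566L
      ),
      centromere = c(
        125000000L, 93300000L, 91000000L, 50400000L, 48400000L,
        61000000L, 59900000L, 45600000L, 49000000L, 40200000L,
        53700000L, 35800000L, 17900000L, 17600000L, 19000000L,
        36600000L, 24000000L, 17200000L, 26500000L, 27500000L,
        13200000L, 14700000L
      ),
      acrocentric = as.character(1:22) %in% c("13", "14", "15", "21", "22"),
      stringsAsFactors = FALSE
    )
  }
  if (any(g$centromere <= 1 | g$centromere >= g$length)) {
    stop("centromere must lie strictly inside the chromosome")
  }
  g
}

#' Chromosome arm table
#'
#' Expands a genome model into per-arm intervals. Every autosome contributes a
#' p and a q arm; arms are flagged `scored` following the 39-arm aneuploidy
#' convention (p arms of acrocentric chromosomes are not scored).
#'
#' @param genome A genome model from [tgct_genome()].
#' @return `data.frame` with columns `chrom`, `arm` ("p"/"q"), `arm_name`
#'   (e.g. "12p"), `start`, `end` (1-based inclusive) and `scored` (logical).
#' @export
genome_arms <- function(genome = tgct_genome()) {
  p <- data.frame(
    chrom = genome$chrom, arm = "p",
    arm_name = paste0(genome$chrom, "p"),
    start = 1, end = genome$centromere,
    scored = !genome$acrocentric,
    stringsAsFactors = FALSE
  )
  q <- data.frame(
    chrom = genome$chrom, arm = "q",
    arm_name = paste0(genome$chrom, "q"),
    start = genome$centromere + 1, end = genome$length,
    scored = TRUE,
    stringsAsFactors = FALSE
  )
  arms <- rbind(p, q)
  arms[order(match(arms$chrom, genome$chrom), arms$arm), , drop = FALSE]
}

#' Evaluate code under a private RNG stream
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded computations neither disturb nor depend on the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
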