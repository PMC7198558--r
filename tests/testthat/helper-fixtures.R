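# Shared fixtures built in code.

# A minimal two-chromosome genome for fast feature tests.
toy_genome <- function() {
  data.frame(
    chrom = c("1", "2"),
    length = c(2e8, 1.5e8),
    centromere = c(1e8, 5e7),
    acrocentric = c(FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Profile from a compact segment description: list of c(chrom, start, end, total).
toy_profile <- function(rows, purity = 1, ploidy = 2, sample = "s1") {
  segs <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = as.character(r[[1]]), start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), major = NA_real_, minor = 0,
               total = as.numeric(r[[4]]), stringsAsFactors = FALSE)
  }))
  segs$minor <- pmin(floor(segs$total / 2), 1)
  segs$major <- segs$total - segs$minor
  cn_profile(sample, segs, purity = purity, ploidy = ploidy)
}

# Whole-genome flat profile at a given copy number.
flat_profile <- function(total, genome = tgct_genome(), ploidy = total,
                         purity = 1, sample = "flat") {
  segs <- data.frame(chrom = genome$chrom, start = 1, end = genome$length,
                     total = total, stringsAsFactors = FALSE)
  segs$minor <- floor(segs$total / 2)
  segs$major <- segs$total - segs$minor
  cn_profile(sample, segs, purity = purity, ploidy = ploidy)
}

# A well-formed variant-call row; override fields as needed.
make_call <- function(...) {
  base <- data.frame(
    chrom = "1", pos = 1000L, ref = "C", alt = "T", class = "SNV",
    consequence = "nonsynonymous", gene = "GENE0001", alt_reads = 10L,
    depth = 100L, vaf = 0.10, alt_fwd = 5L, alt_rev = 5L, base_qual = 33,
    map_qual = 58, callers = "strelka,mutect", oncokb_driver = FALSE,
    cosmic_count = 0L, hotspot = FALSE, sample = "s1", case = "c1",
    dataset = "A", stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

make_calls <- function(...) {
  do.call(rbind, list(...))
}

# Brute-force oscillating-chain oracle: enumerate all maximal alternating
# subintervals of length >= 3.
oscillation_oracle <- function(states) {
  n <- length(states)
  lens <- numeric(0)
  if (n < 3) return(lens)
  is_alt <- function(i, j) {
    if (j - i + 1 < 3) return(FALSE)
    idx <- i:j
    all(states[idx[-1]] != states[idx[-length(idx)]]) &&
      all(states[idx[-(1:2)]] == states[idx[seq_len(length(idx) - 2)]])
  }
  for (i in 1:(n - 2)) {
    for (j in (i + 2):n) {
      if (is_alt(i, j) &&
          (i == 1 || !is_alt(i - 1, j)) &&
          (j == n || !is_alt(i, j + 1))) {
        lens <- c(lens, j - i + 1)
      }
    }
  }
  sort(lens)
}

# Exhaustive BFS oracle for directed minimum-event distances over allele
# profiles of a given length with copy numbers 0..cap. Operations: choose a
# contiguous run with all copies >= 1 and add or subtract 1 (cap respected);
# a position at 0 blocks any operation spanning it. Returns the full
# distance matrix (Inf where unreachable) over all (cap+1)^len states,
# indexed by encode_state().
bfs_distance_matrix <- function(len, cap = 4) {
  requireNamespace("Matrix", quietly = TRUE)
  n_states <- (cap + 1)^len
  encode <- function(v) sum(v * (cap + 1)^(seq_along(v) - 1)) + 1
  # row idx satisfies encode(states[idx, ]) == idx
  states <- do.call(rbind, lapply(seq_len(n_states), function(idx) {
    v <- integer(len); x <- idx - 1
    for (p in seq_len(len)) {
      v[p] <- x %% (cap + 1)
      x <- x %/% (cap + 1)
    }
    v
  }))
  edges <- vector("list", 2 * len^2)
  k <- 0
  for (i in seq_len(len)) {
    for (j in i:len) {
      run_ok <- rowSums(states[, i:j, drop = FALSE] == 0) == 0
      delta <- sum((cap + 1)^((i:j) - 1))
      up_ok <- run_ok & rowSums(states[, i:j, drop = FALSE] == cap) == 0
      k <- k + 1
      edges[[k]] <- cbind(which(up_ok), which(up_ok) + delta)
      k <- k + 1
      edges[[k]] <- cbind(which(run_ok), which(run_ok) - delta)
    }
  }
  e <- do.call(rbind, edges[seq_len(k)])
  adj <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                              dims = c(n_states, n_states))
  d <- matrix(Inf, n_states, n_states)
  diag(d) <- 0
  reached <- diag(n_states)
  step <- 0
  repeat {
    step <- step + 1
    nxt <- as.matrix(reached %*% adj > 0) & !(reached > 0)
    if (!any(nxt)) break
    d[nxt] <- step
    reached <- reached + nxt
  }
  list(d = d, encode = encode, states = states)
}

# Vectorised closed-form directed distances from every profile to target b:
# mirrors allele_event_distance over a whole profile matrix at once.
closed_form_to_target <- function(states, b) {
  dmat <- sweep(-states, 2, b, `+`)  # b - a per row
  p <- pmax(dmat, 0)
  n <- pmax(-dmat, 0)
  inc <- function(m) {
    prev <- cbind(0, m[, -ncol(m), drop = FALSE])
    rowSums(pmax(m - prev, 0))
  }
  out <- inc(p) + inc(n)
  bad <- rowSums(states == 0 & matrix(b, nrow(states), length(b),
                                      byrow = TRUE) > 0) > 0
  out[bad] <- Inf
  out
}

# Wrap an integer allele vector as a single-chromosome cn_profile (the allele
# under test is carried on "major"; "minor" kept constant zero).
allele_profile <- function(v, sample = "p") {
  n <- length(v)
  segs <- data.frame(chrom = "1", start = seq(1, by = 100, length.out = n),
                     end = seq(100, by = 100, length.out = n),
                     major = v, minor = 0, total = v, stringsAsFactors = FALSE)
  cn_profile(sample, segs, purity = 1, ploidy = 2)
}
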