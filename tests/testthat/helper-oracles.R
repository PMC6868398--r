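# Independent brute-force oracles used across the suite. These enumerate base
# positions (or draws) directly and never call the implementation paths they
# check.

# set of covered bases of one interval, as "chrom:pos" tokens
bp_set <- function(chrom, start, end) {
  if (end <= start) return(character(0))
  paste(chrom, start:(end - 1L))
}

oracle_overlaps <- function(a, b) {
  length(intersect(bp_set(a$chrom, a$start, a$end),
                   bp_set(b$chrom, b$start, b$end))) > 0L
}

oracle_intersect_width <- function(a, b) {
  length(intersect(bp_set(a$chrom, a$start, a$end),
                   bp_set(b$chrom, b$start, b$end)))
}

# does interval iv overlap any interval in set (data frame)?
oracle_overlaps_any <- function(iv, set) {
  if (nrow(set) == 0L) return(FALSE)
  bases <- bp_set(iv$chrom, iv$start, iv$end)
  for (j in seq_len(nrow(set))) {
    if (length(intersect(bases, bp_set(set$chrom[j], set$start[j], set$end[j]))))
      return(TRUE)
  }
  FALSE
}

random_intervals <- function(n, chroms = c("chrI", "chrII"), max_coord = 10000L,
                             max_width = 400L) {
  start <- sample.int(max_coord - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), start, start + width)
}

# per-base coverage vector rebuilt independently from reads (single chrom)
oracle_base_coverage <- function(reads, L) {
  cov <- integer(L)
  for (i in seq_len(nrow(reads))) {
    s <- max(reads$start[i], 0L) + 1L
    e <- min(reads$end[i], L)
    if (e >= s) cov[s:e] <- cov[s:e] + 1L
  }
  cov
}

# one-line independent notch oracle
oracle_notch <- function(v)
  stats::median(v) + c(-1, 1) * 1.58 *
    diff(stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)) /
    sqrt(length(v))
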