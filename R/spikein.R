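#' Resolve genome of origin from chromosome names
#'
#' Dual-genome alignments carry both species in one reference; the species is
#' recovered from the chromosome name by prefix. `genome_map` is a named
#' character vector mapping prefix to genome label, e.g.
#' `c(ce = "target", cb = "spike")`. A chromosome matching no prefix is a
#' hard error. Longer prefixes win when several match.
#'
#' @param chrom character vector of chromosome names
#' @param genome_map named character vector, prefix -> genome label
#' @return character vector of genome labels
#' @export
genome_of <- function(chrom, genome_map) {
  prefixes <- names(genome_map)
  prefixes <- prefixes[order(nchar(prefixes), decreasing = TRUE)]
  out <- rep(NA_character_, length(chrom))
  for (p in prefixes) {
    hit <- is.na(out) & startsWith(chrom, p)
    out[hit] <- genome_map[[p]]
  }
  if (anyNA(out))
    stop("chromosome with no genome mapping: ", chrom[is.na(out)][1])
  out
}

#' Partition reads by genome and filter on mapq and blacklist
#'
#' Keeps reads with `mapq >= mapq_min` (inclusive threshold) that overlap no
#' blacklist interval by even a single base, then splits them by genome of
#' origin.
#'
#' @param reads data frame with `chrom`, `start`, `end`, `mapq`
#' @param mapq_min inclusive mapping-quality threshold (default 10)
#' @param blacklist interval data frame of regions to exclude (may be empty)
#' @param genome_map prefix -> genome label mapping (see [genome_of()])
#' @return list with `reads` (named list of per-genome read frames), `counts`
#'   (named integer vector of kept reads per genome), `n_dropped_mapq`,
#'   `n_dropped_blacklist`
#' @export
partition_and_filter <- function(reads, mapq_min = 10L,
                                 blacklist = gintervals(), genome_map) {
  genome <- genome_of(reads$chrom, genome_map)
  keep_q <- reads$mapq >= mapq_min
  n_mapq <- sum(!keep_q)
  reads <- reads[keep_q, , drop = FALSE]
  genome <- genome[keep_q]
  if (nrow(blacklist) && nrow(reads)) {
    in_bl <- overlaps_any(reads, blacklist)
  } else {
    in_bl <- rep(FALSE, nrow(reads))
  }
  n_bl <- sum(in_bl)
  reads <- reads[!in_bl, , drop = FALSE]
  genome <- genome[!in_bl]
  labels <- unique(unname(genome_map))
  by_genome <- lapply(labels, function(g) reads[genome == g, , drop = FALSE])
  names(by_genome) <- labels
  counts <- vapply(by_genome, nrow, integer(1))
  list(reads = by_genome, counts = counts,
       n_dropped_mapq = n_mapq, n_dropped_blacklist = n_bl)
}

#' Spike-in ratio from an input sample
#'
#' The ratio of spike-in to target chromatin in the extract, estimated from
#' the input (non-IP) library as spike-in read count divided by target read
#' count after mapq/blacklist filtering.
#'
#' @param n_spike filtered spike-in read count
#' @param n_target filtered target read count (> 0)
#' @return a `spikein_estimate`: list with `ratio`, `n_spike`, `n_target`
#' @export
spikein_ratio <- function(n_spike, n_target) {
  n_spike <- as.numeric(n_spike)
  n_target <- as.numeric(n_target)
  if (is.na(n_target) || n_target <= 0) stop("zero target reads: cannot form spike-in ratio")
  if (is.na(n_spike) || n_spike <= 0) stop("zero spike-in reads: cannot form spike-in ratio")
  structure(list(ratio = n_spike / n_target, n_spike = n_spike,
                 n_target = n_target),
            class = "spikein_estimate")
}

#' @export
print.spikein_estimate <- function(x, ...) {
  cat(sprintf("spike-in ratio r = %.6g (%d spike / %d target reads)\n",
              x$ratio, x$n_spike, x$n_target))
  invisible(x)
}

#' Count reads overlapping a peak set
#'
#' Peaks are merged first so that a read spanning two book-ended peaks is
#' counted exactly once; a read counts if it shares at least one base with
#' any merged peak.
#'
#' @param reads data frame with `chrom`, `start`, `end`
#' @param peaks interval data frame
#' @return integer count
#' @export
count_reads_in_peaks <- function(reads, peaks) {
  if (nrow(reads) == 0L || nrow(peaks) == 0L) return(0L)
  merged <- interval_merge(peaks)
  sum(overlaps_any(reads, merged))
}

#' Per-ChIP spike-in scaling factor
#'
#' `s = r / (spike-in ChIP reads in spike-in peak regions / 1e6)`: the input
#' spike-in ratio divided by the ChIP's spike-in read count inside spike-in
#' peaks, in millions of reads. Applying `s` to the target raw coverage makes
#' signal comparable across samples and genotypes.
#'
#' @param est a `spikein_estimate` from [spikein_ratio()]
#' @param chip_spike_reads_in_peaks spike-in ChIP read count in spike-in peaks
#' @return a `scaling_factor`: list with `value`, `source_ratio`,
#'   `spike_reads_in_peaks`
#' @export
scaling_factor <- function(est, chip_spike_reads_in_peaks) {
  stopifnot(inherits(est, "spikein_estimate"))
  n <- as.numeric(chip_spike_reads_in_peaks)
  if (is.na(n) || n <= 0) stop("zero spike-in ChIP reads in peaks: cannot form scaling factor")
  structure(list(value = est$ratio / (n / 1e6), source_ratio = est,
                 spike_reads_in_peaks = n),
            class = "scaling_factor")
}

#' @export
print.scaling_factor <- function(x, ...) {
  cat(sprintf("scaling factor s = %.6g (r = %.6g, %g spike ChIP reads in peaks)\n",
              x$value, x$source_ratio$ratio, x$spike_reads_in_peaks))
  invisible(x)
}

#' Spike-in normalize a ChIP sample end to end
#'
#' Convenience wrapper running the full normalization: partition/filter both
#' input and ChIP read sets, estimate the spike-in ratio from the input,
#' derive the scaling factor from spike-in ChIP reads in spike-in peaks,
#' build the target raw coverage track, scale it and subtract the mode.
#'
#' @param chip_reads,input_reads read frames (`chrom,start,end,mapq`)
#' @param spike_peaks spike-in genome peak intervals (from an external caller)
#' @param sizes_target target-genome chromosome sizes
#' @param genome_map prefix -> {"target","spike"} mapping
#' @param mapq_min inclusive mapq threshold
#' @param blacklist intervals to exclude (both genomes)
#' @param bin coverage bin width in bp
#' @return list with `track` (state `background_subtracted`), `ratio`
#'   (`spikein_estimate`), `scaling` (`scaling_factor`), `mode`, and the
#'   filtered read `counts`
#' @export
spikein_normalize <- function(chip_reads, input_reads, spike_peaks, sizes_target,
                              genome_map, mapq_min = 10L,
                              blacklist = gintervals(), bin = 10L) {
  inp <- partition_and_filter(input_reads, mapq_min, blacklist, genome_map)
  chp <- partition_and_filter(chip_reads, mapq_min, blacklist, genome_map)
  est <- spikein_ratio(inp$counts[["spike"]], inp$counts[["target"]])
  n_in_peaks <- count_reads_in_peaks(chp$reads[["spike"]], spike_peaks)
  s <- scaling_factor(est, n_in_peaks)
  raw <- track_from_reads(chp$reads[["target"]], sizes_target, bin = bin)
  track <- subtract_mode(scale_track(raw, s))
  list(track = track, ratio = est, scaling = s, mode = track$mode,
       counts = list(input = inp$counts, chip = chp$counts))
}
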