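#' Genomic intervals (0-based, half-open)
#'
#' All region arithmetic in chipcooc uses the BED convention: coordinates are
#' 0-based and intervals are half-open, `[start, end)`. A set of intervals is
#' represented as a plain data frame with character column `chrom` and integer
#' columns `start` and `end`; extra columns are carried along untouched.
#'
#' @param chrom character vector of chromosome names
#' @param start integer vector of 0-based start positions
#' @param end integer vector of exclusive end positions
#' @return a validated `data.frame` with columns `chrom`, `start`, `end`
#' @export
gintervals <- function(chrom = character(), start = integer(), end = integer()) {
  iv <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  validate_intervals(iv)
  iv
}

#' Validate an interval data frame
#'
#' Checks the interval invariants: non-empty chromosome names,
#' `0 <= start < end` (strictly positive width).
#'
#' @param iv interval data frame
#' @return `iv`, invisibly
#' @export
validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv), all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0L) return(invisible(iv))
  if (any(is.na(iv$chrom)) || any(!nzchar(iv$chrom)))
    stop("interval with empty chromosome name")
  if (any(is.na(iv$start)) || any(is.na(iv$end)))
    stop("interval with missing coordinate")
  if (any(iv$start < 0L)) stop("interval start < 0")
  if (any(iv$start >= iv$end)) stop("interval with non-positive width (start >= end)")
  invisible(iv)
}

#' Chromosome sizes
#'
#' A named integer vector mapping chromosome name to length in bp.
#'
#' @param lengths integer vector of chromosome lengths
#' @param names chromosome names (taken from `names(lengths)` if omitted)
#' @return named integer vector
#' @export
chrom_sizes <- function(lengths, names = NULL) {
  nm <- if (!is.null(names)) names else base::names(lengths)
  lengths <- as.integer(lengths)
  names(lengths) <- nm
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome sizes must be named")
  if (any(lengths <= 0L)) stop("chromosome lengths must be positive")
  lengths
}

.check_chroms <- function(iv, sizes) {
  missing <- setdiff(unique(iv$chrom), names(sizes))
  if (length(missing))
    stop("chromosome(s) not in sizes: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Pairwise interval overlap
#'
#' Two half-open intervals overlap iff they lie on the same chromosome and
#' share at least one base: `a.start < b.end && b.start < a.end`. Intervals on
#' different chromosomes never overlap. `a` and `b` are matched row by row
#' (with recycling of a single row).
#'
#' @param a,b interval data frames
#' @return logical vector
#' @export
interval_overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  stopifnot(nrow(a) == nrow(b))
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Pairwise interval intersection
#'
#' The maximal shared span of each row pair, i.e. `[max(start), min(end))`.
#' Non-overlapping pairs are dropped from the result (an all-empty result is a
#' 0-row interval frame).
#'
#' @inheritParams interval_overlaps
#' @return interval data frame of intersections (0 rows when none overlap)
#' @export
interval_intersect <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  hit <- interval_overlaps(a, b)
  gintervals(
    chrom = a$chrom[hit],
    start = pmax(a$start[hit], b$start[hit]),
    end = pmin(a$end[hit], b$end[hit])
  )
}

#' Rescale intervals to a fixed width
#'
#' Each interval is replaced by a window of exactly `width` bp centred on its
#' midpoint `floor((start + end) / 2)`. Windows that would run past a
#' chromosome boundary are shifted (never truncated) to fit, so the output
#' width is always exactly `width`. A chromosome shorter than `width` is an
#' error.
#'
#' @param iv interval data frame
#' @param width target width in bp (> 0)
#' @param sizes chromosome sizes (named integer vector)
#' @return interval data frame, same number of rows, all widths `== width`
#' @export
rescale_to_width <- function(iv, width, sizes) {
  stopifnot(width > 0)
  validate_intervals(iv)
  if (nrow(iv) == 0L) return(iv)
  .check_chroms(iv, sizes)
  len <- sizes[iv$chrom]
  short <- len < width
  if (any(short))
    stop("chromosome(s) shorter than ", width, " bp: ",
         paste(unique(iv$chrom[short]), collapse = ", "))
  mid <- (iv$start + iv$end) %/% 2L
  half <- width %/% 2L
  start <- mid - half
  start <- pmax(start, 0L)
  start <- pmin(start, len - width)
  out <- iv
  out$start <- as.integer(start)
  out$end <- as.integer(start + width)
  out
}

#' Interval width
#' @param iv interval data frame
#' @return integer vector of widths in bp
#' @export
interval_width <- function(iv) iv$end - iv$start

## -- GRanges bridge (internal): chipcooc is 0-based half-open, GRanges is
## 1-based closed; conversion happens only here.
.iv2gr <- function(iv, seqlvls = unique(iv$chrom)) {
  if (nrow(iv) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(factor(iv$chrom, levels = seqlvls),
                         IRanges::IRanges(iv$start + 1L, iv$end))
}

.gr2iv <- function(gr) {
  gintervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Merge overlapping intervals
#'
#' Collapses a set of intervals into its connected overlap components
#' (book-ended intervals, which share no base, are NOT merged).
#'
#' @param iv interval data frame
#' @return sorted interval data frame of disjoint merged spans
#' @export
interval_merge <- function(iv) {
  validate_intervals(iv)
  if (nrow(iv) == 0L) return(gintervals())
  .gr2iv(GenomicRanges::reduce(.iv2gr(iv), min.gapwidth = 0L))
}

#' Which query intervals overlap any subject interval?
#'
#' @param query,subject interval data frames
#' @return logical vector along `query`
#' @export
overlaps_any <- function(query, subject) {
  validate_intervals(query)
  validate_intervals(subject)
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  lv <- unique(c(query$chrom, subject$chrom))
  GenomicRanges::countOverlaps(.iv2gr(query, lv), .iv2gr(subject, lv)) > 0L
}

#' All overlapping query/subject row pairs
#'
#' @param query,subject interval data frames
#' @return data frame with columns `query`, `subject` (row indices)
#' @export
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(), subject = integer()))
  lv <- unique(c(query$chrom, subject$chrom))
  h <- GenomicRanges::findOverlaps(.iv2gr(query, lv), .iv2gr(subject, lv))
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

#' Sort intervals by (chrom, start, end)
#' @param iv interval data frame
#' @return sorted interval data frame
#' @export
interval_sort <- function(iv) {
  iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
}

#' Deduplicate identical intervals
#' @param iv interval data frame
#' @return interval data frame with duplicated (chrom, start, end) rows removed
#' @export
interval_unique <- function(iv) {
  key <- paste(iv$chrom, iv$start, iv$end, sep = "\r")
  iv[!duplicated(key), , drop = FALSE]
}
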