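#' Binned coverage tracks
#'
#' A `coverage_track` stores per-chromosome signal on fixed bins of `bin` bp
#' (the last bin of a chromosome may cover fewer bases). It carries a `state`
#' tag recording the normalization applied so far; operations check the state
#' they require instead of silently re-normalizing. States: `raw`, `scaled`,
#' `background_subtracted`, `zscored`, `input_normalized`.
#'
#' @param sizes named integer vector of chromosome sizes
#' @param bin bin width in bp (default 10)
#' @param state normalization state tag
#' @param values optional named list of per-chromosome numeric vectors; zeros
#'   when omitted
#' @return a `coverage_track` object
#' @export
coverage_track <- function(sizes, bin = 10L, state = "raw", values = NULL) {
  stopifnot(bin >= 1L)
  nb <- ceiling(sizes / bin)
  if (is.null(values)) {
    values <- lapply(nb, function(n) numeric(n))
  } else {
    stopifnot(identical(sort(names(values)), sort(names(sizes))))
    for (ch in names(sizes)) {
      if (length(values[[ch]]) != nb[[ch]])
        stop("bin vector length mismatch on ", ch)
    }
    values <- values[names(sizes)]
  }
  structure(list(values = values, bin = as.integer(bin), state = state,
                 sizes = sizes),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$values), "chromosome(s), bin", x$bin,
      "bp, state", x$state, "\n")
  invisible(x)
}

.track_compatible <- function(a, b) {
  identical(a$bin, b$bin) && identical(names(a$values), names(b$values)) &&
    all(lengths(a$values) == lengths(b$values))
}

.bin_widths <- function(track, chrom) {
  n <- length(track$values[[chrom]])
  w <- rep(track$bin, n)
  w[n] <- track$sizes[[chrom]] - (n - 1L) * track$bin
  w
}

.bin_means_from_base <- function(basevec, bin) {
  L <- length(basevec)
  nb <- ceiling(L / bin)
  pad <- nb * bin - L
  if (pad > 0L) basevec <- c(basevec, rep(NA_real_, pad))
  colMeans(matrix(basevec, nrow = bin), na.rm = TRUE)
}

#' Read a bedGraph file onto fixed bins
#'
#' Records are resampled to `bin`-bp bins by length-weighted mean; bases not
#' covered by any record count as 0. Overlapping records and records running
#' past the chromosome end are hard errors.
#'
#' @param path 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' @param sizes chromosome sizes
#' @param bin bin width in bp
#' @return a `coverage_track` in state `raw`
#' @export
read_bedgraph <- function(path, sizes, bin = 10L) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "value")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        data.frame(chrom = character(), start = integer(), end = integer(),
                   value = numeric())
      else stop(e)
    })
  values <- list()
  for (ch in names(sizes)) {
    L <- sizes[[ch]]
    rec <- tab[tab$chrom == ch, , drop = FALSE]
    base <- numeric(L)
    if (nrow(rec)) {
      rec <- rec[order(rec$start), , drop = FALSE]
      if (any(rec$end > L))
        stop("bedGraph record beyond chromosome length on ", ch)
      if (any(rec$start < 0) || any(rec$start >= rec$end))
        stop("invalid bedGraph record on ", ch)
      if (nrow(rec) > 1L && any(rec$start[-1L] < rec$end[-nrow(rec)]))
        stop("overlapping bedGraph records on ", ch)
      base[sequence(rec$end - rec$start, from = rec$start + 1L)] <-
        rep(rec$value, rec$end - rec$start)
    }
    values[[ch]] <- .bin_means_from_base(base, bin)
  }
  unknown <- setdiff(unique(tab$chrom), names(sizes))
  if (length(unknown))
    stop("bedGraph chromosome(s) not in sizes: ", paste(unknown, collapse = ", "))
  coverage_track(sizes, bin = bin, state = "raw", values = values)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are collapsed into one record; zero-valued runs
#' are omitted.
#'
#' @param track a `coverage_track`
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths) * track$bin
    starts <- c(0L, ends[-length(ends)])
    ends <- pmin(ends, track$sizes[[ch]])
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                       format(r$values[keep], digits = 10, trim = TRUE,
                              scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Binned coverage from aligned reads
#'
#' Per-base read depth, averaged within bins. Reads are clipped to the
#' chromosome; reads on chromosomes absent from `sizes` are an error.
#'
#' @param reads data frame with `chrom`, `start`, `end`
#' @param sizes chromosome sizes
#' @param bin bin width in bp
#' @return a `coverage_track` in state `raw`
#' @export
track_from_reads <- function(reads, sizes, bin = 10L) {
  .check_chroms(reads, sizes)
  values <- list()
  for (ch in names(sizes)) {
    L <- sizes[[ch]]
    r <- reads[reads$chrom == ch, , drop = FALSE]
    if (nrow(r)) {
      s <- pmax(r$start, 0L)
      e <- pmin(r$end, L)
      d <- tabulate(s + 1L, nbins = L + 1L) - tabulate(e + 1L, nbins = L + 1L)
      base <- cumsum(d)[seq_len(L)]
    } else {
      base <- numeric(L)
    }
    values[[ch]] <- .bin_means_from_base(base, bin)
  }
  coverage_track(sizes, bin = bin, state = "raw", values = values)
}

#' Multiply a raw track by a scaling factor
#'
#' @param track a `coverage_track` in state `raw`
#' @param s a `scaling_factor` (see [scaling_factor()]) or a positive number
#' @return the scaled track, state `scaled`
#' @export
scale_track <- function(track, s) {
  if (track$state != "raw")
    stop("scale_track expects a raw track, got state ", track$state)
  sval <- if (inherits(s, "scaling_factor")) s$value else as.numeric(s)
  stopifnot(sval > 0)
  track$values <- lapply(track$values, function(v) v * sval)
  track$state <- "scaled"
  track$scaling <- sval
  track
}

#' Estimate the mode of a numeric sample
#'
#' For effectively discrete samples (zero interquartile range or few unique
#' values) the most frequent value is returned, ties broken toward the
#' smallest. Otherwise a histogram with Freedman-Diaconis bin width is built
#' over the value range and the midpoint of the tallest bin is returned, ties
#' broken toward the lower bin.
#'
#' @param v numeric vector
#' @return scalar mode estimate
#' @export
estimate_mode <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(0)
  rng <- range(v)
  if (diff(rng) == 0) return(v[1])
  h <- 2 * stats::IQR(v, type = 7) * length(v)^(-1 / 3)
  ux <- sort(unique(v))
  if (h <= 0 || length(ux) <= 64L) {
    cnt <- tabulate(match(v, ux))
    return(ux[which.max(cnt)])
  }
  nb <- max(1L, ceiling(diff(rng) / h))
  idx <- pmin(floor((v - rng[1]) / h) + 1L, nb)
  cnt <- tabulate(idx, nbins = nb)
  top <- which.max(cnt)
  rng[1] + (top - 0.5) * h
}

#' Remove background by mode subtraction
#'
#' Estimates the mode of the genome-wide binned value distribution, subtracts
#' it from every bin and clamps negatives to zero. The estimated mode is
#' attached as attribute `mode` for the run log.
#'
#' @param track a `coverage_track` in state `scaled`
#' @return the background-subtracted track, state `background_subtracted`
#' @export
subtract_mode <- function(track) {
  if (track$state != "scaled")
    stop("subtract_mode expects a scaled track, got state ", track$state)
  all_v <- unlist(track$values, use.names = FALSE)
  if (all(all_v == 0)) {
    warning("all-zero track: mode subtraction is a no-op")
    m <- 0
  } else {
    m <- estimate_mode(all_v)
    track$values <- lapply(track$values, function(v) pmax(v - m, 0))
  }
  track$state <- "background_subtracted"
  track$mode <- m
  track
}

#' Z-score a track genome-wide
#'
#' `(value - mean) / sd` with mean and population (divisor n) standard
#' deviation over all bins of all chromosomes.
#'
#' @param track a `coverage_track` (any state)
#' @return the z-scored track, state `zscored`
#' @export
zscore_track <- function(track) {
  all_v <- unlist(track$values, use.names = FALSE)
  mu <- mean(all_v)
  sd_pop <- sqrt(mean((all_v - mu)^2))
  if (sd_pop == 0) stop("cannot z-score a zero-variance track")
  track$values <- lapply(track$values, function(v) (v - mu) / sd_pop)
  track$state <- "zscored"
  track
}

#' Input-normalize a ChIP track (log2 ratio)
#'
#' A documented stand-in for external input-normalization pipelines: both
#' tracks are scaled to equal total mass, then the per-bin
#' `log2((chip + pseudocount) / (input + pseudocount))` is taken.
#'
#' @param chip,input `coverage_track`s with identical binning and chromosomes
#' @param pseudocount added to both numerator and denominator (default 1)
#' @return log2-ratio track, state `input_normalized`
#' @export
input_normalize <- function(chip, input, pseudocount = 1) {
  if (!.track_compatible(chip, input))
    stop("chip and input tracks differ in binning or chromosomes")
  m_chip <- sum(unlist(chip$values))
  m_input <- sum(unlist(input$values))
  if (m_chip <= 0 || m_input <= 0) stop("cannot mass-match a zero-mass track")
  f <- m_chip / m_input
  out <- chip
  out$values <- Map(function(c_v, i_v) log2((c_v + pseudocount) /
                                            (i_v * f + pseudocount)),
                    chip$values, input$values)
  out$state <- "input_normalized"
  out
}

#' Per-region mean signal
#'
#' Mean per-base signal of each region, looked up from the binned track
#' (each base takes the value of its bin).
#'
#' @param track a `coverage_track`
#' @param regions interval data frame
#' @return numeric vector of per-region means
#' @export
region_means <- function(track, regions) {
  validate_intervals(regions)
  if (nrow(regions) == 0L) return(numeric(0))
  .check_chroms(regions, track$sizes)
  bin <- track$bin
  vapply(seq_len(nrow(regions)), function(i) {
    v <- track$values[[regions$chrom[i]]]
    pos <- regions$start[i]:(regions$end[i] - 1L)
    pos <- pos[pos >= 0L & pos < track$sizes[[regions$chrom[i]]]]
    mean(v[pos %/% bin + 1L])
  }, numeric(1))
}
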