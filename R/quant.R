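#' Region-by-bin signal matrix
#'
#' Binned signal per region over a window centred on the region midpoint and
#' spanning `region half-width + flank` on each side (for 300 bp regions with
#' `flank = 0` this is the region itself). Columns are `bin`-bp wide; bases
#' outside the chromosome contribute 0 and the affected rows are listed in
#' attribute `clipped`.
#'
#' @param track a `coverage_track`
#' @param regions interval data frame of fixed-width regions
#' @param flank extra bp on each side of the region (multiple of `bin`)
#' @param bin column width in bp (defaults to the track's bin)
#' @return numeric matrix, one row per region, with attributes `flank`,
#'   `bin` and `clipped`
#' @export
region_matrix <- function(track, regions, flank = 0L, bin = track$bin) {
  validate_intervals(regions)
  widths <- unique(interval_width(regions))
  if (length(widths) > 1L) stop("regions must share a fixed width")
  if (flank %% bin != 0L) stop("flank must be a multiple of bin")
  .check_chroms(regions, track$sizes)
  half <- widths %/% 2L + flank
  ncol_out <- (2L * half) %/% bin
  n <- nrow(regions)
  out <- matrix(0, nrow = n, ncol = ncol_out)
  clipped <- logical(n)
  tb <- track$bin
  for (i in seq_len(n)) {
    mid <- (regions$start[i] + regions$end[i]) %/% 2L
    pos <- (mid - half):(mid + half - 1L)
    L <- track$sizes[[regions$chrom[i]]]
    inside <- pos >= 0L & pos < L
    clipped[i] <- !all(inside)
    base <- numeric(length(pos))
    v <- track$values[[regions$chrom[i]]]
    base[inside] <- v[pos[inside] %/% tb + 1L]
    out[i, ] <- .bin_means_from_base(base, bin)
  }
  attr(out, "flank") <- flank
  attr(out, "bin") <- bin
  attr(out, "clipped") <- which(clipped)
  out
}

#' Classify regions into strong and weak targets by k-means
#'
#' Each track contributes one feature per region (the row mean of its signal
#' matrix); features are standardized and clustered with k-means (k = 2).
#' The cluster whose centroid is higher on the ranking track (H3K4me3 by
#' convention) is labelled `strong`, the other `weak`; a tie is broken by the
#' first remaining track's centroid. Deterministic for a given seed.
#'
#' @param matrices named list of region signal matrices (same region order)
#' @param rank_track name of the matrix whose centroid ranks the clusters
#'   (default `"H3K4me3"`, falling back to the last matrix if absent)
#' @param seed RNG seed for k-means initialization (default 13)
#' @param n_init number of random starts (default 10)
#' @param max_iter k-means iteration cap (default 100)
#' @return a `compass_classification`: list with `labels` (factor
#'   strong/weak per region), `centroids` (k x tracks, standardized units),
#'   `features`, `seed`
#' @export
kmeans_strong_weak <- function(matrices, rank_track = "H3K4me3", seed = 13L,
                               n_init = 10L, max_iter = 100L) {
  stopifnot(is.list(matrices), length(matrices) >= 1L, !is.null(names(matrices)))
  nr <- unique(vapply(matrices, nrow, integer(1)))
  if (length(nr) != 1L) stop("matrices must share the same region order")
  if (nr < 2L) stop("need at least 2 regions to cluster")
  feats <- vapply(matrices, rowMeans, numeric(nr))
  feats <- matrix(feats, nrow = nr, dimnames = list(NULL, names(matrices)))
  sds <- apply(feats, 2, stats::sd)
  if (all(sds == 0)) stop("all regions have identical signal: nothing to cluster")
  z <- scale(feats[, sds > 0, drop = FALSE])
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  km <- stats::kmeans(z, centers = 2L, nstart = n_init, iter.max = max_iter)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  if (!rank_track %in% colnames(z)) rank_track <- colnames(z)[ncol(z)]
  cen <- km$centers
  r <- cen[, rank_track]
  if (r[1] == r[2]) {
    alt <- setdiff(colnames(cen), rank_track)
    if (length(alt)) r <- cen[, alt[1]]
  }
  strong_cluster <- which.max(r)
  labels <- factor(ifelse(km$cluster == strong_cluster, "strong", "weak"),
                   levels = c("strong", "weak"))
  structure(list(labels = labels, centroids = cen, features = feats,
                 seed = seed),
            class = "compass_classification")
}

#' @export
print.compass_classification <- function(x, ...) {
  cat("strong/weak classification:", sum(x$labels == "strong"), "strong,",
      sum(x$labels == "weak"), "weak (seed", x$seed, ")\n")
  invisible(x)
}

#' Tukey box-plot notch interval
#'
#' `median +/- 1.58 * IQR / sqrt(n)` (quartiles by linear interpolation,
#' type 7). Non-overlap of two notch intervals is the informal criterion for
#' a significant difference between medians.
#'
#' @param values numeric vector (n >= 1)
#' @return named numeric vector `c(low, high)`
#' @export
notch_interval <- function(values) {
  stopifnot(length(values) >= 1L)
  med <- stats::median(values)
  iqr <- stats::IQR(values, type = 7)
  half <- 1.58 * iqr / sqrt(length(values))
  c(low = med - half, high = med + half)
}

#' Do two notch intervals overlap?
#' @param a,b notch intervals from [notch_interval()]
#' @return logical
#' @export
notches_overlap <- function(a, b) {
  a[["low"]] <= b[["high"]] && b[["low"]] <= a[["high"]]
}

#' Quantify a track over named region sets
#'
#' For each set, the per-region mean signal plus a summary (median, type-7
#' quartiles, notch interval). Intended for z-scored or spike-in normalized
#' tracks; pass `require_state` to enforce the track state.
#'
#' @param track a `coverage_track`
#' @param region_sets named list of interval data frames
#' @param require_state optional state tag the track must carry (e.g.
#'   `"zscored"`)
#' @return named list: per set, a list with `means` (numeric vector) and
#'   `summary` (median, q1, q3, n, notch low/high); empty sets yield empty
#'   means and an all-NA summary
#' @export
quantify_sets <- function(track, region_sets, require_state = NULL) {
  stopifnot(is.list(region_sets), !is.null(names(region_sets)))
  if (!is.null(require_state) && track$state != require_state)
    stop("track state is ", track$state, ", expected ", require_state)
  lapply(region_sets, function(rg) {
    m <- region_means(track, rg)
    if (!length(m)) {
      return(list(means = numeric(0),
                  summary = c(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                              n = 0, notch_low = NA_real_, notch_high = NA_real_)))
    }
    q <- stats::quantile(m, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    nt <- notch_interval(m)
    list(means = m,
         summary = c(median = q[2], q1 = q[1], q3 = q[3], n = length(m),
                     notch_low = nt[["low"]], notch_high = nt[["high"]]))
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels, same length
#' @return numeric scalar
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
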