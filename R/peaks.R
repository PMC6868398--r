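#' Extend peak summits into fixed-width regions
#'
#' Each summit is extended `flank` bp upstream and downstream into a
#' `2 * flank` bp region (`[summit - flank, summit + flank)`), shifted to fit
#' at chromosome edges so every output region keeps the full width.
#'
#' @param peaks data frame with `chrom` and absolute 0-based `summit`
#' @param flank bp added on each side of the summit (default 150)
#' @param sizes chromosome sizes
#' @return interval data frame, one region per peak, all `2 * flank` bp wide
#' @export
extend_summits <- function(peaks, flank = 150L, sizes) {
  stopifnot(flank > 0L)
  if (nrow(peaks) == 0L) return(gintervals())
  .check_chroms(peaks, sizes)
  if (any(peaks$summit < 0L) || any(peaks$summit >= sizes[peaks$chrom]))
    stop("summit outside chromosome bounds")
  rescale_to_width(
    gintervals(peaks$chrom, peaks$summit, peaks$summit + 1L),
    width = 2L * flank, sizes = sizes
  )
}

#' Consensus regions from two replicate region sets
#'
#' Every overlapping pair contributes its intersection, which is then
#' rescaled back to `width` bp; identical results are deduplicated and the
#' output is sorted by coordinate. The operation is symmetric in its inputs.
#' Used both for replicate consensus and for consensus across independent
#' antibodies.
#'
#' @param rep_a,rep_b interval data frames (fixed-width region calls)
#' @param width output region width in bp (default 300)
#' @param sizes chromosome sizes
#' @return sorted, deduplicated interval data frame of `width`-bp regions
#' @export
consensus <- function(rep_a, rep_b, width = 300L, sizes) {
  validate_intervals(rep_a)
  validate_intervals(rep_b)
  hits <- overlap_pairs(rep_a, rep_b)
  if (nrow(hits) == 0L) return(gintervals())
  inter <- interval_intersect(rep_a[hits$query, , drop = FALSE],
                              rep_b[hits$subject, , drop = FALSE])
  out <- rescale_to_width(inter, width, sizes)
  interval_sort(interval_unique(out))
}

#' @rdname consensus
#' @param calls_ab1,calls_ab2 region calls obtained with two independent
#'   antibodies against the same factor
#' @export
antibody_consensus <- function(calls_ab1, calls_ab2, width = 300L, sizes) {
  consensus(calls_ab1, calls_ab2, width = width, sizes = sizes)
}

#' Filter regions on mappability and blacklist
#'
#' A region is discarded if it overlaps any blacklist interval, or if it
#' overlaps any bin of the mappability track whose value is below
#' `map_min_fraction` (uniquely mappable fraction < 25% by default).
#'
#' @param regions interval data frame
#' @param mappability a `coverage_track` of per-bin mappable fraction in
#'   `[0, 1]`, or `NULL` to skip the mappability test
#' @param map_min_fraction minimum mappable fraction (default 0.25)
#' @param blacklist interval data frame (may be empty)
#' @return surviving regions, original order preserved
#' @export
filter_peaks <- function(regions, mappability = NULL, map_min_fraction = 0.25,
                         blacklist = gintervals()) {
  validate_intervals(regions)
  if (nrow(regions) == 0L) return(regions)
  drop <- rep(FALSE, nrow(regions))
  if (nrow(blacklist)) drop <- drop | overlaps_any(regions, blacklist)
  if (!is.null(mappability)) {
    vals <- unlist(mappability$values, use.names = FALSE)
    if (any(vals < 0 | vals > 1))
      stop("mappability values must lie in [0, 1]")
    bin <- mappability$bin
    low <- vapply(seq_len(nrow(regions)), function(i) {
      v <- mappability$values[[regions$chrom[i]]]
      b0 <- regions$start[i] %/% bin + 1L
      b1 <- (regions$end[i] - 1L) %/% bin + 1L
      b1 <- min(b1, length(v))
      any(v[b0:b1] < map_min_fraction)
    }, logical(1))
    drop <- drop | low
  }
  regions[!drop, , drop = FALSE]
}

#' Multi-factor co-occupancy superset
#'
#' The genome-wide union of all factors' fixed-width region calls is split
#' into connected overlap components; each component is represented by one
#' region of exactly `width` bp centred on the component span (regions
#' carried by a single factor are kept). Each representative is then
#' annotated with a boolean occupancy flag per factor by overlap against that
#' factor's original calls. Sets passed in `annotate_only` contribute flags
#' but do not seed components (e.g. externally published factor peaks).
#'
#' @param named_sets named list of interval data frames, one per factor
#' @param width representative region width in bp (default 300)
#' @param sizes chromosome sizes
#' @param annotate_only named list of additional interval sets used only for
#'   flag annotation
#' @return data frame: `chrom`, `start`, `end`, one logical column per factor
#'   (building factors first, then annotation-only factors), and `n_factors`
#' @export
build_superset <- function(named_sets, width = 300L, sizes,
                           annotate_only = list()) {
  stopifnot(length(named_sets) >= 1L, !is.null(names(named_sets)))
  all_iv <- do.call(rbind, lapply(named_sets, function(x)
    x[, c("chrom", "start", "end")]))
  comp <- interval_merge(all_iv)
  if (nrow(comp) == 0L)
    return(cbind(gintervals(), n_factors = integer()))
  reg <- rescale_to_width(comp, width, sizes)
  flag_sets <- c(named_sets, annotate_only)
  flags <- vapply(flag_sets, function(s) overlaps_any(reg, s),
                  logical(nrow(reg)))
  flags <- matrix(flags, nrow = nrow(reg),
                  dimnames = list(NULL, names(flag_sets)))
  out <- cbind(reg, as.data.frame(flags, check.names = FALSE))
  out$n_factors <- rowSums(flags)
  rownames(out) <- NULL
  interval_sort(out)
}

#' Assign regions to promoters and genes
#'
#' A region overlapping an annotated promoter is assigned to that promoter's
#' gene. Otherwise the region is assigned to the nearest gene start within
#' `max_dist` bp (inclusive), distance measured from the closest region edge
#' and 0 when the start lies inside the region; ties are broken by smallest
#' distance then lexicographic gene id. Unassigned regions are returned with
#' `is_promoter = FALSE`.
#'
#' @param regions interval data frame
#' @param promoter_annotation interval data frame with a `gene_id` column, or
#'   `NULL` / empty when no promoter map is available
#' @param genes data frame with `gene_id`, `chrom`, `start` (strand-resolved
#'   5' end, 0-based), `strand`
#' @param max_dist maximum distance to a gene start in bp (default 500)
#' @return data frame: region coordinates plus `gene_id` (NA when unassigned),
#'   `is_promoter`, `distance_to_start` (signed; NA when unassigned)
#' @export
assign_promoters <- function(regions, promoter_annotation = NULL, genes,
                             max_dist = 500L) {
  validate_intervals(regions)
  n <- nrow(regions)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  if (!is.null(promoter_annotation) && nrow(promoter_annotation)) {
    stopifnot("gene_id" %in% names(promoter_annotation))
    hits <- overlap_pairs(regions, promoter_annotation)
    if (nrow(hits)) {
      hits$gene <- promoter_annotation$gene_id[hits$subject]
      hits <- hits[order(hits$query, hits$gene), , drop = FALSE]
      first <- !duplicated(hits$query)
      gene_id[hits$query[first]] <- hits$gene[first]
      dist[hits$query[first]] <- 0L
    }
  }
  todo <- which(is.na(gene_id))
  if (length(todo) && nrow(genes)) {
    g <- genes[order(genes$gene_id), , drop = FALSE]
    for (i in todo) {
      same <- g$chrom == regions$chrom[i]
      if (!any(same)) next
      gs <- g$start[same]
      ids <- g$gene_id[same]
      # signed distance from gene start to the nearest region edge (0 inside)
      clamped <- pmin(pmax(gs, regions$start[i]), regions$end[i])
      d <- gs - clamped
      ok <- abs(d) <= max_dist
      if (!any(ok)) next
      pick <- which(ok)[order(abs(d[ok]), ids[ok])][1]
      gene_id[i] <- ids[pick]
      dist[i] <- d[pick]
    }
  }
  out <- regions[, c("chrom", "start", "end")]
  out$gene_id <- gene_id
  out$is_promoter <- !is.na(gene_id)
  out$distance_to_start <- dist
  out
}
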