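#' Spectral-count enrichment filter parameters
#'
#' Defaults follow the AP-MS interactor filter: an IP spectral count of at
#' least `min_sc` with a matched control count of 0, or an IP/control ratio
#' of at least `min_ratio`, in at least one replicate. Set `min_ratio = Inf`
#' to disable the ratio branch (the stricter variant requiring control = 0).
#'
#' @param min_sc minimum IP spectral count (default 3)
#' @param min_ratio minimum IP/control ratio (default 5; `Inf` allowed)
#' @return a `filter_params` list
#' @export
filter_params <- function(min_sc = 3L, min_ratio = 5) {
  stopifnot(min_sc >= 1L, min_ratio > 0)
  structure(list(min_sc = as.integer(min_sc), min_ratio = as.numeric(min_ratio)),
            class = "filter_params")
}

.sc_matrices <- function(tab) {
  ip_cols <- grep("^ip_", names(tab), value = TRUE)
  ctl_cols <- grep("^control_", names(tab), value = TRUE)
  stopifnot(length(ip_cols) >= 1L, length(ip_cols) == length(ctl_cols))
  list(ip = as.matrix(tab[, ip_cols, drop = FALSE]),
       ctl = as.matrix(tab[, ctl_cols, drop = FALSE]))
}

#' Does a protein pass the enrichment filter?
#'
#' A protein passes if some replicate `i` has `ip[i] >= min_sc` and
#' (`control[i] == 0` or `ip[i] / control[i] >= min_ratio`). The ratio branch
#' is evaluated as `ip >= min_ratio * control` in exact integer arithmetic,
#' so `control == 0` never enters a division and an infinite `min_ratio`
#' cleanly disables the branch.
#'
#' @param sc_ip integer vector of IP spectral counts per replicate
#' @param sc_control matched control counts, same length
#' @param p a `filter_params`
#' @return logical scalar
#' @export
passes_filter <- function(sc_ip, sc_control, p = filter_params()) {
  stopifnot(length(sc_ip) == length(sc_control), length(sc_ip) >= 1L,
            all(sc_ip >= 0), all(sc_control >= 0))
  enriched <- (sc_control == 0) |
    (is.finite(p$min_ratio) & sc_ip >= p$min_ratio * sc_control)
  any(sc_ip >= p$min_sc & enriched)
}

#' Filter a spectral-count table
#'
#' Applies [passes_filter()] to every protein, preserving input order, and
#' reports the thresholds and per-branch pass counts.
#'
#' @param tab SC data frame (see [read_sc_table()])
#' @param p a `filter_params`
#' @return list with `passed` (subset of `tab`), `pass_ids` (character) and
#'   `report` (thresholds, totals, per-branch counts)
#' @export
filter_table <- function(tab, p = filter_params()) {
  if (nrow(tab) == 0L) {
    return(list(passed = tab, pass_ids = character(),
                report = list(min_sc = p$min_sc, min_ratio = p$min_ratio,
                              n_in = 0L, n_pass = 0L,
                              n_pass_zero_control = 0L, n_pass_ratio = 0L)))
  }
  m <- .sc_matrices(tab)
  sc_ok <- m$ip >= p$min_sc
  zero_branch <- sc_ok & m$ctl == 0
  ratio_branch <- sc_ok & m$ctl > 0 &
    (is.finite(p$min_ratio) & m$ip >= p$min_ratio * m$ctl)
  keep <- rowSums(zero_branch | ratio_branch) > 0L
  list(passed = tab[keep, , drop = FALSE],
       pass_ids = tab$protein_id[keep],
       report = list(min_sc = p$min_sc, min_ratio = p$min_ratio,
                     n_in = nrow(tab), n_pass = sum(keep),
                     n_pass_zero_control = sum(rowSums(zero_branch) > 0L),
                     n_pass_ratio = sum(rowSums(ratio_branch) > 0L &
                                          rowSums(zero_branch) == 0L)))
}

#' Shared and bait-specific interactors across baits
#'
#' Partitions the union of per-bait passing protein sets into the proteins
#' found with every bait and those unique to each single bait (proteins in
#' some but not all baits are reported separately).
#'
#' @param pass_sets named list (one character vector of protein ids per bait)
#' @return list with `shared` (in all baits), `unique` (named list, proteins
#'   found only with that bait), `partial` (in >1 but not all baits) and
#'   `counts`
#' @export
compare_baits <- function(pass_sets) {
  stopifnot(is.list(pass_sets), length(pass_sets) >= 2L, !is.null(names(pass_sets)))
  pass_sets <- lapply(pass_sets, unique)
  all_ids <- unique(unlist(pass_sets))
  membership <- vapply(pass_sets, function(s) all_ids %in% s,
                       logical(length(all_ids)))
  membership <- matrix(membership, nrow = length(all_ids),
                       dimnames = list(all_ids, names(pass_sets)))
  n_in <- rowSums(membership)
  shared <- all_ids[n_in == length(pass_sets)]
  uniq <- lapply(names(pass_sets), function(b)
    all_ids[membership[, b] & n_in == 1L])
  names(uniq) <- names(pass_sets)
  partial <- all_ids[n_in > 1L & n_in < length(pass_sets)]
  list(shared = shared, unique = uniq, partial = partial,
       counts = c(shared = length(shared),
                  vapply(uniq, length, integer(1)),
                  partial = length(partial), union = length(all_ids)))
}
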