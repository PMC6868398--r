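#' Expressed-gene universe from a DE table
#'
#' Genes with `baseMean` strictly above the threshold form the universe for
#' all downstream set comparisons; a gene at exactly the threshold is
#' excluded.
#'
#' @param de DE data frame (see [read_de_table()])
#' @param basemean_min expression threshold (default 10)
#' @return character vector of gene ids
#' @export
select_universe <- function(de, basemean_min = 10) {
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene_id: ", de$gene_id[duplicated(de$gene_id)][1])
  de$gene_id[de$baseMean > basemean_min]
}

#' Up- and down-regulated gene sets at an FDR threshold
#'
#' Within the universe, genes with `padj < alpha` (strict) are split by the
#' sign of the log2 fold change. Missing `padj` counts as not significant
#' (the independent-filtering convention); genes with `log2fc == 0` land in
#' neither set. Both exclusions are counted in the result.
#'
#' @param de DE data frame
#' @param universe character vector of gene ids (from [select_universe()])
#' @param alpha FDR threshold (default 0.05)
#' @return list with `up`, `down` (character vectors), `n_padj_missing`,
#'   `n_zero_lfc`
#' @export
de_sets <- function(de, universe, alpha = 0.05) {
  de <- de[de$gene_id %in% universe, , drop = FALSE]
  missing_padj <- is.na(de$padj)
  sig <- !missing_padj & de$padj < alpha
  list(up = de$gene_id[sig & de$log2fc > 0],
       down = de$gene_id[sig & de$log2fc < 0],
       n_padj_missing = sum(missing_padj),
       n_zero_lfc = sum(sig & de$log2fc == 0))
}

#' Exact hypergeometric tail by log-factorial summation
#'
#' `P(X >= k)` where `X` counts white balls in `n_draw` draws without
#' replacement from a population of size `n_pop` containing `n_white` white
#' balls. Summed term by term on the log scale.
#'
#' @param k observed overlap
#' @param n_white,n_draw,n_pop hypergeometric parameters
#' @return upper-tail probability
#' @export
hyper_upper_tail <- function(k, n_white, n_draw, n_pop) {
  stopifnot(n_pop >= 1L, n_white <= n_pop, n_draw <= n_pop, k >= 0L)
  hi <- min(n_white, n_draw)
  if (k > hi) return(0)
  i <- k:hi
  lp <- lchoose(n_white, i) + lchoose(n_pop - n_white, n_draw - i) -
    lchoose(n_pop, n_draw)
  sum(exp(lp))
}

#' Overlap significance of two gene sets
#'
#' Fisher's exact test for enrichment of the overlap between two gene sets
#' drawn from a common universe: `k = |A intersect B|` and the one-sided
#' upper hypergeometric tail `P(X >= k)` with population `|universe|`,
#' successes `|A|`, draws `|B|`. `alternative = "two.sided"` sums the
#' probabilities of all tables no more likely than the observed one.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of `universe`
#' @param universe character vector of gene ids
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @return list with `k`, `n_a`, `n_b`, `n_universe`, `expected`, `p`
#' @export
overlap_test <- function(set_a, set_b, universe, alternative = "greater") {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("gene sets must be subsets of the universe")
  k <- length(intersect(set_a, set_b))
  m <- length(set_a)
  nd <- length(set_b)
  N <- length(universe)
  p <- switch(match.arg(alternative, c("greater", "two.sided")),
    greater = hyper_upper_tail(k, m, nd, N),
    two.sided = {
      i <- max(0L, m + nd - N):min(m, nd)
      lp <- lchoose(m, i) + lchoose(N - m, nd - i) - lchoose(N, nd)
      obs <- lp[i == k]
      min(1, sum(exp(lp[lp <= obs + 1e-7])))
    })
  list(k = k, n_a = m, n_b = nd, n_universe = N,
       expected = m * nd / N, p = min(1, p))
}

#' Pairwise overlap table for several genotypes
#'
#' Runs [overlap_test()] for every genotype pair and direction, plus the
#' three-way intersection counts when exactly three genotypes are given.
#'
#' @param sets named list per genotype, each a list with `up` and `down`
#'   character vectors (as from [de_sets()])
#' @param universe character vector of gene ids
#' @return list with `pairs` (data frame: genotype pair, direction, set
#'   sizes, overlap `k`, `expected`, `p`) and `venn` (named overlap counts
#'   per direction, NULL unless three genotypes)
#' @export
de_overlap_table <- function(sets, universe) {
  gt <- names(sets)
  stopifnot(length(gt) >= 2L)
  rows <- list()
  for (dir in c("up", "down")) {
    for (i in seq_along(gt)) for (j in seq_along(gt)) {
      if (i >= j) next
      r <- overlap_test(sets[[i]][[dir]], sets[[j]][[dir]], universe)
      rows[[length(rows) + 1L]] <- data.frame(
        a = gt[i], b = gt[j], direction = dir,
        n_a = r$n_a, n_b = r$n_b, k = r$k,
        expected = r$expected, p = r$p, stringsAsFactors = FALSE)
    }
  }
  venn <- NULL
  if (length(gt) == 3L) {
    venn <- lapply(c(up = "up", down = "down"), function(dir) {
      s <- lapply(sets, `[[`, dir)
      triple <- Reduce(intersect, s)
      c(stats::setNames(vapply(s, length, integer(1)), gt),
        ab = length(intersect(s[[1]], s[[2]])),
        ac = length(intersect(s[[1]], s[[3]])),
        bc = length(intersect(s[[2]], s[[3]])),
        abc = length(triple))
    })
  }
  list(pairs = do.call(rbind, rows), venn = venn)
}
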