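sizes <- chrom_sizes(c(chrI = 100000L))

make_track <- function(values, bin = 10L, L = length(values) * bin) {
  coverage_track(chrom_sizes(c(chrI = as.integer(L))), bin = bin,
                 values = list(chrI = values))
}

test_that("region_matrix extracts centred windows with zero fill outside", {
  tr <- make_track(rep(2.5, 1000))
  regs <- gintervals("chrI", c(1000L, 5000L, 9000L), c(1300L, 5300L, 9300L))
  m <- region_matrix(tr, regs)
  expect_equal(dim(m), c(3L, 30L))
  expect_true(all(m == 2.5))

  # planted peak centred on its region -> row maximum at the central columns
  v <- rep(0.1, 1000)
  v[511:520] <- 5   # bases 5100..5199, centred on region 2's midpoint 5150
  tr2 <- make_track(v)
  m2 <- region_matrix(tr2, regs, flank = 100L)
  expect_equal(dim(m2), c(3L, 50L))
  centre <- which.max(m2[2, ])
  expect_true(centre %in% 21:30)
  # region near chromosome start is flagged when the window is clipped
  m3 <- region_matrix(tr, gintervals("chrI", 0, 300), flank = 200L)
  expect_equal(attr(m3, "clipped"), 1L)
  expect_error(region_matrix(tr, regs, flank = 15L), "multiple")
})

test_that("k-means separates planted classes and ranks by H3K4me3 centroid", {
  set.seed(413)
  n <- 200
  strong <- rep(c(TRUE, FALSE), each = n / 2)
  feat <- function(mu_s, mu_w, sd) ifelse(strong, mu_s, mu_w) + stats::rnorm(n, 0, sd)
  mats <- list("CFP-1" = matrix(feat(8, 2, 0.6), ncol = 1),
               "H3K4me3" = matrix(feat(10, 2, 0.8), ncol = 1))
  km <- kmeans_strong_weak(mats, seed = 13)
  expect_equal(adjusted_rand_index(km$labels, strong), 1.0)
  expect_true(all((km$labels == "strong") == strong))

  # label assignment invariant under row permutation
  perm <- sample.int(n)
  mats_p <- lapply(mats, function(m) m[perm, , drop = FALSE])
  km_p <- kmeans_strong_weak(mats_p, seed = 13)
  expect_equal(as.character(km_p$labels), as.character(km$labels)[perm])

  # degenerate input: identical regions cannot be clustered
  flat <- list("H3K4me3" = matrix(1, nrow = 10, ncol = 3))
  expect_error(kmeans_strong_weak(flat), "identical")
  expect_error(kmeans_strong_weak(lapply(mats, function(m) m[1, , drop = FALSE])),
               "2 regions")
})

test_that("notch_interval matches the Tukey definition", {
  got <- notch_interval(1:9)
  expect_equal(unname(got), oracle_notch(1:9))
  expect_equal(unname(got), c(5 - 1.58 * 4 / 3, 5 + 1.58 * 4 / 3))
  expect_equal(unname(notch_interval(rep(3.3, 10))), c(3.3, 3.3))
  # quadrupling n halves the width (same quartiles by replication)
  w1 <- diff(notch_interval(rep(1:9, 4)))
  w4 <- diff(notch_interval(rep(1:9, 16)))
  expect_equal(unname(w4 / w1), 0.5, tolerance = 1e-12)
  expect_true(notches_overlap(c(low = 0, high = 2), c(low = 1, high = 3)))
  expect_false(notches_overlap(c(low = 0, high = 1), c(low = 2, high = 3)))
})

test_that("quantify_sets summarises per-region means", {
  tr <- zscore_track(make_track(c(rep(0, 500), rep(4, 500))))
  sets <- list(low = gintervals("chrI", c(100L, 600L), c(400L, 900L)),
               hi = gintervals("chrI", 6000L, 6300L),
               empty = gintervals())
  q <- quantify_sets(tr, sets, require_state = "zscored")
  expect_equal(length(q$low$means), 2L)
  expect_equal(unname(q$hi$summary["median"]), q$hi$means)  # singleton set
  expect_equal(unname(q$empty$summary["n"]), 0)
  expect_error(quantify_sets(make_track(1:4), sets, require_state = "zscored"),
               "state")

  # per-region means match direct per-base averaging
  set.seed(414)
  v <- stats::runif(1000)
  tr2 <- make_track(v)
  regs <- gintervals("chrI", c(123L, 4567L), c(423L, 4867L))
  got <- region_means(tr2, regs)
  per_base <- rep(v, each = 10)
  want <- vapply(seq_len(2), function(i)
    mean(per_base[(regs$start[i] + 1L):regs$end[i]]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("constant track gives constant means and zero-width notches", {
  tr <- make_track(rep(1.7, 100))
  q <- quantify_sets(tr, list(s = gintervals("chrI", c(10L, 300L), c(210L, 500L))))
  expect_equal(q$s$means, c(1.7, 1.7))
  expect_equal(unname(q$s$summary["notch_low"]), 1.7)
  expect_equal(unname(q$s$summary["notch_high"]), 1.7)
})

test_that("adjusted_rand_index behaves at its anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  set.seed(415)
  a <- sample(1:2, 2000, TRUE)
  b <- sample(1:2, 2000, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
})
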