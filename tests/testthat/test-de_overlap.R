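test_that("universe selection is strictly greater than the threshold", {
  de <- data.frame(gene_id = c("a", "b", "c"), baseMean = c(10.0, 10.01, 3),
                   log2fc = 0, padj = 1)
  expect_equal(select_universe(de), "b")
  expect_equal(length(select_universe(de[0, ])), 0L)
  expect_error(select_universe(rbind(de, de[1, ])), "duplicate")
})

test_that("de_sets splits by sign at strict FDR, treating NA as not significant", {
  de <- data.frame(gene_id = letters[1:6],
                   baseMean = 100,
                   log2fc = c(1.2, -2, 0.5, 0, 3, -1),
                   padj = c(0.049, 0.01, 0.05, 0.01, NA, 0.2))
  u <- select_universe(de)
  s <- de_sets(de, u)
  expect_setequal(s$up, "a")
  expect_setequal(s$down, "b")
  expect_equal(s$n_padj_missing, 1L)
  expect_equal(s$n_zero_lfc, 1L)
})

test_that("hypergeometric tail matches enumeration, phyper and Monte Carlo", {
  # |universe|=10, |A|=|B|=5, k=5: exactly one of C(10,5) draws overlaps fully
  r <- overlap_test(letters[1:5], letters[1:5], letters[1:10])
  draws <- utils::combn(10, 5)
  brute <- mean(apply(draws, 2, function(d) length(intersect(d, 1:5)) >= 5))
  expect_equal(r$p, 1 / choose(10, 5))
  expect_equal(r$p, brute)

  set.seed(418)
  for (i in 1:25) {
    N <- sample(10:40, 1)
    m <- sample(1:N, 1)
    nd <- sample(1:N, 1)
    k <- sample(0:min(m, nd), 1)
    expect_equal(hyper_upper_tail(k, m, nd, N),
                 stats::phyper(k - 1, m, N - m, nd, lower.tail = FALSE),
                 tolerance = 1e-12)
    # symmetry in the roles of A and B
    expect_equal(hyper_upper_tail(k, m, nd, N), hyper_upper_tail(k, nd, m, N),
                 tolerance = 1e-12)
  }

  # resampling oracle on one small instance
  set.seed(419)
  u <- sprintf("g%03d", 1:40)
  A <- u[1:12]
  B <- u[5:18]
  r2 <- overlap_test(A, B, u)
  mc <- replicate(20000, length(intersect(sample(u, 12), B)) >= r2$k)
  se <- sqrt(mean(mc) * (1 - mean(mc)) / 20000)
  expect_lt(abs(r2$p - mean(mc)), 3 * se + 1e-9)
})

test_that("overlap p is monotone in k and handles forced overlap", {
  u <- sprintf("g%03d", 1:100)
  full <- overlap_test(u, u, u)
  expect_equal(full$k, 100L)
  expect_equal(full$p, 1.0)
  ps <- vapply(0:20, hyper_upper_tail, numeric(1), n_white = 20, n_draw = 20,
               n_pop = 100)
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(overlap_test("a", "a", character(0)), "universe")
  expect_error(overlap_test("zz", character(0), u), "subsets")
})

test_that("two-sided option sums tables no more likely than observed", {
  u <- sprintf("g%02d", 1:30)
  A <- u[1:10]
  B <- u[c(1:6, 15:18)]
  got <- overlap_test(A, B, u, alternative = "two.sided")
  # cross-check against the standard Fisher implementation
  k <- length(intersect(A, B))
  tab <- matrix(c(k, length(A) - k, length(B) - k,
                  30 - length(A) - length(B) + k), 2)
  expect_equal(got$p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
})

test_that("planted DE overlap structure is recovered exactly", {
  ov <- list(up = c(abc = 50, ab = 25, ac = 15, bc = 10),
             down = c(abc = 30, ab = 10, ac = 20, bc = 5))
  sim <- simulate_de_tables(31, overlap = ov)
  des <- sim$tables
  universe <- Reduce(intersect, lapply(des, select_universe))
  sets <- lapply(des, de_sets, universe = universe)
  tabs <- de_overlap_table(sets, universe)
  expect_equal(unname(tabs$venn$up["abc"]), 50)
  expect_equal(unname(tabs$venn$up["ab"]), 75)   # abc + pairwise-only
  expect_equal(unname(tabs$venn$down["ac"]), 50)
  expect_equal(unname(tabs$venn$down[1]), 180)   # per-genotype set size
  # overlap p decreases as the planted shared fraction grows
  null_sim <- simulate_de_tables(31, overlap = NULL)
  null_sets <- lapply(null_sim$tables, de_sets,
                      universe = Reduce(intersect, lapply(null_sim$tables,
                                                          select_universe)))
  p_planted <- tabs$pairs$p[tabs$pairs$a == "cfp-1" & tabs$pairs$b == "set-2" &
                              tabs$pairs$direction == "up"]
  null_tabs <- de_overlap_table(null_sets, Reduce(intersect,
                                                  lapply(null_sim$tables,
                                                         select_universe)))
  p_null <- null_tabs$pairs$p[null_tabs$pairs$a == "cfp-1" &
                                null_tabs$pairs$b == "set-2" &
                                null_tabs$pairs$direction == "up"]
  expect_lt(p_planted, 1e-10)
  expect_gt(p_null, 1e-6)
})
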