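sizes <- chrom_sizes(c(chrI = 100000L, chrII = 80000L))

test_that("extend_summits builds 300 bp regions, shifting at edges", {
  pk <- data.frame(chrom = c("chrI", "chrI", "chrII"),
                   summit = c(1000L, 50L, 79990L))
  out <- extend_summits(pk, flank = 150L, sizes = sizes)
  expect_equal(nrow(out), 3L)
  expect_true(all(interval_width(out) == 300L))
  expect_equal(out[1, ], gintervals("chrI", 850, 1150), ignore_attr = TRUE)
  expect_equal(out[2, ], gintervals("chrI", 0, 300), ignore_attr = TRUE)
  expect_equal(out[3, ], gintervals("chrII", 79700, 80000), ignore_attr = TRUE)
  expect_error(extend_summits(data.frame(chrom = "chrI", summit = 100001L),
                              sizes = sizes), "bounds")
})

test_that("consensus intersects, rescales, deduplicates and is symmetric", {
  a <- gintervals("chrI", 850, 1150)
  b <- gintervals("chrI", 1000, 1300)
  got <- consensus(a, b, width = 300L, sizes = sizes)
  expect_equal(got, gintervals("chrI", 925, 1225), ignore_attr = TRUE)

  set.seed(410)
  ra <- random_intervals(200, max_coord = 50000L, max_width = 300L)
  rb <- random_intervals(200, max_coord = 50000L, max_width = 300L)
  expect_equal(consensus(ra, rb, sizes = sizes), consensus(rb, ra, sizes = sizes),
               ignore_attr = TRUE)
  # identical inputs reproduce themselves when the set is internally disjoint
  sp <- rescale_to_width(gintervals("chrI", seq(1000L, 20000L, by = 1000L),
                                    seq(1000L, 20000L, by = 1000L) + 1L),
                         300L, sizes)
  expect_equal(consensus(sp, sp, sizes = sizes), interval_sort(sp),
               ignore_attr = TRUE)
  expect_equal(nrow(consensus(gintervals("chrI", 0, 300),
                              gintervals("chrI", 5000, 5300), sizes = sizes)), 0L)
  expect_equal(nrow(antibody_consensus(ra, gintervals(), sizes = sizes)), 0L)
})

test_that("chained replicate+antibody consensus keeps only four-way supported sites", {
  # sites at fixed positions; each input carries a subset
  s_all <- c(1000L, 5000L, 9000L, 13000L)
  reg <- function(sm) rescale_to_width(gintervals("chrI", sm, sm + 1L), 300L, sizes)
  a1 <- reg(s_all)                 # antibody 1, rep 1: all sites
  a2 <- reg(s_all[c(1, 2, 4)])     # rep 2 misses site 3
  b1 <- reg(s_all[c(1, 2, 3)])     # antibody 2, rep 1 misses site 4
  b2 <- reg(s_all)
  chained <- antibody_consensus(consensus(a1, a2, sizes = sizes),
                                consensus(b1, b2, sizes = sizes), sizes = sizes)
  expect_equal(chained, reg(s_all[c(1, 2)]), ignore_attr = TRUE)
})

test_that("filter_peaks drops blacklist and low-mappability regions", {
  mp <- coverage_track(chrom_sizes(c(chrI = 100L)), bin = 50L,
                       values = list(chrI = c(1.0, 0.2)))
  regions <- gintervals(c("chrI", "chrI"), c(0, 40), c(40, 90))
  out <- filter_peaks(regions, mappability = mp)
  expect_equal(out, regions[1, ], ignore_attr = TRUE)

  bl <- gintervals("chrI", 35, 45)
  expect_equal(nrow(filter_peaks(regions, blacklist = bl)), 0L)
  expect_equal(nrow(filter_peaks(regions)), 2L)

  # raising the threshold never increases survivors
  set.seed(411)
  mp2 <- coverage_track(chrom_sizes(c(chrI = 10000L)), bin = 100L,
                        values = list(chrI = stats::runif(100)))
  regs <- random_intervals(100, chroms = "chrI", max_coord = 10000L)
  surv <- vapply(seq(0, 1, by = 0.1), function(th)
    nrow(filter_peaks(regs, mappability = mp2, map_min_fraction = th)),
    integer(1))
  expect_true(all(diff(surv) <= 0L))
})

test_that("build_superset forms components, rescales and flags factors", {
  one <- list("CFP-1" = gintervals("chrI", 1000, 1300))
  ss1 <- build_superset(one, sizes = sizes,
                        annotate_only = list("SIN-3" = gintervals(),
                                             "HDA-1" = gintervals()))
  expect_equal(nrow(ss1), 1L)
  expect_true(ss1[["CFP-1"]])
  expect_false(ss1[["SIN-3"]] || ss1[["HDA-1"]])

  two <- list("CFP-1" = gintervals("chrI", 1000, 1300),
              "SIN-3" = gintervals("chrI", 1100, 1400))
  ss2 <- build_superset(two, sizes = sizes)
  expect_equal(ss2[, c("chrom", "start", "end")],
               gintervals("chrI", 1050, 1350), ignore_attr = TRUE)
  expect_true(ss2[["CFP-1"]] && ss2[["SIN-3"]])

  disj <- list("CFP-1" = gintervals("chrI", 0, 300),
               "SIN-3" = gintervals("chrI", 1000, 1300),
               "HDA-1" = gintervals("chrI", 2000, 2300))
  expect_equal(nrow(build_superset(disj, sizes = sizes)), 3L)
})

test_that("superset flags match the base-pair oracle on a random landscape", {
  set.seed(412)
  nsets <- list(
    "CFP-1" = random_intervals(300, max_coord = 60000L, max_width = 300L),
    "SIN-3" = random_intervals(300, max_coord = 60000L, max_width = 300L),
    "HDA-1" = random_intervals(300, max_coord = 60000L, max_width = 300L))
  ss <- build_superset(nsets, sizes = sizes)
  expect_true(all(interval_width(ss) == 300L))
  expect_true(all(ss$n_factors >= 1L))
  idx <- sample.int(nrow(ss), 60)
  for (i in idx) {
    for (f in names(nsets)) {
      expect_identical(ss[[f]][i], oracle_overlaps_any(ss[i, ], nsets[[f]]),
                       label = paste("flag", f, "region", i))
    }
  }
})

test_that("promoter assignment handles containment, the 500 bp boundary and ties", {
  genes <- data.frame(gene_id = c("gB", "gA", "gC"), chrom = "chrI",
                      start = c(800L, 1000L, 5000L), strand = c("+", "+", "-"))
  r1 <- assign_promoters(gintervals("chrI", 900, 1200), NULL, genes)
  expect_true(r1$is_promoter)
  expect_equal(r1$distance_to_start, 0L)
  expect_equal(r1$gene_id, "gA")  # contained beats 100 bp away

  r2 <- assign_promoters(gintervals("chrI", 0, 300), NULL,
                         genes[genes$gene_id == "gB", ])
  expect_true(r2$is_promoter)
  expect_equal(r2$distance_to_start, 500L)  # inclusive boundary
  r3 <- assign_promoters(gintervals("chrI", 0, 300), NULL,
                         data.frame(gene_id = "gB", chrom = "chrI",
                                    start = 801L, strand = "+"))
  expect_false(r3$is_promoter)

  # equidistant genes break ties lexicographically
  tie <- data.frame(gene_id = c("gZ", "gM"), chrom = "chrI",
                    start = c(600L, 1500L), strand = "+")
  r4 <- assign_promoters(gintervals("chrI", 900, 1200), NULL, tie)
  expect_equal(r4$gene_id, "gM")

  # annotated promoter overlap wins over distance
  prom <- gintervals("chrI", 1100, 1250)
  prom$gene_id <- "gP"
  r5 <- assign_promoters(gintervals("chrI", 900, 1200), prom, genes)
  expect_equal(r5$gene_id, "gP")
  expect_equal(r5$distance_to_start, 0L)
})
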