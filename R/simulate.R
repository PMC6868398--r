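## Seeded synthetic-data generators. Each generator runs in its own RNG
## substream derived from (seed, generator name), so adding one generator
## never perturbs another's output at a fixed seed, and restores the caller's
## RNG state on exit.

.substream <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 100000L
  (as.integer(seed) %% 20000L) * 100003L + h
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Toy genome for simulations
#'
#' @param n_chrom number of chromosomes
#' @param chrom_len length of each chromosome in bp
#' @param prefix chromosome-name prefix (doubles as the species token for
#'   genome-of-origin resolution)
#' @return named integer chromosome sizes
#' @export
sim_genome <- function(n_chrom = 2L, chrom_len = 1e6, prefix = "ce") {
  chrom_sizes(rep(as.integer(chrom_len), n_chrom),
              paste0(prefix, "chr", seq_len(n_chrom)))
}

## Draw n reads: a fraction lands around peak summits (weighted), the rest
## uniform. Assumes the RNG is already seeded by the caller.
.draw_reads <- function(n, sizes, peaks = NULL, frac_in_peaks = 0,
                        read_len = 150L, pos_sd = 40, mapq_fail_frac = 0.1) {
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mapq = integer()))
  chroms <- names(sizes)
  in_peak <- if (!is.null(peaks) && nrow(peaks) && frac_in_peaks > 0)
    stats::runif(n) < frac_in_peaks else rep(FALSE, n)
  chrom <- character(n)
  start <- integer(n)
  n_bg <- sum(!in_peak)
  if (n_bg) {
    ch <- sample(chroms, n_bg, replace = TRUE, prob = as.numeric(sizes))
    chrom[!in_peak] <- ch
    start[!in_peak] <- floor(stats::runif(n_bg) * (sizes[ch] - read_len))
  }
  n_pk <- sum(in_peak)
  if (n_pk) {
    w <- if ("weight" %in% names(peaks)) peaks$weight else rep(1, nrow(peaks))
    idx <- sample.int(nrow(peaks), n_pk, replace = TRUE, prob = w)
    centre <- peaks$summit[idx] + round(stats::rnorm(n_pk, 0, pos_sd))
    s <- centre - read_len %/% 2L
    s <- pmax(0L, pmin(s, sizes[peaks$chrom[idx]] - read_len))
    chrom[in_peak] <- peaks$chrom[idx]
    start[in_peak] <- s
  }
  fail <- stats::runif(n) < mapq_fail_frac
  mapq <- integer(n)
  mapq[fail] <- sample(0:9, sum(fail), replace = TRUE)
  mapq[!fail] <- sample(10:42, sum(!fail), replace = TRUE)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + read_len), mapq = mapq,
             stringsAsFactors = FALSE)
}

## Evenly spaced candidate summits, >= min_gap apart, away from chromosome
## edges; errors when n sites cannot be packed.
.place_sites <- function(sizes, n, min_gap = 600L, edge = 500L) {
  cand <- do.call(rbind, lapply(names(sizes), function(ch) {
    pos <- seq(edge, sizes[[ch]] - edge, by = min_gap)
    data.frame(chrom = ch, summit = as.integer(pos), stringsAsFactors = FALSE)
  }))
  if (nrow(cand) < n)
    stop("infeasible site packing: ", n, " sites requested, ",
         nrow(cand), " positions available")
  picked <- sort(sample.int(nrow(cand), n))
  cand[picked, , drop = FALSE]
}

#' Simulate dual-genome input and ChIP read sets
#'
#' Emulates the spike-in design: input reads fall on the spike-in genome with
#' probability `r / (1 + r)` and uniformly along either genome; ChIP reads
#' concentrate around planted peak summits (per-site weights) in both
#' genomes, with a configurable fraction drawn as uniform background. A
#' configurable fraction of reads gets mapq < 10 so the filter has work to
#' do.
#'
#' @param seed integer seed (bit-reproducible output)
#' @param r planted spike-in ratio (spike / target chromatin)
#' @param n_input,n_chip read counts for the input and ChIP libraries
#' @param sizes_target,sizes_spike chromosome sizes of the two genomes
#'   (chromosome-name prefixes must differ)
#' @param peaks_target,peaks_spike data frames with `chrom`, `summit` and
#'   optional `weight`; generated on a grid when NULL
#' @param n_sites sites per genome when peaks are generated here
#' @param frac_in_peaks fraction of ChIP reads drawn from peaks
#' @param read_len read length in bp
#' @param pos_sd SD of read-centre jitter around the summit in bp
#' @param mapq_fail_frac fraction of reads simulated with mapq < 10
#' @return list with `input`, `chip` (read frames) and `truth` (planted
#'   parameters including the peak tables)
#' @export
simulate_dual_genome_reads <- function(seed, r = 0.1, n_input = 1e5,
                                       n_chip = 2e5,
                                       sizes_target = sim_genome(prefix = "ce"),
                                       sizes_spike = sim_genome(prefix = "cb"),
                                       peaks_target = NULL, peaks_spike = NULL,
                                       n_sites = 150L, frac_in_peaks = 0.85,
                                       read_len = 150L, pos_sd = 40,
                                       mapq_fail_frac = 0.1) {
  stopifnot(r > 0, n_input > 0, n_chip > 0)
  .with_seed(.substream(seed, "dual_genome_reads"), {
    if (is.null(peaks_target)) {
      peaks_target <- .place_sites(sizes_target, n_sites)
      peaks_target$weight <- exp(stats::rnorm(nrow(peaks_target), 0, 0.3))
    }
    if (is.null(peaks_spike)) {
      peaks_spike <- .place_sites(sizes_spike, n_sites)
      peaks_spike$weight <- exp(stats::rnorm(nrow(peaks_spike), 0, 0.3))
    }
    p_spike <- r / (1 + r)
    draw_sample <- function(n, frac_pk) {
      n_sp <- stats::rbinom(1, n, p_spike)
      tg <- .draw_reads(n - n_sp, sizes_target, peaks_target, frac_pk,
                        read_len, pos_sd, mapq_fail_frac)
      sp <- .draw_reads(n_sp, sizes_spike, peaks_spike, frac_pk,
                        read_len, pos_sd, mapq_fail_frac)
      out <- rbind(tg, sp)
      out[sample.int(nrow(out)), , drop = FALSE]
    }
    input <- draw_sample(n_input, 0)
    chip <- draw_sample(n_chip, frac_in_peaks)
    rownames(input) <- rownames(chip) <- NULL
    list(input = input, chip = chip,
         truth = list(r = r, peaks_target = peaks_target,
                      peaks_spike = peaks_spike,
                      frac_in_peaks = frac_in_peaks, read_len = read_len,
                      mapq_fail_frac = mapq_fail_frac))
  })
}

#' Simulate a multi-factor peak landscape
#'
#' Plants `n_sites` sites at least 600 bp apart so neighbouring 300 bp
#' regions can never merge by accident. Each site draws a factor combination
#' from `combo_probs` (its co-occupancy truth) and a strong/weak class; every
#' occupied factor gets two replicate peak calls whose summits jitter around
#' the site with SD `jitter_sd` (0 reproduces the planted regions exactly).
#'
#' @param seed integer seed
#' @param sizes chromosome sizes
#' @param n_sites number of planted sites
#' @param combo_probs named probabilities over factor combinations, names
#'   like `"CFP-1+SIN-3"`; must sum to 1. The default emulates a landscape
#'   where most sites carry CFP-1 and co-occupancy with SIN-3/HDA-1 is
#'   common.
#' @param strong_fraction fraction of sites planted as strong targets
#' @param jitter_sd replicate summit jitter SD in bp
#' @return list with `peaks` (per factor, a list of two replicate data
#'   frames with `chrom`, `start`, `end`, `summit`, `score`) and `truth`
#'   (site table with `chrom`, `summit`, `strong` and one logical column per
#'   factor, plus `combo_probs`)
#' @export
simulate_peak_landscape <- function(seed, sizes = sim_genome(prefix = "ce"),
                                    n_sites = 1000L,
                                    combo_probs = c("CFP-1+SIN-3+HDA-1" = 0.45,
                                                    "CFP-1+HDA-1" = 0.15,
                                                    "CFP-1+SIN-3" = 0.10,
                                                    "CFP-1" = 0.10,
                                                    "HDA-1" = 0.15,
                                                    "SIN-3" = 0.05),
                                    strong_fraction = 0.4, jitter_sd = 20) {
  stopifnot(abs(sum(combo_probs) - 1) < 1e-9, all(combo_probs >= 0))
  factors <- unique(unlist(strsplit(names(combo_probs), "+", fixed = TRUE)))
  .with_seed(.substream(seed, "peak_landscape"), {
    truth <- .place_sites(sizes, n_sites)
    combo <- sample(names(combo_probs), n_sites, replace = TRUE,
                    prob = combo_probs)
    for (f in factors)
      truth[[f]] <- vapply(strsplit(combo, "+", fixed = TRUE),
                           function(x) f %in% x, logical(1))
    n_strong <- round(strong_fraction * n_sites)
    strong <- rep(FALSE, n_sites)
    strong[sample.int(n_sites, n_strong)] <- TRUE
    truth$strong <- strong
    peaks <- lapply(factors, function(f) {
      at <- truth[truth[[f]], , drop = FALSE]
      lapply(1:2, function(rep_i) {
        jit <- if (jitter_sd > 0) round(stats::rnorm(nrow(at), 0, jitter_sd)) else 0L
        summit <- pmax(200L, pmin(at$summit + jit, sizes[at$chrom] - 200L))
        data.frame(chrom = at$chrom, start = as.integer(summit - 200L),
                   end = as.integer(summit + 200L),
                   summit = as.integer(summit),
                   score = round(stats::runif(nrow(at), 50, 1000), 1),
                   stringsAsFactors = FALSE)
      })
    })
    names(peaks) <- factors
    list(peaks = peaks, truth = truth, combo_probs = combo_probs)
  })
}

#' Simulate signal tracks over a planted landscape
#'
#' Builds one binned coverage track per entry of `track_params`. Each track
#' is uniform background plus truncated Gaussian bin noise, with a per-site
#' boxcar of half-width 150 bp whose amplitude is log-normal around the
#' site's class mean (`strong` / `weak`); sites not carrying `factor` (when
#' given) contribute nothing. This emulates the bimodal strong/weak signal
#' structure; it does not emulate fragment-length effects or GC bias.
#'
#' @param seed integer seed
#' @param truth site table from [simulate_peak_landscape()]
#' @param sizes chromosome sizes
#' @param track_params named list; each element a list with `strong`, `weak`
#'   (class mean amplitudes), and optionally `sdlog` (default 0.15),
#'   `background` (default 0.5), `noise_sd` (default 0.1), `factor` (site
#'   column gating which sites carry signal; default all sites)
#' @param bin bin width in bp
#' @return named list of `coverage_track`s (state `raw`)
#' @export
simulate_signal_tracks <- function(seed, truth, sizes = sim_genome(prefix = "ce"),
                                   track_params = list(
                                     "CFP-1" = list(strong = 8, weak = 2, factor = "CFP-1"),
                                     "H3K4me3" = list(strong = 10, weak = 2)),
                                   bin = 10L) {
  .with_seed(.substream(seed, "signal_tracks"), {
    lapply(track_params, function(tp) {
      sdlog <- if (is.null(tp$sdlog)) 0.15 else tp$sdlog
      bg <- if (is.null(tp$background)) 0.5 else tp$background
      nsd <- if (is.null(tp$noise_sd)) 0.1 else tp$noise_sd
      sites <- if (is.null(tp$factor)) truth else truth[truth[[tp$factor]], , drop = FALSE]
      values <- lapply(names(sizes), function(ch) {
        nb <- ceiling(sizes[[ch]] / bin)
        pmax(bg + stats::rnorm(nb, 0, nsd), 0)
      })
      names(values) <- names(sizes)
      if (nrow(sites)) {
        mu <- ifelse(sites$strong, tp$strong, tp$weak)
        amp <- exp(stats::rnorm(nrow(sites), log(mu), sdlog))
        for (i in seq_len(nrow(sites))) {
          ch <- sites$chrom[i]
          b0 <- max(1L, (sites$summit[i] - 150L) %/% bin + 1L)
          b1 <- min(length(values[[ch]]), (sites$summit[i] + 149L) %/% bin + 1L)
          values[[ch]][b0:b1] <- values[[ch]][b0:b1] + amp[i]
        }
      }
      coverage_track(sizes, bin = bin, state = "raw", values = values)
    })
  })
}

#' Simulate a spectral-count table with planted interactors
#'
#' Planted interactors always pass the enrichment filter by construction
#' (replicate 1 has IP SC >= `min_sc` with control 0); background proteins
#' always fail, either by low IP counts or by a control that caps the
#' IP/control ratio strictly below `min_ratio`.
#'
#' @param seed integer seed
#' @param n_proteins total proteins in the table
#' @param n_planted planted true interactors
#' @param n_reps replicates per condition
#' @param min_sc,min_ratio thresholds the construction respects
#' @return list with `table` (SC data frame) and `truth` (planted protein
#'   ids)
#' @export
simulate_sc_table <- function(seed, n_proteins = 500L, n_planted = 50L,
                              n_reps = 2L, min_sc = 3L, min_ratio = 5) {
  stopifnot(n_planted <= n_proteins)
  .with_seed(.substream(seed, "sc_table"), {
    ids <- sprintf("P%05d", seq_len(n_proteins))
    planted <- sort(sample(ids, n_planted))
    ip <- matrix(0L, n_proteins, n_reps)
    ctl <- matrix(0L, n_proteins, n_reps)
    is_planted <- ids %in% planted
    n_bg <- sum(!is_planted)
    # planted: replicate 1 passes cleanly, others free low counts
    ip[is_planted, 1] <- min_sc + stats::rpois(n_planted, 7)
    ctl[is_planted, 1] <- 0L
    if (n_reps > 1L) {
      for (j in 2:n_reps) {
        ip[is_planted, j] <- stats::rpois(n_planted, 4)
        ctl[is_planted, j] <- stats::rpois(n_planted, 1)
      }
    }
    # background: half low-IP, half high-control (ratio < min_ratio)
    low <- which(!is_planted)[seq_len(n_bg %/% 2)]
    high <- setdiff(which(!is_planted), low)
    for (j in seq_len(n_reps)) {
      ip[low, j] <- pmin(stats::rpois(length(low), 1), min_sc - 1L)
      ctl[low, j] <- stats::rpois(length(low), 2)
      ip_h <- min_sc + stats::rpois(length(high), 3)
      ip[high, j] <- ip_h
      ctl[high, j] <- ip_h %/% min_ratio + 1L + stats::rpois(length(high), 1)
    }
    tab <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
    for (j in seq_len(n_reps)) tab[[paste0("ip_", j)]] <- ip[, j]
    for (j in seq_len(n_reps)) tab[[paste0("control_", j)]] <- ctl[, j]
    tab <- tab[sample.int(n_proteins), , drop = FALSE]
    rownames(tab) <- NULL
    list(table = tab, truth = planted)
  })
}

#' Simulate differential-expression tables with planted overlap structure
#'
#' Three (or more) genotypes share a gene universe; a configurable fraction
#' of genes is expressed (`baseMean > 10`). DE genes get `padj` drawn below
#' `alpha` and a signed log2 fold change; everything else draws `padj` at or
#' above `alpha` (with a small missing fraction). With `overlap = NULL` the
#' per-genotype DE sets are drawn independently from the universe (the null
#' used for calibration); otherwise `overlap` plants exact triple / pairwise
#' shared counts per direction.
#'
#' @param seed integer seed
#' @param n_genes total genes
#' @param frac_expressed fraction with `baseMean > 10`
#' @param genotypes genotype names
#' @param n_up,n_down planted DE genes per genotype and direction
#' @param overlap NULL for independent sets, or a list with elements `up`
#'   and `down`, each `c(abc = , ab = , ac = , bc = )` giving the planted
#'   triple count and the extra pairwise-only counts (three genotypes only)
#' @param alpha FDR level the `padj` draws respect
#' @param na_frac fraction of non-DE expressed genes with missing `padj`
#' @return list with `tables` (named list of DE data frames), `truth`
#'   (universe, per-genotype up/down sets, planted overlap)
#' @export
simulate_de_tables <- function(seed, n_genes = 2000L, frac_expressed = 0.6,
                               genotypes = c("cfp-1", "set-2", "sin-3"),
                               n_up = 180L, n_down = 180L, overlap = NULL,
                               alpha = 0.05, na_frac = 0.02) {
  .with_seed(.substream(seed, "de_tables"), {
    ids <- sprintf("gene%05d", seq_len(n_genes))
    n_expr <- round(frac_expressed * n_genes)
    expressed <- sort(sample(ids, n_expr))
    baseMean <- stats::setNames(stats::runif(n_genes, 0.1, 10), ids)
    baseMean[expressed] <- 10 + stats::rlnorm(n_expr, log(150), 1.2)
    if (n_up + n_down > length(expressed))
      stop("infeasible overlap specification: pool exhausted")
    if (is.null(overlap)) {
      # null model: each genotype draws its DE genes independently of the
      # others; up and down stay disjoint within a genotype
      up_sets <- stats::setNames(vector("list", length(genotypes)), genotypes)
      down_sets <- up_sets
      for (g in genotypes) {
        idx <- sample(expressed, n_up + n_down)
        up_sets[[g]] <- idx[seq_len(n_up)]
        down_sets[[g]] <- idx[n_up + seq_len(n_down)]
      }
    } else {
      # planted-overlap model: one shared pool across directions and groups
      # so a gene never lands in two sets unless the plan says so
      pool <- sample(expressed)
      take <- function(k) {
        if (k > length(pool))
          stop("infeasible overlap specification: pool exhausted")
        out <- pool[seq_len(k)]
        pool <<- pool[-seq_len(k)]
        out
      }
      assign_sets <- function(n_set, ov) {
        stopifnot(length(genotypes) == 3L,
                  all(c("abc", "ab", "ac", "bc") %in% names(ov)))
        sets <- stats::setNames(vector("list", length(genotypes)), genotypes)
        for (g in genotypes) sets[[g]] <- character(0)
        grab <- list(abc = c(1, 2, 3), ab = c(1, 2), ac = c(1, 3), bc = c(2, 3))
        for (gname in names(grab)) {
          genes <- take(ov[[gname]])
          for (gi in grab[[gname]])
            sets[[genotypes[gi]]] <- c(sets[[genotypes[gi]]], genes)
        }
        for (g in genotypes) {
          rest <- n_set - length(sets[[g]])
          if (rest < 0) stop("infeasible overlap specification: ",
                             g, " exceeds ", n_set)
          sets[[g]] <- c(sets[[g]], take(rest))
        }
        sets
      }
      up_sets <- assign_sets(n_up, overlap$up)
      down_sets <- assign_sets(n_down, overlap$down)
    }
    tables <- lapply(genotypes, function(g) {
      de_up <- ids %in% up_sets[[g]]
      de_down <- ids %in% down_sets[[g]]
      padj <- stats::runif(n_genes, alpha, 1)
      padj[de_up | de_down] <- stats::runif(sum(de_up | de_down), 0, alpha * 0.9)
      lfc <- stats::rnorm(n_genes, 0, 0.2)
      lfc[de_up] <- abs(stats::rnorm(sum(de_up), 1.5, 0.5)) + 0.1
      lfc[de_down] <- -(abs(stats::rnorm(sum(de_down), 1.5, 0.5)) + 0.1)
      miss <- !(de_up | de_down) & stats::runif(n_genes) < na_frac
      padj[miss] <- NA_real_
      padj[!(ids %in% expressed)] <- NA_real_
      data.frame(gene_id = ids, baseMean = unname(baseMean), log2fc = lfc,
                 padj = padj, stringsAsFactors = FALSE)
    })
    names(tables) <- genotypes
    list(tables = tables,
         truth = list(universe = expressed, up = up_sets, down = down_sets,
                      overlap = overlap, alpha = alpha))
  })
}
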