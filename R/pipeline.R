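## Orchestration: full-preset simulation to disk, config-driven end-to-end
## runs, and a manifest that ties outputs to inputs, parameters and seeds.

.cc_error <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.jitter_calls <- function(truth, factor, sizes, jitter_sd, seed) {
  .with_seed(seed, {
    at <- truth[truth[[factor]], , drop = FALSE]
    lapply(1:2, function(i) {
      jit <- if (jitter_sd > 0) round(stats::rnorm(nrow(at), 0, jitter_sd)) else 0L
      summit <- pmax(200L, pmin(at$summit + jit, sizes[at$chrom] - 200L))
      data.frame(chrom = at$chrom, start = as.integer(summit - 200L),
                 end = as.integer(summit + 200L), summit = as.integer(summit),
                 score = 100, stringsAsFactors = FALSE)
    })
  })
}

#' Write a complete synthetic dataset to disk
#'
#' The "full" preset: a two-genome read population with planted spike-in
#' ratio, a planted multi-factor peak landscape (two replicates per factor,
#' plus a second SIN-3 antibody), signal tracks, gene and promoter
#' annotations, blacklist and mappability files, a spectral-count table and
#' three DE tables — everything the end-to-end pipeline consumes, in the
#' plain-text formats the readers expect, plus a machine-readable
#' `truth.json`.
#'
#' @param seed integer seed; output is bit-reproducible
#' @param out_dir output directory (created if needed)
#' @param chrom_len,n_sites,n_input,n_chip scale knobs (defaults keep the
#'   full preset a few seconds)
#' @param r planted spike-in ratio
#' @param jitter_sd replicate summit jitter in bp
#' @return invisibly, a list of all written paths plus the in-memory truth
#' @export
simulate_all <- function(seed, out_dir, chrom_len = 3e5, n_sites = 200L,
                         n_input = 50000L, n_chip = 100000L, r = 0.1,
                         jitter_sd = 20) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  sizes_t <- sim_genome(chrom_len = chrom_len, prefix = "ce")
  sizes_s <- sim_genome(chrom_len = chrom_len, prefix = "cb")

  land <- simulate_peak_landscape(seed, sizes_t, n_sites = n_sites,
                                  jitter_sd = jitter_sd)
  truth <- land$truth
  # H3K4me3 ChIP reads concentrate at planted sites, strong sites heavier
  site_peaks <- data.frame(chrom = truth$chrom, summit = truth$summit,
                           weight = ifelse(truth$strong, 10, 2))
  reads <- simulate_dual_genome_reads(seed, r = r, n_input = n_input,
                                      n_chip = n_chip, sizes_target = sizes_t,
                                      sizes_spike = sizes_s,
                                      peaks_target = site_peaks)
  tracks <- simulate_signal_tracks(seed, truth, sizes_t)

  write_chrom_sizes(sizes_t, p("target.chrom.sizes"))
  write_chrom_sizes(sizes_s, p("spike.chrom.sizes"))
  write_reads_bed(reads$input, p("input_reads.bed"))
  write_reads_bed(reads$chip, p("chip_reads.bed"))
  sp <- reads$truth$peaks_spike
  write_bed(gintervals(sp$chrom, sp$summit - 150L, sp$summit + 150L),
            p("spike_peaks.bed"))
  # blacklist and a low-mappability window per target chromosome, both away
  # from planted sites (sites start 500 bp in)
  blacklist <- gintervals(names(sizes_t), 0L, 400L)
  write_bed(blacklist, p("blacklist.bed"))
  map_lines <- unlist(lapply(names(sizes_t), function(ch) {
    L <- sizes_t[[ch]]
    c(sprintf("%s\t0\t%d\t1.0", ch, L - 400L),
      sprintf("%s\t%d\t%d\t0.1", ch, L - 400L, L))
  }))
  writeLines(map_lines, p("mappability.bedGraph"))

  peak_files <- list()
  for (f in names(land$peaks)) {
    for (i in 1:2) {
      path <- p(gsub("-", "", f), "_rep", i, ".narrowPeak")
      write_narrowpeak(land$peaks[[f]][[i]], path)
      peak_files[[paste0(f, "_rep", i)]] <- path
    }
  }
  ab2 <- .jitter_calls(truth, "SIN-3", sizes_t, jitter_sd,
                       .substream(seed, "sin3_ab2"))
  for (i in 1:2) {
    path <- p("SIN3_ab2_rep", i, ".narrowPeak")
    write_narrowpeak(ab2[[i]], path)
    peak_files[[paste0("SIN-3_ab2_rep", i)]] <- path
  }

  for (tn in names(tracks))
    write_bedgraph(tracks[[tn]], p(gsub("-", "", tn), ".bedGraph"))

  # genes: one per site (start near the summit for most), plus decoys
  genes <- .with_seed(.substream(seed, "genes"), {
    near <- stats::runif(nrow(truth)) < 0.85
    gstart <- ifelse(near,
                     truth$summit + round(stats::rnorm(nrow(truth), 0, 120)),
                     truth$summit + 2000L + sample(0:500, nrow(truth), TRUE))
    data.frame(gene_id = sprintf("g%04d", seq_len(nrow(truth))),
               chrom = truth$chrom,
               start = pmax(0L, pmin(as.integer(gstart), sizes_t[truth$chrom] - 1L)),
               strand = sample(c("+", "-"), nrow(truth), TRUE),
               stringsAsFactors = FALSE)
  })
  write_gene_table(genes, p("genes.tsv"))
  prom_idx <- .with_seed(.substream(seed, "promoters"),
                         which(stats::runif(nrow(genes)) < 0.6))
  prom <- genes[prom_idx, , drop = FALSE]
  prom_iv <- gintervals(prom$chrom, pmax(0L, prom$start - 150L),
                        prom$start + 150L)
  prom_iv$name <- prom$gene_id
  write_bed(prom_iv, p("promoters.bed"))

  sc <- simulate_sc_table(seed)
  write_sc_table(sc$table, p("sc_table.tsv"))
  de <- simulate_de_tables(seed,
                           overlap = list(up = c(abc = 40, ab = 20, ac = 20, bc = 5),
                                          down = c(abc = 40, ab = 20, ac = 20, bc = 5)))
  for (g in names(de$tables))
    write_de_table(de$tables[[g]], p("de_", gsub("-", "", g), ".tsv"))

  truth_out <- list(seed = seed, r = r,
                    n_sites = nrow(truth), n_strong = sum(truth$strong),
                    sites = truth, sc_planted = sc$truth,
                    de_truth = list(universe_size = length(de$truth$universe),
                                    up = de$truth$up, down = de$truth$down))
  jsonlite::write_json(truth_out, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(dir = out_dir, truth = truth_out, sizes_target = sizes_t,
                 sizes_spike = sizes_s, genes = genes))
}

#' Default pipeline configuration
#'
#' Every numeric parameter defaults to the study's stated value and every
#' default is overridable: 150 bp summit flank (300 bp regions), mapq >= 10,
#' mappability >= 25%, 500 bp promoter distance, SC >= 3 and ratio >= 5,
#' baseMean > 10, FDR < 0.05, k = 2.
#'
#' @param dir directory holding a [simulate_all()] dataset, used to fill in
#'   input paths (optional)
#' @param ... overrides
#' @return config list
#' @export
pipeline_config <- function(dir = NULL, ...) {
  cfg <- list(mapq_min = 10L, flank = 150L, width = 300L,
              map_min_fraction = 0.25, max_dist = 500L,
              min_sc = 3L, min_ratio = 5, basemean_min = 10,
              alpha = 0.05, k = 2L, seed = 13L, bin = 10L,
              target_prefix = "ce", spike_prefix = "cb")
  if (!is.null(dir)) {
    p <- function(...) file.path(dir, paste0(...))
    cfg <- c(cfg, list(
      target_sizes = p("target.chrom.sizes"),
      spike_sizes = p("spike.chrom.sizes"),
      chip_reads = p("chip_reads.bed"),
      input_reads = p("input_reads.bed"),
      spike_peaks = p("spike_peaks.bed"),
      blacklist = p("blacklist.bed"),
      mappability = p("mappability.bedGraph"),
      peaks = list(
        "CFP-1" = c(p("CFP1_rep1.narrowPeak"), p("CFP1_rep2.narrowPeak")),
        "SIN-3" = c(p("SIN3_rep1.narrowPeak"), p("SIN3_rep2.narrowPeak")),
        "HDA-1" = c(p("HDA1_rep1.narrowPeak"), p("HDA1_rep2.narrowPeak"))),
      sin3_ab2 = c(p("SIN3_ab2_rep1.narrowPeak"), p("SIN3_ab2_rep2.narrowPeak")),
      tracks = list("CFP-1" = p("CFP1.bedGraph"), "H3K4me3" = p("H3K4me3.bedGraph")),
      genes = p("genes.tsv"),
      promoters = p("promoters.bed"),
      sc_table = p("sc_table.tsv"),
      de_tables = list("cfp-1" = p("de_cfp1.tsv"), "set-2" = p("de_set2.tsv"),
                       "sin-3" = p("de_sin3.tsv"))))
  }
  utils::modifyList(cfg, list(...))
}

.input_files <- function(cfg) {
  keys <- c("target_sizes", "spike_sizes", "chip_reads", "input_reads",
            "spike_peaks", "blacklist", "mappability", "genes", "promoters",
            "sc_table")
  files <- unlist(c(cfg[intersect(keys, names(cfg))], cfg$peaks, cfg$sin3_ab2,
                    cfg$tracks, cfg$de_tables), use.names = FALSE)
  files[!is.na(files)]
}

#' Run the full analysis pipeline
#'
#' Stage order: read partition/filter, spike-in ratio, scaling factor, track
#' scaling, mode subtraction, summit extension, replicate (and SIN-3
#' antibody) consensus, mappability/blacklist peak filtering, co-occupancy
#' superset, strong/weak classification, set quantification, promoter
#' assignment, and (when inputs are configured) the spectral-count filter
#' and the DE-overlap tests. A failing stage aborts with the stage named.
#'
#' @param config list from [pipeline_config()], or path to a JSON file
#' @param out_dir where outputs and `manifest.json` go
#' @return the run manifest, invisibly (also written to
#'   `out_dir/manifest.json`)
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) .cc_error("cc_config_error", "config file not found: ", config)
    config <- utils::modifyList(pipeline_config(), jsonlite::read_json(config, simplifyVector = TRUE))
  }
  for (k in c("target_sizes", "chip_reads", "input_reads", "spike_peaks"))
    if (is.null(config[[k]]))
      .cc_error("cc_config_error", "config is missing required key: ", k)
  missing <- .input_files(config)
  missing <- missing[!file.exists(missing)]
  if (length(missing))
    .cc_error("cc_input_error", "missing input file(s): ",
              paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(...) file.path(out_dir, paste0(...))
  stage <- "setup"
  derived <- list()
  outputs <- character()
  run_stage <- function(name, expr) {
    stage <- name
    tryCatch(expr, error = function(e) {
      if (inherits(e, "cc_input_error") || inherits(e, "cc_config_error")) stop(e)
      .cc_error("cc_stage_error", "stage '", name, "' failed: ",
                conditionMessage(e))
    })
  }

  sizes_t <- run_stage("read_inputs", read_chrom_sizes(config$target_sizes))
  genome_map <- stats::setNames(c("target", "spike"),
                                c(config$target_prefix, config$spike_prefix))
  blacklist <- if (!is.null(config$blacklist)) read_bed(config$blacklist) else gintervals()

  norm <- run_stage("spikein_normalize", {
    spikein_normalize(
      chip_reads = read_reads_bed(config$chip_reads),
      input_reads = read_reads_bed(config$input_reads),
      spike_peaks = read_bed(config$spike_peaks),
      sizes_target = sizes_t, genome_map = genome_map,
      mapq_min = config$mapq_min, blacklist = blacklist, bin = config$bin)
  })
  derived$r <- norm$ratio$ratio
  derived$s <- norm$scaling$value
  derived$mode <- norm$mode
  run_stage("write_normalized_track", {
    write_bedgraph(norm$track, outp("h3k4me3_normalized.bedGraph"))
    outputs <- c(outputs, outp("h3k4me3_normalized.bedGraph"))
  })

  mapp <- if (!is.null(config$mappability))
    run_stage("read_mappability",
              read_bedgraph(config$mappability, sizes_t, bin = config$bin)) else NULL

  calls <- run_stage("peak_consensus", {
    cl <- lapply(names(config$peaks), function(f) {
      reps <- lapply(config$peaks[[f]], read_narrowpeak)
      regs <- lapply(reps, extend_summits, flank = config$flank, sizes = sizes_t)
      consensus(regs[[1]], regs[[2]], width = config$width, sizes = sizes_t)
    })
    names(cl) <- names(config$peaks)
    if (!is.null(config$sin3_ab2) && "SIN-3" %in% names(cl)) {
      reps2 <- lapply(config$sin3_ab2, read_narrowpeak)
      regs2 <- lapply(reps2, extend_summits, flank = config$flank, sizes = sizes_t)
      cons2 <- consensus(regs2[[1]], regs2[[2]], width = config$width, sizes = sizes_t)
      cl[["SIN-3"]] <- antibody_consensus(cl[["SIN-3"]], cons2,
                                          width = config$width, sizes = sizes_t)
    }
    cl
  })
  calls <- run_stage("peak_filter", {
    lapply(calls, filter_peaks, mappability = mapp,
           map_min_fraction = config$map_min_fraction, blacklist = blacklist)
  })
  superset <- run_stage("superset", {
    ss <- build_superset(calls, width = config$width, sizes = sizes_t)
    utils::write.table(ss, outp("superset.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, outp("superset.tsv"))
    ss
  })
  derived$n_superset <- nrow(superset)

  classification <- NULL
  if (!is.null(config$tracks)) {
    classification <- run_stage("classify", {
      cfp1 <- superset[superset[["CFP-1"]], , drop = FALSE]
      mats <- lapply(config$tracks, function(path) {
        tr <- zscore_track(read_bedgraph(path, sizes_t, bin = config$bin))
        region_matrix(tr, cfp1)
      })
      names(mats) <- names(config$tracks)
      km <- kmeans_strong_weak(mats, seed = config$seed)
      cls <- cbind(cfp1[, c("chrom", "start", "end")],
                   class = as.character(km$labels))
      utils::write.table(cls, outp("compass_classes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, outp("compass_classes.tsv"))
      list(km = km, regions = cfp1)
    })
    run_stage("quantify", {
      track_z <- zscore_track(read_bedgraph(config$tracks[[length(config$tracks)]],
                                            sizes_t, bin = config$bin))
      lab <- classification$km$labels
      sets <- list(strong = classification$regions[lab == "strong", ],
                   weak = classification$regions[lab == "weak", ])
      q <- quantify_sets(track_z, sets, require_state = "zscored")
      jsonlite::write_json(lapply(q, function(x) as.list(x$summary)),
                           outp("quantify_summary.json"), auto_unbox = TRUE,
                           digits = NA)
      outputs <- c(outputs, outp("quantify_summary.json"))
    })
  }

  if (!is.null(config$genes)) {
    run_stage("promoters", {
      genes <- read_gene_table(config$genes)
      prom <- if (!is.null(config$promoters)) {
        pa <- read_bed(config$promoters)
        names(pa)[names(pa) == "name"] <- "gene_id"
        pa
      } else NULL
      asn <- assign_promoters(superset, prom, genes, max_dist = config$max_dist)
      utils::write.table(asn, outp("promoter_assignment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, outp("promoter_assignment.tsv"))
      derived$n_promoter <- sum(asn$is_promoter)
    })
  }

  if (!is.null(config$sc_table)) {
    run_stage("ipms_filter", {
      res <- filter_table(read_sc_table(config$sc_table),
                          filter_params(config$min_sc, config$min_ratio))
      write_sc_table(res$passed, outp("ipms_pass.tsv"))
      outputs <- c(outputs, outp("ipms_pass.tsv"))
      derived$n_ipms_pass <- res$report$n_pass
    })
  }

  if (!is.null(config$de_tables)) {
    run_stage("de_overlap", {
      des <- lapply(config$de_tables, read_de_table)
      universe <- Reduce(intersect, lapply(des, select_universe,
                                           basemean_min = config$basemean_min))
      sets <- lapply(des, de_sets, universe = universe, alpha = config$alpha)
      ov <- de_overlap_table(sets, universe)
      utils::write.table(ov$pairs, outp("de_overlap.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, outp("de_overlap.tsv"))
      derived$de_universe <- length(universe)
    })
  }

  manifest <- list(
    config = config[setdiff(names(config), c("peaks", "sin3_ab2", "tracks",
                                             "de_tables"))],
    parameters = config[c("mapq_min", "flank", "width", "map_min_fraction",
                          "max_dist", "min_sc", "min_ratio", "basemean_min",
                          "alpha", "k", "seed", "bin")],
    input_checksums = as.list(tools::md5sum(.input_files(config))),
    derived = derived,
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Verify a run manifest against the files on disk
#'
#' Recomputes the md5 checksum of every input recorded in the manifest; a
#' mismatch (or missing file) is an error, so a stale or corrupted input can
#' never be silently reused for an incremental re-run.
#'
#' @param manifest_path path to a `manifest.json`
#' @return TRUE invisibly when everything matches
#' @export
verify_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  recorded <- unlist(man$input_checksums)
  current <- tools::md5sum(names(recorded))
  bad <- names(recorded)[is.na(current) | current != recorded]
  if (length(bad))
    .cc_error("cc_input_error", "input checksum mismatch: ",
              paste(bad, collapse = ", "))
  invisible(TRUE)
}
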