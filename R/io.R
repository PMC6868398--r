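#' Read a two-column chrom.sizes file
#'
#' @param path file with `chrom<TAB>length` records
#' @return named integer vector of chromosome sizes
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  chrom_sizes(tab$length, tab$chrom)
}

#' Write a chrom.sizes file
#' @param sizes named integer vector
#' @param path output path
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), unname(sizes)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read BED3/BED4/BED6 intervals
#'
#' Coordinates are kept 0-based half-open as in the file. Columns beyond the
#' first three are mapped to `name`, `score`, `strand` when present.
#'
#' @param path BED file (no header)
#' @return interval data frame
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 3L) stop("BED file needs >= 3 columns: ", path)
  names(tab)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  k <- min(ncol(tab) - 3L, 3L)
  if (k > 0L) names(tab)[4:(3L + k)] <- extra[seq_len(k)]
  tab$chrom <- as.character(tab$chrom)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  validate_intervals(tab)
  tab
}

#' Write intervals as BED
#'
#' Emits BED3 or, when `name`/`score`/`strand` columns are present, up to
#' BED6. Tab-delimited, newline-terminated, no header.
#'
#' @param iv interval data frame
#' @param path output path
#' @export
write_bed <- function(iv, path) {
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(iv)) cols <- c(cols, extra) else break
  }
  utils::write.table(iv[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read ENCODE narrowPeak calls
#'
#' 10-column narrowPeak. The column-10 summit offset (relative to `start`) is
#' converted to an absolute 0-based `summit` position on read; an offset of -1
#' (no summit called) is an error, since downstream summit extension needs it.
#'
#' @param path narrowPeak file
#' @return data frame with `chrom`, `start`, `end`, `name`, `score`, `summit`
#' @export
read_narrowpeak <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name", "score",
                                         "strand", "signalValue", "pValue",
                                         "qValue", "peak"))
  tab$chrom <- as.character(tab$chrom)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  validate_intervals(tab)
  if (any(tab$peak < 0L)) stop("narrowPeak record without summit offset: ", path)
  out <- tab[, c("chrom", "start", "end", "name", "score")]
  out$summit <- tab$start + as.integer(tab$peak)
  if (any(out$summit < out$start | out$summit >= out$end))
    stop("summit outside its peak interval: ", path)
  out
}

#' Write peaks as narrowPeak
#' @param peaks data frame with `chrom`, `start`, `end`, `summit` and
#'   optionally `name`, `score`
#' @param path output path
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  tab <- data.frame(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name else sprintf("peak_%d", seq_len(n)),
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = ".",
    signalValue = if ("score" %in% names(peaks)) peaks$score else 0,
    pValue = -1, qValue = -1,
    peak = peaks$summit - peaks$start
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a spectral-count table
#'
#' Tab-delimited with header: `protein_id`, then IP replicate columns
#' `ip_1 ... ip_k` and matched control columns `control_1 ... control_k`.
#' Missing cells are read as 0. Duplicate protein ids and negative counts are
#' hard errors.
#'
#' @param path TSV file
#' @return data frame with `protein_id` and integer `ip_*` / `control_*` columns
#' @export
read_sc_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"protein_id" %in% names(tab)) stop("SC table needs a protein_id column: ", path)
  ip_cols <- grep("^ip_", names(tab), value = TRUE)
  ctl_cols <- grep("^control_", names(tab), value = TRUE)
  if (length(ip_cols) == 0L || length(ip_cols) != length(ctl_cols))
    stop("SC table needs matched ip_*/control_* replicate columns: ", path)
  if (anyDuplicated(tab$protein_id))
    stop("duplicate protein_id in SC table: ",
         tab$protein_id[duplicated(tab$protein_id)][1])
  for (cc in c(ip_cols, ctl_cols)) {
    v <- tab[[cc]]
    v[is.na(v)] <- 0L
    if (any(v < 0)) stop("negative spectral count in column ", cc)
    tab[[cc]] <- as.integer(v)
  }
  tab[, c("protein_id", ip_cols, ctl_cols)]
}

#' Write a spectral-count table
#' @param tab SC data frame as returned by [read_sc_table()]
#' @param path output path
#' @export
write_sc_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a differential-expression table
#'
#' Tab-delimited with header columns `gene_id`, `baseMean`, `log2FoldChange`,
#' `padj`. `padj` given as `NA` is kept missing (not coerced to 0); any other
#' unparseable numeric is a hard error reporting the offending line.
#'
#' @param path TSV file
#' @return data frame with `gene_id`, `baseMean`, `log2fc`, `padj`
#' @export
read_de_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                           na.strings = "NA", colClasses = "character")
  need <- c("gene_id", "baseMean", "log2FoldChange", "padj")
  if (!all(need %in% names(tab)))
    stop("DE table needs columns ", paste(need, collapse = ", "), ": ", path)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop("unparseable ", col, " at line ", bad[1] + 1L, " of ", path)
    v
  }
  out <- data.frame(gene_id = tab$gene_id,
                    baseMean = num("baseMean"),
                    log2fc = num("log2FoldChange"),
                    padj = num("padj"),
                    stringsAsFactors = FALSE)
  if (any(out$baseMean < 0, na.rm = TRUE)) stop("negative baseMean in ", path)
  if (any(out$padj < 0 | out$padj > 1, na.rm = TRUE)) stop("padj outside [0,1] in ", path)
  out
}

#' Write a differential-expression table
#' @param de data frame as returned by [read_de_table()]
#' @param path output path
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(gene_id = de$gene_id, baseMean = de$baseMean,
                    log2FoldChange = de$log2fc, padj = de$padj)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a minimal gene-start table
#'
#' Tab-delimited with header `gene_id`, `chrom`, `start`, `strand`; `start`
#' is the strand-resolved 5' end of the gene, 0-based.
#'
#' @param path TSV file
#' @return data frame with those four columns
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "strand")
  if (!all(need %in% names(tab)))
    stop("gene table needs columns ", paste(need, collapse = ", "), ": ", path)
  if (any(tab$start < 0)) stop("negative gene start in ", path)
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be + or - in ", path)
  tab[, need]
}

#' Write a gene-start table
#' @param genes data frame as returned by [read_gene_table()]
#' @param path output path
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "start", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read aligned reads from BED4 (chrom, start, end, mapq)
#'
#' The minimal text representation of an aligned read used throughout: a
#' 0-based half-open interval plus an integer mapping quality in column 4.
#'
#' @param path BED-like file
#' @return data frame with `chrom`, `start`, `end`, `mapq`
#' @export
read_reads_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "mapq"))
  tab$chrom <- as.character(tab$chrom)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$mapq <- as.integer(tab$mapq)
  validate_intervals(tab)
  if (any(tab$mapq < 0L)) stop("negative mapq in ", path)
  tab
}

#' Write aligned reads as BED4
#' @param reads data frame with `chrom`, `start`, `end`, `mapq`
#' @param path output path
#' @export
write_reads_bed <- function(reads, path) {
  utils::write.table(reads[, c("chrom", "start", "end", "mapq")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}
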