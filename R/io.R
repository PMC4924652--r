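## File IO for the formats the pipeline consumes and emits.
## All in-memory intervals are 0-based half-open (BED convention); the
## rtracklayer/GRanges boundary handles the 1-based conversion.

#' Read a TSS annotation (BED6)
#'
#' Column 4 is the gene id, column 6 the strand; the TSS is the single base
#' at `start` (0-based).
#'
#' @param path BED6 file.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("TSS BED6 must have strand '+' or '-' in column 6")
  df <- data.frame(gene_id = gr$name,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   tss = GenomicRanges::start(gr) - 1L,
                   strand = strand,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in TSS BED")
  df
}

#' @rdname read_tss_bed
#' @param tss data.frame as returned by [read_tss_bed()].
#' @export
write_tss_bed <- function(tss, path) {
  check_columns(tss, c("gene_id", "chrom", "tss", "strand"))
  gr <- GenomicRanges::GRanges(tss$chrom,
                               IRanges::IRanges(tss$tss + 1L, width = 1L),
                               strand = tss$strand)
  gr$name <- tss$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write plain interval sets (BED3+)
#'
#' @param path BED file with at least chrom/start/end.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) plus
#'   a `name` column when present.
#' @export
read_bed_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_regions(gr)
  if (!is.null(gr$name)) df$name <- gr$name
  df
}

#' @rdname read_bed_regions
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `name` and `score` columns.
#' @export
write_bed_regions <- function(regions, path) {
  gr <- regions_to_granges(regions)
  if (!is.null(regions$name)) gr$name <- regions$name
  if (!is.null(regions$score)) gr$score <- regions$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write a per-base signal track (bedGraph)
#'
#' @param path bedGraph file.
#' @return data.frame `chrom`, `start`, `end`, `score` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- granges_to_regions(gr)
  df$score <- gr$score
  df
}

#' @rdname read_bedgraph
#' @param track data.frame with `chrom`, `start`, `end`, `score`; adjacent
#'   equal-score runs are collapsed before writing.
#' @export
write_bedgraph <- function(track, path) {
  check_columns(track, c("chrom", "start", "end", "score"))
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  ## collapse book-ended runs of equal score within a chromosome
  if (nrow(track) > 1L) {
    same <- track$chrom[-1L] == track$chrom[-nrow(track)] &
      track$start[-1L] == track$end[-nrow(track)] &
      track$score[-1L] == track$score[-nrow(track)]
    run <- cumsum(c(TRUE, !same))
    track <- data.frame(
      chrom = tapply(track$chrom, run, `[`, 1L),
      start = as.integer(tapply(track$start, run, min)),
      end = as.integer(tapply(track$end, run, max)),
      score = tapply(track$score, run, `[`, 1L),
      stringsAsFactors = FALSE)
  }
  gr <- regions_to_granges(track)
  gr$score <- track$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write transcription-factor peaks (narrowPeak or BED)
#'
#' narrowPeak column 10 is the summit offset from `start`; when absent (or
#' -1) the interval midpoint is used, as the field convention dictates.
#'
#' @param path narrowPeak (BED6+4) or plain BED file.
#' @return data.frame `chrom`, `start`, `end`, `name`, `summit` (absolute
#'   0-based position of the summit base).
#' @export
read_narrowpeak <- function(path) {
  first <- readLines(path, n = 1L)
  ncol <- length(strsplit(first, "\t")[[1L]])
  if (ncol >= 10L) {
    gr <- rtracklayer::import(path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
    df <- granges_to_regions(gr)
    df$name <- gr$name %||% paste0("peak_", seq_along(gr))
    off <- gr$peak
    off[is.na(off) | off < 0L] <- -1L
    df$summit <- ifelse(off >= 0L, df$start + off,
                        df$start + (df$end - df$start) %/% 2L)
  } else {
    df <- read_bed_regions(path)
    if (is.null(df$name)) df$name <- paste0("peak_", seq_len(nrow(df)))
    df$summit <- df$start + (df$end - df$start) %/% 2L
  }
  df$summit <- as.integer(df$summit)
  df
}

#' @rdname read_narrowpeak
#' @param peaks data.frame with `chrom`, `start`, `end`, `name`, `summit`.
#' @export
write_narrowpeak <- function(peaks, path) {
  check_columns(peaks, c("chrom", "start", "end", "name", "summit"))
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    0L, ".", 0, -1, -1,
                    peaks$summit - peaks$start)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write gene-set collections (GMT)
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ", l)
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1L]][1L], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome (FASTA)
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that strips FASTA
#' description text from the sequence names.
#'
#' @param path FASTA file.
#' @return a `DNAStringSet` named by chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[`, "", 1L)
  genome
}
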