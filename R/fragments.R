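## Fragment ingestion and size-class bookkeeping.
##
## A fragment is one sequenced protection event: the template molecule
## between the outer ends of a properly paired read pair. Fragments are
## stored 0-based half-open; the dyad proxy is the integer midpoint
## start + floor(length / 2).

#' Construct a fragment table from coordinates
#'
#' @param chrom,start,end vectors of chromosome, 0-based start, half-open
#'   end.
#' @return data.frame with columns `chrom`, `start`, `end`, `length`,
#'   `midpoint`, satisfying `length == end - start` and
#'   `midpoint == start + floor(length/2)`.
#' @export
fragment_table <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("fragments must satisfy end > start")
  len <- end - start
  data.frame(chrom = as.character(chrom), start = start, end = end,
             length = len, midpoint = start + len %/% 2L,
             stringsAsFactors = FALSE)
}

#' Read paired-end fragments from BED or BAM
#'
#' BED mode expects >= 3 columns (chrom, start, end); malformed lines
#' abort with the offending line number. BAM mode pairs mates by name,
#' keeps proper pairs only, and discards secondary/supplementary
#' alignments and reads below the mapping-quality cutoff (the
#' "non-uniquely-mapped" filter). A `.sam` path is converted on the fly so
#' that plain-text alignments can be ingested directly.
#'
#' Fragments longer than `max_length` are dropped with a warning (gel
#' size selection makes long templates implausible chimeras). Dropped
#' record counts by reason are attached as `attr(x, "dropped")`.
#'
#' @param path input file.
#' @param format `"bed"` or `"bam"`.
#' @param min_mapq mapping-quality cutoff for BAM mode (default 10).
#' @param max_length fragments longer than this are dropped (default 500).
#' @return fragment data.frame (see [fragment_table()]).
#' @export
read_fragments <- function(path, format = c("bed", "bam"), min_mapq = 10L,
                           max_length = 500L) {
  format <- match.arg(format)
  frags <- if (format == "bed") read_fragments_bed(path)
           else read_fragments_bam(path, min_mapq = min_mapq)
  dropped <- attr(frags, "dropped") %||% c()
  too_long <- frags$length > max_length
  if (any(too_long)) {
    warning(sprintf("dropping %d fragment(s) longer than %d bp",
                    sum(too_long), max_length))
    dropped <- c(dropped, too_long = sum(too_long))
    frags <- frags[!too_long, , drop = FALSE]
    rownames(frags) <- NULL
  }
  attr(frags, "dropped") <- dropped
  frags
}

read_fragments_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  fields <- strsplit(lines[keep], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(keep)[which(nf < 3L)[1L]]
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 bad, path))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0L)
    stop(sprintf("malformed BED line %d in %s: bad coordinates",
                 which(keep)[bad[1L]], path))
  fragment_table(chrom, start, end)
}

read_fragments_bam <- function(path, min_mapq = 10L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    path <- bam
  }
  ## first mates of proper pairs with acceptable MAPQ give the template
  flags <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                  isFirstMateRead = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "mpos", "isize", "mapq"))
  rec <- Rsamtools::scanBam(path, param = par)[[1L]]
  n_all <- Rsamtools::countBam(path)$records
  keep <- !is.na(rec$isize) & rec$isize != 0L & rec$mapq >= min_mapq
  chrom <- as.character(rec$rname[keep])
  ## template spans [min(pos, mpos) - 1, min(pos, mpos) - 1 + |TLEN|)
  left <- pmin(rec$pos[keep], rec$mpos[keep]) - 1L
  frags <- fragment_table(chrom, left, left + abs(rec$isize[keep]))
  n_frag <- nrow(frags)
  attr(frags, "dropped") <- c(not_proper_or_lowmapq = n_all - 2L * n_frag)
  frags
}

#' Fragment size classes
#'
#' The two analysis classes deliberately leave a 125-129 bp gap:
#' sub-nucleosomal protections are `< 125` bp (floored at 1, or 50 in the
#' simulator), nucleosome-protected fragments are 130-175 bp.
#'
#' @param label `"subnucleosomal"`, `"nucleosomal"` or `"all"`.
#' @return list with `label`, `min_len`, `max_len` (inclusive bounds).
#' @export
size_class <- function(label = c("nucleosomal", "subnucleosomal", "all")) {
  label <- match.arg(label)
  switch(label,
         subnucleosomal = list(label = label, min_len = 1L, max_len = 124L),
         nucleosomal = list(label = label, min_len = 130L, max_len = 175L),
         all = list(label = label, min_len = 1L, max_len = .Machine$integer.max))
}

#' Keep fragments of one size class
#'
#' @param fragments fragment data.frame.
#' @param class a [size_class()] (or its label).
#' @return the retained fragments, order preserved.
#' @export
partition_by_size <- function(fragments, class) {
  if (is.character(class)) class <- size_class(class)
  stopifnot(is.list(class), class$min_len <= class$max_len)
  keep <- fragments$length >= class$min_len & fragments$length <= class$max_len
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "size_class") <- class$label
  out
}

#' Fraction of fragments on capture target
#'
#' Membership uses the fragment midpoint (matching the midpoint-centric
#' downstream analysis); set `mode = "overlap"` for any-overlap
#' membership.
#'
#' @param fragments fragment data.frame.
#' @param capture_regions data.frame `chrom`, `start`, `end`; overlapping
#'   regions are merged first.
#' @param mode `"midpoint"` (default) or `"overlap"`.
#' @return list with `fraction`, `n_on_target`, `n_total`, and
#'   `per_region` counts.
#' @export
on_target_fraction <- function(fragments, capture_regions,
                               mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  if (nrow(fragments) == 0L)
    stop("on-target fraction is undefined for zero fragments")
  regions <- GenomicRanges::reduce(regions_to_granges(capture_regions))
  query <- if (mode == "midpoint") {
    GenomicRanges::GRanges(fragments$chrom,
                           IRanges::IRanges(fragments$midpoint + 1L, width = 1L))
  } else {
    regions_to_granges(fragments)
  }
  hits <- GenomicRanges::countOverlaps(query, regions)
  per_region <- GenomicRanges::countOverlaps(regions, query)
  out_regions <- granges_to_regions(regions)
  out_regions$n_fragments <- per_region
  list(fraction = mean(hits > 0L),
       n_on_target = sum(hits > 0L),
       n_total = nrow(fragments),
       per_region = out_regions)
}

#' Fragment length histogram
#'
#' @param fragments fragment data.frame.
#' @param bin bin width in bp (lengths are floored to multiples of `bin`).
#' @return data.frame `bin_start`, `count`; counts sum to the input size.
#' @export
length_histogram <- function(fragments, bin = 10L) {
  stopifnot(bin >= 1L)
  if (nrow(fragments) == 0L)
    return(data.frame(bin_start = integer(0), count = integer(0)))
  bs <- (fragments$length %/% bin) * bin
  tab <- table(bs)
  data.frame(bin_start = as.integer(names(tab)),
             count = as.integer(tab))
}

#' Write fragments as BED5 (score column = fragment length)
#'
#' @param fragments fragment data.frame.
#' @param path output BED path.
#' @export
write_fragments <- function(fragments, path) {
  check_columns(fragments, c("chrom", "start", "end", "length"))
  out <- data.frame(fragments$chrom, fragments$start, fragments$end,
                    sprintf("frag_%d", seq_len(nrow(fragments))),
                    fragments$length)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
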