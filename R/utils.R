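`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' All stochastic generators in the package draw their randomness from named
#' streams so that, e.g., the fragment simulator for patient 2 does not
#' perturb the stream used for the genome sequence. Sub-seeds are a simple
#' deterministic hash of (seed, tag), kept below 2^31.
#'
#' @param seed integer master seed.
#' @param tag character stream name.
#' @return an integer seed.
#' @export
sub_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

## truncated normal by rejection; bounds are inclusive after rounding
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(integer(0))
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  as.integer(out)
}

## most frequent value (ties broken by smallest)
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

## assert a data.frame has the given columns
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

## 0-based half-open data.frame -> GRanges (1-based closed)
regions_to_granges <- function(df) {
  check_columns(df, c("chrom", "start", "end"), "regions")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_regions <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted architecture classes by clustering.
#' Computed from the contingency-table closed form.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Sequence-capture space reduction
#'
#' Percent of the genome removed by restricting sequencing to the captured
#' TSS windows: `100 * (1 - captured_bp / genome_bp)`. Capturing ~0.05 Gb
#' of TSS windows out of a 3.4 Gb genome is a 98.5% reduction.
#'
#' @param captured_bp base pairs retained by the capture design.
#' @param genome_bp total genome size in base pairs.
#' @return percent reduction (numeric scalar).
#' @export
capture_space_reduction <- function(captured_bp, genome_bp) {
  stopifnot(captured_bp >= 0, genome_bp > 0, captured_bp <= genome_bp)
  100 * (1 - captured_bp / genome_bp)
}

#' Fold enrichment implied by a qPCR cycle-threshold difference
#'
#' Under perfect doubling per PCR cycle a difference of `delta_ct` cycles
#' between on-target and off-target amplicons corresponds to a
#' `2^delta_ct`-fold enrichment; 9 cycles is 512-fold.
#'
#' @param delta_ct cycle-threshold difference (off-target minus on-target).
#' @param efficiency per-cycle amplification factor (2 = perfect doubling).
#' @return fold enrichment (numeric).
#' @export
qpcr_fold_enrichment <- function(delta_ct, efficiency = 2) {
  stopifnot(efficiency > 1)
  efficiency^delta_ct
}
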