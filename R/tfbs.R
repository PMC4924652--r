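## Transcription-factor-related structure: shuffle-based enrichment of TF
## peaks in difference regions, and sub-nucleosomal footprint aggregation
## at peak summits with condition-change estimation.

#' Shuffle TF peaks within capture space
#'
#' Places each peak uniformly at random inside the union of capture
#' regions on its chromosome, preserving its length (so the shuffled
#' length multiset and chromosome assignment match the observed set).
#' Placements are independent across peaks and iterations and
#' deterministic per (seed, iteration).
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `name`,
#'   `summit`), e.g. from [read_narrowpeak()].
#' @param capture_regions data.frame `chrom`, `start`, `end`; merged
#'   internally.
#' @param n_iter number of shuffle iterations (default 100).
#' @param seed RNG seed.
#' @return data.frame like `peaks` with an extra `iteration` column;
#'   summits are re-derived as interval midpoints.
#' @export
shuffle_peaks <- function(peaks, capture_regions, n_iter = 100L, seed = 1L) {
  check_columns(peaks, c("chrom", "start", "end"))
  stopifnot(n_iter >= 1L)
  regions <- granges_to_regions(
    GenomicRanges::reduce(regions_to_granges(capture_regions)))
  by_chrom <- split(regions, regions$chrom)
  lens <- peaks$end - peaks$start
  out <- vector("list", n_iter)
  with_seed(as.integer(seed), {
    for (it in seq_len(n_iter)) {
      new_start <- integer(nrow(peaks))
      for (i in seq_len(nrow(peaks))) {
        reg <- by_chrom[[peaks$chrom[i]]]
        if (is.null(reg)) stop("no capture region on chromosome ",
                               peaks$chrom[i])
        fit <- reg$end - reg$start - lens[i] + 1L   # valid starts per region
        ok <- fit > 0L
        if (!any(ok))
          stop("peak ", peaks$name[i] %||% i,
               " is longer than every capture region on its chromosome")
        j <- if (sum(ok) == 1L) which(ok)
             else sample(which(ok), 1L, prob = fit[ok])
        new_start[i] <- reg$start[j] + sample.int(fit[j], 1L) - 1L
      }
      df <- peaks
      df$start <- new_start
      df$end <- new_start + lens
      df$summit <- as.integer(df$start + lens %/% 2L)
      df$iteration <- it
      out[[it]] <- df
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## count peaks whose summit lies inside any region
count_summits_in <- function(peaks, regions_gr) {
  if (nrow(peaks) == 0L) return(0L)
  summits <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$summit + 1L, width = 1L))
  sum(GenomicRanges::countOverlaps(summits, regions_gr) > 0L)
}

#' Observed/shuffled TFBS enrichment ratio in difference regions
#'
#' Counts peak summits falling in any difference region, for the observed
#' set and for each shuffle iteration. `ratio = observed /
#' mean(shuffled)`; values above 1 indicate enrichment and below 1
#' depletion of binding sites in the regions. The empirical interval is
#' the (alpha/2, 1-alpha/2) quantile range of the shuffled counts, also
#' expressed on the ratio scale.
#'
#' @param regions difference-region data.frame (`chrom`, `start`, `end`).
#' @param observed observed peak data.frame with `summit`.
#' @param shuffled shuffled peaks from [shuffle_peaks()] (with an
#'   `iteration` column), or a list of peak data.frames.
#' @param conf confidence level of the empirical interval (default 0.95).
#' @return list with `ratio`, `observed_count`, `shuffled_mean`,
#'   `interval_counts`, `interval_ratio`, `inside` (is the observed count
#'   within the shuffled interval), `n_iter`, `infinite` flag.
#' @export
enrichment_ratio <- function(regions, observed, shuffled, conf = 0.95) {
  if (nrow(regions) == 0L) stop("empty difference-region set")
  if (is.data.frame(shuffled)) {
    check_columns(shuffled, c("chrom", "summit", "iteration"))
    shuffled <- split(shuffled, shuffled$iteration)
  }
  if (length(shuffled) < 2L) stop("need >= 2 shuffle iterations")
  gr <- GenomicRanges::reduce(regions_to_granges(regions))
  obs <- count_summits_in(observed, gr)
  shuf <- vapply(shuffled, count_summits_in, integer(1), regions_gr = gr)
  m <- mean(shuf)
  alpha <- 1 - conf
  iv <- unname(quantile(shuf, c(alpha / 2, 1 - alpha / 2), type = 1L))
  list(ratio = if (m == 0) Inf else obs / m,
       observed_count = obs,
       shuffled_mean = m,
       interval_counts = iv,
       interval_ratio = if (m == 0) c(NA_real_, NA_real_) else iv / m,
       inside = obs >= iv[1L] && obs <= iv[2L],
       n_iter = length(shuf),
       infinite = m == 0)
}

#' Aggregate fragment-midpoint footprint at peak summits
#'
#' Per-position counts of fragment midpoints at offsets relative to each
#' peak summit, summed over peaks and scaled to midpoints per million
#' fragments. Pass fragments already restricted to a size class
#' ([partition_by_size()]); `total` should be the sample's total fragment
#' count so that footprints from different conditions are comparable (the
#' class-restricted count is used when `total` is `NA`).
#'
#' @param fragments fragment data.frame (one size class).
#' @param peaks peak data.frame with `summit`.
#' @param flank half-window around the summit in bp (default 500).
#' @param total normalization denominator; default
#'   `attr(fragments, "total_fragments")`, falling back to
#'   `nrow(fragments)`.
#' @return object of class `aggregate_footprint`: data.frame `offset`,
#'   `count`, `signal`; attributes `n_peaks`, `total`, `size_class`.
#' @export
aggregate_footprint <- function(fragments, peaks, flank = 500L,
                                total = NULL) {
  if (nrow(fragments) == 0L)
    stop("no fragments in the requested size class")
  check_columns(peaks, c("chrom", "summit"))
  total <- total %||% attr(fragments, "total_fragments") %||% nrow(fragments)
  mids <- midpoints_by_chrom(fragments)
  offsets <- seq.int(-flank, flank)
  counts <- integer(length(offsets))
  for (i in seq_len(nrow(peaks))) {
    m <- mids[[peaks$chrom[i]]]
    if (is.null(m)) next
    lo <- peaks$summit[i] - flank
    hi <- peaks$summit[i] + flank
    sel <- m[m >= lo & m <= hi]
    if (length(sel) == 0L) next
    tab <- tabulate(sel - lo + 1L, nbins = length(offsets))
    counts <- counts + tab
  }
  structure(data.frame(offset = offsets, count = counts,
                       signal = counts * 1e6 / total),
            n_peaks = nrow(peaks), total = total,
            size_class = attr(fragments, "size_class"),
            class = c("aggregate_footprint", "data.frame"))
}

#' Percent binding change between conditions at TF footprints
#'
#' Sums the sub-nucleosomal footprint signal over offsets within
#' `core_halfwidth` of the summit and reports
#' `100 * (S_tumor - S_normal) / S_normal`, the convention in which a
#' planted tumor/normal multiplier of 0.87 reads as a 13% decrease.
#'
#' @param normal,tumor [aggregate_footprint()] objects computed over the
#'   identical peak set and offset grid.
#' @param core_halfwidth half-width of the summit core in bp (default
#'   100).
#' @return list with `percent_change`, `s_normal`, `s_tumor`,
#'   `core_halfwidth`.
#' @export
binding_change <- function(normal, tumor, core_halfwidth = 100L) {
  if (!identical(normal$offset, tumor$offset))
    stop("footprints must share one offset grid")
  if (!identical(attr(normal, "n_peaks"), attr(tumor, "n_peaks")))
    stop("footprints must be computed over the identical peak set")
  core <- abs(normal$offset) <= core_halfwidth
  s_n <- sum(normal$signal[core])
  s_t <- sum(tumor$signal[core])
  if (s_n == 0) stop("normal core signal is zero; change undefined")
  list(percent_change = 100 * (s_t - s_n) / s_n,
       s_normal = s_n, s_tumor = s_t,
       core_halfwidth = core_halfwidth)
}
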