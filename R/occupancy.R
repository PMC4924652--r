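## Occupancy and dyad-density profiling.
##
## Two signal representations are supported throughout the package:
##  * per-bp "fpm" coverage: fragments per million covering each base of
##    the probed regions;
##  * the windowed dyad grid: fragment midpoints summed in 100-bp windows
##    at a 10-bp step, the processed representation used for correlation,
##    clustering and model comparison.

#' Construct a signal matrix (genes x positions)
#'
#' Rows are genes, columns are positions relative to the TSS in the
#' direction of transcription (minus-strand rows are already reversed, so
#' positive positions are always downstream of the TSS).
#'
#' @param values numeric matrix with rownames = gene ids.
#' @param positions integer vector of relative positions (bp), one per
#'   column.
#' @param units signal units, e.g. `"fpm"` or `"dyads_per_million"`.
#' @param grid_step spacing of the positional grid in bp (1 = per-bp).
#' @return a `signal_matrix` object.
#' @export
signal_matrix <- function(values, positions, units = "fpm", grid_step = 1L) {
  stopifnot(is.matrix(values), ncol(values) == length(positions),
            !is.null(rownames(values)))
  if (any(!is.finite(values)) || any(values < 0))
    stop("signal values must be finite and non-negative")
  structure(values, positions = as.integer(positions), units = units,
            grid_step = as.integer(grid_step),
            class = c("signal_matrix", class(values)))
}

#' @export
print.signal_matrix <- function(x, ...) {
  pos <- attr(x, "positions")
  cat(sprintf("signal_matrix: %d genes x %d positions [%d..%d bp, step %d], units=%s\n",
              nrow(x), ncol(x), min(pos), max(pos), attr(x, "grid_step"),
              attr(x, "units")))
  invisible(x)
}

#' Positions of a signal matrix
#' @param x a `signal_matrix`.
#' @return integer vector of TSS-relative positions.
#' @export
positions <- function(x) attr(x, "positions")

## fragment coverage as an RleList, seqlengths padded to cover `regions`
fragment_coverage <- function(fragments, regions = NULL) {
  ends <- tapply(fragments$end, fragments$chrom, max)
  if (!is.null(regions)) {
    rend <- tapply(regions$end, regions$chrom, max)
    all_chroms <- union(names(ends), names(rend))
    ends <- pmax(ends[all_chroms], rend[all_chroms], na.rm = TRUE)
    names(ends) <- all_chroms
  }
  ends <- setNames(as.integer(ends), names(ends))
  gr <- GenomicRanges::GRanges(
    fragments$chrom,
    IRanges::IRanges(fragments$start + 1L, fragments$end),
    seqlengths = ends + 1L)
  GenomicRanges::coverage(gr)
}

#' Per-bp occupancy (fragments per million) over probed regions
#'
#' `value(bp) = 10^6 * (# fragments covering bp) / total`, where `total`
#' defaults to the number of input fragments; pass the on-target fragment
#' count to normalize by capture-space totals. Positions outside
#' `regions` are absent from the output.
#'
#' @param fragments fragment data.frame.
#' @param regions data.frame `chrom`, `start`, `end` (the probed regions).
#' @param total normalization denominator (fragment count).
#' @return bedGraph-style data.frame `chrom`, `start`, `end`, `score`
#'   with equal-value runs collapsed; zero runs inside regions are kept.
#' @export
occupancy_profile <- function(fragments, regions, total = nrow(fragments)) {
  if (nrow(fragments) == 0L || total <= 0L)
    stop("occupancy_profile needs a positive fragment total")
  cov <- fragment_coverage(fragments, regions)
  regions <- granges_to_regions(
    GenomicRanges::reduce(regions_to_granges(regions)))
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    v <- cov[[chrom]][(regions$start[i] + 1L):regions$end[i]]
    rl <- S4Vectors::runLength(v); rv <- S4Vectors::runValue(v)
    ends <- regions$start[i] + cumsum(rl)
    out[[i]] <- data.frame(chrom = chrom, start = ends - rl, end = ends,
                           score = rv * 1e6 / total,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "total") <- total
  res
}

## sorted midpoints split by chromosome
midpoints_by_chrom <- function(fragments) {
  lapply(split(fragments$midpoint, fragments$chrom), sort)
}

## counts of midpoints in [lo, hi) given the sorted vector
count_in_range <- function(sorted_mids, lo, hi) {
  findInterval(hi - 1L, sorted_mids) - findInterval(lo - 1L, sorted_mids)
}

#' Windowed dyad (fragment midpoint) track
#'
#' Sums fragment midpoints in `window`-bp windows advanced by `step` bp;
#' window starts are the non-negative multiples of `step` and the value is
#' reported at the window center.
#'
#' @param fragments fragment data.frame.
#' @param window window width in bp (default 100).
#' @param step step size in bp (default 10).
#' @param normalize if `TRUE`, counts are scaled to dyads per million.
#' @param total normalization denominator when `normalize = TRUE`.
#' @return data.frame `chrom`, `start`, `end`, `center`, `count`, `value`.
#' @export
dyad_track <- function(fragments, window = 100L, step = 10L,
                       normalize = FALSE, total = nrow(fragments)) {
  stopifnot(window >= step, step >= 1L)
  mids <- midpoints_by_chrom(fragments)
  out <- lapply(names(mids), function(chrom) {
    m <- mids[[chrom]]
    if (length(m) == 0L) return(NULL)
    starts <- seq.int(0L, (max(m) %/% step) * step, by = step)
    counts <- count_in_range(m, starts, starts + window)
    data.frame(chrom = chrom, start = starts, end = starts + window,
               center = starts + window %/% 2L, count = counts,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), center = integer(0),
                      count = integer(0))
  res$value <- if (normalize) res$count * 1e6 / total else res$count
  rownames(res) <- NULL
  res
}

#' Strand-oriented per-gene signal matrix around TSSs
#'
#' Builds a genes x positions matrix directly from fragments, on either
#' the windowed dyad grid (default: midpoints in 100-bp windows at 10-bp
#' steps centered on each grid position) or per-bp fpm coverage.
#' Minus-strand rows are reversed so positive positions run downstream in
#' the direction of transcription. Windows clipped at chromosome edges
#' are zero-filled and the affected genes recorded in
#' `attr(x, "clipped_genes")`.
#'
#' @param fragments fragment data.frame.
#' @param tss TSS table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param flank half-window in bp (default 1000).
#' @param grid `"dyad"` or `"bp"`.
#' @param window,step dyad-grid smoothing parameters.
#' @param normalize scale to per-million counts (default `TRUE`).
#' @param total normalization denominator; defaults to the number of
#'   input fragments (pass the on-target count for capture-space fpm).
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   detect clipped windows.
#' @return a [signal_matrix()].
#' @export
tss_matrix <- function(fragments, tss, flank = 1000L,
                       grid = c("dyad", "bp"), window = 100L, step = 10L,
                       normalize = TRUE, total = nrow(fragments),
                       chrom_sizes = NULL) {
  grid <- match.arg(grid)
  check_columns(tss, c("gene_id", "chrom", "tss", "strand"))
  missing_chrom <- setdiff(tss$chrom, unique(fragments$chrom))
  scale <- if (normalize) 1e6 / total else 1
  if (grid == "dyad") {
    offsets <- seq.int(-flank, flank, by = step)
    mids <- midpoints_by_chrom(fragments)
    half <- window %/% 2L
    values <- matrix(0, nrow = nrow(tss), ncol = length(offsets),
                     dimnames = list(tss$gene_id, NULL))
    for (i in seq_len(nrow(tss))) {
      m <- mids[[tss$chrom[i]]]
      if (is.null(m)) next
      centers <- if (tss$strand[i] == "+") tss$tss[i] + offsets
                 else tss$tss[i] - offsets
      values[i, ] <- count_in_range(m, centers - half, centers + half)
    }
    units <- if (normalize) "dyads_per_million" else "dyad_count"
    out <- signal_matrix(values * scale, offsets, units = units,
                         grid_step = step)
  } else {
    offsets <- seq.int(-flank, flank - 1L)
    cov <- fragment_coverage(fragments)
    values <- matrix(0, nrow = nrow(tss), ncol = length(offsets),
                     dimnames = list(tss$gene_id, NULL))
    for (i in seq_len(nrow(tss))) {
      chrom <- tss$chrom[i]
      if (!chrom %in% names(cov)) next
      pos <- if (tss$strand[i] == "+") tss$tss[i] + offsets
             else tss$tss[i] - offsets
      ok <- pos >= 0L & pos < length(cov[[chrom]])
      v <- numeric(length(offsets))
      v[ok] <- as.numeric(cov[[chrom]][pos[ok] + 1L])
      values[i, ] <- v
    }
    units <- if (normalize) "fpm" else "coverage"
    out <- signal_matrix(values * scale, offsets, units = units,
                         grid_step = 1L)
  }
  clipped <- character(0)
  if (!is.null(chrom_sizes)) {
    lo <- tss$tss - flank
    hi <- tss$tss + flank
    clipped <- tss$gene_id[lo < 0L | hi > chrom_sizes[tss$chrom]]
  }
  attr(out, "clipped_genes") <- clipped
  attr(out, "total") <- total
  out
}

#' Column-wise average profile of a signal matrix
#'
#' @param matrix a [signal_matrix()].
#' @param genes optional subset of gene ids (must all be present).
#' @return data.frame `position`, `mean`, `sd`, `n`.
#' @export
average_profile <- function(matrix, genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(matrix))
    if (length(missing) > 0L)
      stop("genes absent from matrix: ", paste(missing, collapse = ", "))
    if (length(genes) == 0L) stop("empty gene subset")
    m <- matrix[genes, , drop = FALSE]
  } else m <- matrix
  if (nrow(m) == 0L) stop("empty gene subset")
  data.frame(position = attr(matrix, "positions"),
             mean = colMeans(m),
             sd = apply(m, 2L, sd),
             n = nrow(m))
}
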