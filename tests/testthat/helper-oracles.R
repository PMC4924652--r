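## Brute-force reference implementations, kept deliberately naive and
## independent of the package's internals.

## per-bp coverage at given positions by scanning every fragment
oracle_coverage <- function(fragments, chrom, pos) {
  vapply(pos, function(p) {
    sum(fragments$chrom == chrom & fragments$start <= p & fragments$end > p)
  }, numeric(1))
}

## midpoint count in [start, start + window) by direct comparison
oracle_window_counts <- function(mids, starts, window) {
  vapply(starts, function(s) sum(mids >= s & mids < s + window), numeric(1))
}

## maximal runs with |x| > threshold via a linear scan
oracle_regions <- function(values, threshold) {
  out <- NULL
  in_run <- FALSE
  for (i in seq_along(values)) {
    if (abs(values[i]) > threshold) {
      if (!in_run) { first <- i; in_run <- TRUE }
      last <- i
    } else if (in_run) {
      out <- rbind(out, c(first, last)); in_run <- FALSE
    }
  }
  if (in_run) out <- rbind(out, c(first, last))
  out
}

## interval union via per-bp boolean marking
oracle_merge <- function(regions, max_bp = 10000L) {
  covered <- logical(max_bp)
  for (i in seq_len(nrow(regions)))
    covered[(regions$start[i] + 1L):regions$end[i]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values] - 1L, end = ends[r$values])
}

## footprint profile by a double loop over (peak, fragment midpoint)
oracle_footprint <- function(mids, summits, flank) {
  offsets <- seq.int(-flank, flank)
  counts <- integer(length(offsets))
  for (s in summits) for (m in mids) {
    d <- m - s
    if (abs(d) <= flank) counts[d + flank + 1L] <- counts[d + flank + 1L] + 1L
  }
  data.frame(offset = offsets, count = counts)
}

## upper-tail hypergeometric by full enumeration of draws
oracle_hyper_upper <- function(overlap, set_size, universe, query_size) {
  draws <- utils::combn(universe, query_size)
  hits <- colSums(draws <= set_size)   # items 1..set_size are the set
  mean(hits >= overlap)
}

planted_templates <- function(ann) {
  setNames(ann$design$template, ann$design$gene_id)
}
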