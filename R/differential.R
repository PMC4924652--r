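## Tumor-versus-normal redistribution analysis: difference maps,
## correlation-based change calling, cross-patient intersection,
## difference-region thresholding, and gene-set enrichment.

#' Normal-minus-tumor difference map
#'
#' Positive values mean higher occupancy in the normal sample, negative
#' values higher occupancy in the tumor. The per-gene mean difference (the
#' heatmap sort key) is attached as `attr(x, "sort_key")`.
#'
#' @param normal,tumor [signal_matrix()] objects with identical genes and
#'   positions.
#' @return a `signal-matrix`-shaped numeric matrix of differences (class
#'   `difference_map`).
#' @export
difference_map <- function(normal, tumor) {
  if (!identical(dim(normal), dim(tumor)) ||
      !identical(rownames(normal), rownames(tumor)) ||
      !identical(attr(normal, "positions"), attr(tumor, "positions")))
    stop("normal and tumor matrices must share genes and positions")
  d <- unclass(normal) - unclass(tumor)
  structure(d, positions = attr(normal, "positions"),
            grid_step = attr(normal, "grid_step"),
            sort_key = rowMeans(d),
            class = c("difference_map", "matrix", "array"))
}

#' Per-gene normal-vs-tumor correlation change calling
#'
#' Computes the Pearson correlation between the normal and tumor signal
#' over each gene's TSS window and flags the least-correlated quantile as
#' changed. Exactly `floor(quantile * n_eligible)` genes are called, ties
#' broken by ascending r then gene id, for reproducibility. Genes with
#' zero variance in either sample are excluded and listed in
#' `attr(x, "excluded")`.
#'
#' @param normal,tumor [signal_matrix()] objects (same genes/positions).
#' @param quantile fraction of genes to call changed (default 0.20).
#' @return data.frame `gene_id`, `r`, `changed`.
#' @export
correlation_change_call <- function(normal, tumor, quantile = 0.20) {
  if (!identical(rownames(normal), rownames(tumor)) ||
      !identical(dim(normal), dim(tumor)))
    stop("normal and tumor matrices must share genes and positions")
  sd_n <- apply(normal, 1L, sd)
  sd_t <- apply(tumor, 1L, sd)
  eligible <- sd_n > 0 & sd_t > 0
  if (!any(eligible))
    stop("all genes have zero variance in at least one sample")
  genes <- rownames(normal)[eligible]
  r <- vapply(which(eligible), function(i)
    cor(normal[i, ], tumor[i, ]), numeric(1))
  ord <- order(r, genes)
  n_changed <- floor(quantile * length(genes))
  changed <- logical(length(genes))
  changed[ord[seq_len(n_changed)]] <- TRUE
  out <- data.frame(gene_id = genes, r = r, changed = changed,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- rownames(normal)[!eligible]
  attr(out, "quantile") <- quantile
  out
}

#' Intersect changed-gene calls across patients
#'
#' @param calls list of >= 2 change-call tables from
#'   [correlation_change_call()] over the same gene universe.
#' @return list with `shared` (genes changed in every patient),
#'   `pairwise` (per-pair overlap counts, expected overlap under
#'   independence, and upper-tail hypergeometric p), and `n_universe`.
#' @export
intersect_changed <- function(calls) {
  stopifnot(is.list(calls), length(calls) >= 2L)
  universe <- sort(calls[[1L]]$gene_id)
  for (cc in calls[-1L])
    if (!identical(sort(cc$gene_id), universe))
      stop("change-call tables must share one gene universe")
  changed_sets <- lapply(calls, function(cc) cc$gene_id[cc$changed])
  shared <- Reduce(intersect, changed_sets)
  N <- length(universe)
  idx <- utils::combn(length(calls), 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(idx)), function(j) {
    a <- changed_sets[[idx[1L, j]]]; b <- changed_sets[[idx[2L, j]]]
    ov <- length(intersect(a, b))
    data.frame(sample_a = idx[1L, j], sample_b = idx[2L, j],
               overlap = ov,
               expected = length(a) * length(b) / N,
               p = phyper(ov - 1L, length(a), N - length(a), length(b),
                          lower.tail = FALSE))
  }))
  list(shared = sort(shared), pairwise = pairwise, n_universe = N)
}

## maximal runs where threshold is exceeded, on an index grid
region_runs <- function(values, threshold, min_len = 1L, two_sided = TRUE) {
  x <- if (two_sided) abs(values) else values
  above <- !is.na(x) & x > threshold
  if (!any(above))
    return(data.frame(first = integer(0), last = integer(0),
                      max_abs = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(first = starts[keep], last = ends[keep],
             max_abs = vapply(which(keep), function(k)
               max(abs(values[starts[k]:ends[k]])), numeric(1)))
}

#' Call difference regions by thresholding a difference track
#'
#' Emits maximal runs of consecutive grid positions whose (absolute)
#' difference exceeds `threshold`. The default threshold of 5 is on the
#' per-million-normalized difference scale. With a [difference_map()] and
#' a TSS table, runs are mapped back to genomic coordinates (each grid
#' position represents `[pos, pos + grid_step)`); with a plain numeric
#' vector, `chrom`/`origin` give the track location.
#'
#' @param diff a `difference_map` or numeric vector.
#' @param tss TSS table (required for the matrix method).
#' @param threshold positive difference threshold (default 5).
#' @param min_len minimum run length in grid positions (default 1).
#' @param two_sided threshold `|difference|` (default) or the signed value.
#' @param patient_id identifier recorded with each region.
#' @param chrom,origin,step track location for the vector method.
#' @return data.frame `chrom`, `start`, `end`, `max_abs_difference`,
#'   `patient_id` (and `gene_id` for the matrix method).
#' @export
call_difference_regions <- function(diff, tss = NULL, threshold = 5,
                                    min_len = 1L, two_sided = TRUE,
                                    patient_id = "patient",
                                    chrom = "chr", origin = 0L, step = 1L) {
  stopifnot(threshold > 0)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), max_abs_difference = numeric(0),
                      patient_id = character(0))
  if (is.matrix(diff)) {
    if (is.null(tss)) stop("tss table required for a difference map")
    check_columns(tss, c("gene_id", "chrom", "tss", "strand"))
    offsets <- attr(diff, "positions")
    gstep <- attr(diff, "grid_step") %||% 1L
    out <- lapply(seq_len(nrow(diff)), function(i) {
      runs <- region_runs(diff[i, ], threshold, min_len, two_sided)
      if (nrow(runs) == 0L) return(NULL)
      g <- match(rownames(diff)[i], tss$gene_id)
      if (is.na(g)) stop("gene absent from annotation: ", rownames(diff)[i])
      if (tss$strand[g] == "+") {
        gs <- tss$tss[g] + offsets[runs$first]
        ge <- tss$tss[g] + offsets[runs$last] + gstep
      } else {
        gs <- tss$tss[g] - offsets[runs$last]
        ge <- tss$tss[g] - offsets[runs$first] + gstep
      }
      data.frame(chrom = tss$chrom[g], start = gs, end = ge,
                 max_abs_difference = runs$max_abs,
                 patient_id = patient_id, gene_id = rownames(diff)[i],
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    if (is.null(res)) res <- cbind(empty, gene_id = character(0))
  } else {
    runs <- region_runs(diff, threshold, min_len, two_sided)
    res <- data.frame(chrom = rep(chrom, nrow(runs)),
                      start = origin + (runs$first - 1L) * step,
                      end = origin + (runs$last - 1L) * step + step,
                      max_abs_difference = runs$max_abs,
                      patient_id = rep(patient_id, nrow(runs)),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Merge difference regions across patients
#'
#' Overlapping or book-ended intervals from any patients are merged into
#' maximal intervals; each merged region lists its contributing patients.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `patient_id`.
#' @return data.frame `chrom`, `start`, `end`, `patients`, `n_patients`.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), patients = character(0),
                      n_patients = integer(0)))
  gr <- regions_to_granges(regions)
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  pid <- regions$patient_id %||% rep("patient", nrow(regions))
  contribs <- split(pid[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
  out <- granges_to_regions(merged)
  out$patients <- vapply(seq_len(nrow(out)), function(i) {
    paste(sort(unique(contribs[[as.character(i)]])), collapse = ",")
  }, "")
  out$n_patients <- vapply(strsplit(out$patients, ","), length, 1L)
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and each collection set (intersected with the universe), with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param query_genes character vector of query gene ids (subset of
#'   `universe`).
#' @param universe character vector of all testable gene ids.
#' @param collections named list of gene sets (e.g. from [read_gmt()]).
#' @return data.frame `set`, `set_size`, `overlap`, `expected`, `p`, `q`,
#'   sorted by p.
#' @export
geneset_enrichment <- function(query_genes, universe, collections) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe))
    stop("query genes must be a subset of the universe")
  k <- length(query_genes)
  N <- length(universe)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(collections[[nm]], universe)
    m <- length(set)
    ov <- length(intersect(query_genes, set))
    data.frame(set = nm, set_size = m, overlap = ov,
               expected = k * m / N,
               p = if (m == 0L) 1 else
                 phyper(ov - 1L, m, N - m, k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
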