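## Sequence-level analyses: A/T dinucleotide positional periodicity of
## protected fragments, and agreement of measured profiles with a
## DNA-encoded nucleosome-occupancy model track.

#' Positional dinucleotide frequency of protected fragments
#'
#' For fragments of exactly `length` bp (the canonical 150 bp
#' nucleosome-protected size; set `relax` for sparse data), computes at
#' each position p the fraction of fragments whose bases (p, p+1) form
#' one of the pooled dinucleotide classes (default AA/TT/AT/TA).
#' Fragments with a `strand` column equal to `-` are reverse-complemented
#' before counting; the pooled A/T classes are strand-symmetric so this
#' only matters for custom class sets.
#'
#' @param fragments fragment data.frame.
#' @param genome a `DNAStringSet` (or FASTA path) covering all fragments.
#' @param length fragment length retained (default 150).
#' @param classes dinucleotides counted as a pooled class.
#' @param relax half-width of the accepted length window (default 0 =
#'   exactly `length`; retained fragments are trimmed/centered to
#'   `length`).
#' @return object of class `dinuc_profile`: data.frame `position`
#'   (0-based along the fragment), `frequency`; attributes `n_fragments`,
#'   `classes`.
#' @export
dinuc_profile <- function(fragments, genome, length = 150L,
                          classes = c("AA", "TT", "AT", "TA"),
                          relax = 0L) {
  if (is.character(genome)) genome <- read_genome(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  keep <- abs(fragments$length - length) <= relax
  frags <- fragments[keep, , drop = FALSE]
  if (nrow(frags) == 0L)
    stop("no fragments of length ", length, " (+/- ", relax, ")")
  ## center-trim relaxed fragments to exactly `length`
  shift <- (frags$length - length) %/% 2L
  start <- frags$start + shift
  end <- start + length
  bad <- !(frags$chrom %in% names(genome)) | start < 0L |
    end > Biostrings::width(genome)[match(frags$chrom, names(genome))]
  if (any(bad, na.rm = TRUE) || anyNA(bad))
    stop("fragment(s) outside the supplied genome")
  seqs <- character(nrow(frags))
  for (chrom in unique(frags$chrom)) {
    i <- which(frags$chrom == chrom)
    v <- Biostrings::Views(genome[[chrom]],
                           start = start[i] + 1L, end = end[i])
    seqs[i] <- as.character(v)
  }
  if (!is.null(frags$strand)) {
    neg <- which(frags$strand == "-")
    if (length(neg) > 0L)
      seqs[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[neg])))
  }
  n_pos <- length - 1L
  freq <- vapply(seq_len(n_pos), function(p) {
    mean(substr(seqs, p, p + 1L) %in% classes)
  }, numeric(1))
  structure(data.frame(position = seq_len(n_pos) - 1L, frequency = freq),
            n_fragments = nrow(frags), classes = classes,
            class = c("dinuc_profile", "data.frame"))
}

#' Dominant period of a positional frequency profile
#'
#' Detrends the profile (removing its linear trend), computes the
#' autocorrelation, and reports the lag of the first significant local
#' autocorrelation maximum within `lag_range` (default 5-25 bp, bracketing
#' the ~10 bp helical repeat). A flat or aperiodic profile yields
#' `detected = FALSE` and `period = NA` rather than an error;
#' significance uses a Bonferroni-corrected white-noise band at level
#' `alpha`.
#'
#' @param profile a `dinuc_profile` or numeric vector.
#' @param lag_range integer c(min, max) lag window in bp.
#' @param alpha familywise significance level of the white-noise band.
#' @return list with `period`, `detected`, `acf` (data.frame lag, acf),
#'   `threshold`.
#' @export
estimate_period <- function(profile, lag_range = c(5L, 25L), alpha = 0.02) {
  x <- if (inherits(profile, "dinuc_profile")) profile$frequency
       else as.numeric(profile)
  stopifnot(length(x) >= 3L * lag_range[1L])
  lag_max <- min(lag_range[2L], length(x) - 2L)
  detr <- resid(lm(x ~ seq_along(x)))
  none <- list(period = NA_integer_, detected = FALSE,
               acf = data.frame(lag = integer(0), acf = numeric(0)),
               threshold = NA_real_)
  ## flat up to the linear trend (within float noise): nothing to detect
  if (sd(detr) <= 1e-10 * max(sd(x), .Machine$double.eps)) return(none)
  a <- as.numeric(acf(detr, lag.max = lag_max, plot = FALSE,
                      demean = TRUE)$acf)[-1L]  # drop lag 0
  lags <- seq_len(lag_max)
  n_cand <- sum(lags >= lag_range[1L] & lags <= lag_range[2L])
  threshold <- qnorm(1 - alpha / (2 * n_cand)) / sqrt(length(x))
  ## local maxima of the autocorrelation
  is_max <- vapply(seq_along(a), function(k) {
    left <- if (k == 1L) TRUE else a[k] > a[k - 1L]
    right <- if (k == length(a)) TRUE else a[k] >= a[k + 1L]
    left && right
  }, logical(1))
  cand <- which(is_max & lags >= lag_range[1L] & lags <= lag_range[2L] &
                  a > threshold)
  out <- list(period = if (length(cand) > 0L) lags[cand[1L]] else NA_integer_,
              detected = length(cand) > 0L,
              acf = data.frame(lag = lags, acf = a),
              threshold = threshold)
  out
}

## bin-mean resample a per-bp vector onto a coarser grid centered on
## `offsets` (window = step); partially covered edge bins use the
## covered bases only
bin_mean <- function(values, positions, offsets, step) {
  vapply(offsets, function(o) {
    sel <- positions >= o - step %/% 2L & positions < o + (step + 1L) %/% 2L
    mean(values[sel], na.rm = TRUE)
  }, numeric(1))
}

#' Agreement of measured profiles with a DNA-encoded occupancy model
#'
#' For each gene, correlates the normal and the tumor profile with the
#' DNA-encoded nucleosome-occupancy model over the TSS window and reports
#' which condition agrees better with the sequence-preferred positions.
#' The summary gives the fraction of genes where the tumor is closer to
#' the model (`r_tumor > r_normal`) and the percent change of the mean
#' correlation, `100 * (mean r_tumor - mean r_normal) / |mean r_normal|`.
#'
#' @param normal,tumor [signal_matrix()] objects (same genes/positions).
#' @param model either a [signal_matrix()] of model scores on the same
#'   genes, or a bedGraph data.frame (then `tss` is required and the
#'   model is resampled onto the matrix grid by bin means).
#' @param gene_subset optional gene ids to restrict to (e.g. the changed
#'   set).
#' @param tss TSS table, required when `model` is a bedGraph.
#' @return list with `table` (gene_id, r_normal, r_tumor, tumor_closer),
#'   `summary` (fraction_tumor_closer, pct_change_mean_r, n_genes), and
#'   `excluded` (zero-variance model windows).
#' @export
model_agreement <- function(normal, tumor, model, gene_subset = NULL,
                            tss = NULL) {
  if (!identical(rownames(normal), rownames(tumor)) ||
      !identical(dim(normal), dim(tumor)))
    stop("normal and tumor matrices must share genes and positions")
  offsets <- attr(normal, "positions")
  if (is.data.frame(model)) {
    if (is.null(tss)) stop("tss table required for a bedGraph model")
    model <- model_matrix_from_bedgraph(model, tss, offsets,
                                        attr(normal, "grid_step") %||% 1L)
  }
  if (!all(rownames(normal) %in% rownames(model)))
    stop("model matrix is missing genes")
  mpos <- attr(model, "positions")   # matrix subsetting drops attributes
  model <- model[rownames(normal), , drop = FALSE]
  if (ncol(model) != ncol(normal)) {
    ## resample a finer model grid onto the signal grid by bin means
    if (is.null(mpos))
      stop("model grid does not match the signal matrices")
    step <- attr(normal, "grid_step") %||% 1L
    res <- t(apply(unclass(model), 1L, bin_mean, positions = mpos,
                   offsets = offsets, step = step))
    if (any(!is.finite(res)))
      stop("model matrix does not cover the signal grid")
    model <- signal_matrix(res, offsets, units = "model_score",
                           grid_step = step)
  }
  genes <- rownames(normal)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, genes)
    if (length(missing) > 0L)
      stop("subset genes absent: ", paste(head(missing), collapse = ", "))
    genes <- gene_subset
  }
  sd_m <- apply(model[genes, , drop = FALSE], 1L, sd)
  sd_n <- apply(normal[genes, , drop = FALSE], 1L, sd)
  sd_t <- apply(tumor[genes, , drop = FALSE], 1L, sd)
  ok <- sd_m > 0 & sd_n > 0 & sd_t > 0
  excluded <- genes[!ok]
  genes <- genes[ok]
  if (length(genes) == 0L) stop("no genes with usable model windows")
  r_n <- vapply(genes, function(g) cor(normal[g, ], model[g, ]), numeric(1))
  r_t <- vapply(genes, function(g) cor(tumor[g, ], model[g, ]), numeric(1))
  tab <- data.frame(gene_id = genes, r_normal = r_n, r_tumor = r_t,
                    tumor_closer = r_t > r_n, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  mean_n <- mean(r_n); mean_t <- mean(r_t)
  list(table = tab,
       summary = list(fraction_tumor_closer = mean(tab$tumor_closer),
                      pct_change_mean_r =
                        100 * (mean_t - mean_n) / abs(mean_n),
                      mean_r_normal = mean_n, mean_r_tumor = mean_t,
                      n_genes = length(genes)),
       excluded = excluded)
}

## build a genes x offsets model matrix from a bedGraph track
model_matrix_from_bedgraph <- function(track, tss, offsets, step) {
  check_columns(track, c("chrom", "start", "end", "score"))
  values <- matrix(NA_real_, nrow = nrow(tss), ncol = length(offsets),
                   dimnames = list(tss$gene_id, NULL))
  by_chrom <- split(track, track$chrom)
  by_chrom <- lapply(by_chrom, function(tr) tr[order(tr$start), ])
  for (i in seq_len(nrow(tss))) {
    tr <- by_chrom[[tss$chrom[i]]]
    if (is.null(tr)) stop("model track missing chromosome ", tss$chrom[i])
    lo <- tss$tss[i] - max(abs(offsets)) - step
    hi <- tss$tss[i] + max(abs(offsets)) + step
    ## per-bp lookup into the (disjoint, sorted) bedGraph runs
    pos <- lo:hi
    idx <- findInterval(pos, tr$start)
    valid <- idx >= 1L & pos < tr$end[pmax(idx, 1L)]
    v <- rep(NA_real_, length(pos))
    v[valid] <- tr$score[idx[valid]]
    rel <- if (tss$strand[i] == "+") pos - tss$tss[i] else tss$tss[i] - pos
    values[i, ] <- bin_mean(v, rel, offsets, step)
  }
  if (any(!is.finite(values)))
    stop("model track does not cover every gene window")
  signal_matrix(values, offsets, units = "model_score", grid_step = step)
}
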