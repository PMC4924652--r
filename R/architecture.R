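## Promoter nucleosome-architecture clustering.
##
## Per-gene profiles over TSS +/- 500 bp are scaled to unit mean (which
## preserves occupancy shape including NDR depth, unlike z-scoring) and
## clustered by k-means with multiple random starts. Clusters are
## renumbered in descending size so reports are stable across runs.

#' k-means clustering of per-gene nucleosome profiles
#'
#' @param matrix a [signal_matrix()], typically over TSS +/- 500 bp on the
#'   10-bp dyad grid.
#' @param k number of clusters (default 4, the canonical promoter
#'   architecture count).
#' @param seed RNG seed for initialization (default 1357).
#' @param scale `"mean"` (divide each row by its mean; default),
#'   `"zscore"`, or `"none"`.
#' @param nstart number of random starts (default 10).
#' @param iter.max maximum Lloyd iterations per start.
#' @return object of class `cluster_result`: list with `labels` (named
#'   integer vector, clusters numbered 1..k by descending size),
#'   `centroids` (k x positions, on the scaled data), `sizes`, `inertia`
#'   (total within-cluster sum of squares), `k`, `seed`, `scale`.
#' @export
cluster_profiles <- function(matrix, k = 4L, seed = 1357L,
                             scale = c("mean", "zscore", "none"),
                             nstart = 10L, iter.max = 100L) {
  scale <- match.arg(scale)
  stopifnot(k >= 1L, nrow(matrix) >= k)
  x <- unclass(matrix)
  if (scale == "mean") {
    mu <- rowMeans(x)
    if (any(mu == 0)) stop("rows with zero mean cannot be mean-scaled: ",
                           paste(head(rownames(x)[mu == 0]), collapse = ", "))
    x <- x / mu
  } else if (scale == "zscore") {
    s <- apply(x, 1L, sd)
    if (any(s == 0)) stop("rows with zero variance cannot be z-scored")
    x <- (x - rowMeans(x)) / s
  }
  if (nrow(unique(x)) < k)
    stop("degenerate input: fewer distinct profiles than clusters")
  if (k == nrow(x)) {
    ## every gene its own cluster (stats::kmeans rejects k = n)
    km <- list(cluster = seq_len(k), centers = x,
               size = rep(1L, k), tot.withinss = 0)
  } else {
    km <- with_seed(as.integer(seed),
                    kmeans(x, centers = k, nstart = nstart,
                           iter.max = iter.max))
  }
  ## renumber by descending size (ties by original index)
  ord <- order(-km$size, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- setNames(relabel[km$cluster], rownames(x))
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  structure(list(labels = labels, centroids = centroids,
                 sizes = as.integer(km$size[ord]),
                 inertia = km$tot.withinss, k = k,
                 seed = as.integer(seed), scale = scale,
                 positions = attr(matrix, "positions")),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k=%d, sizes=%s, inertia=%.3g (seed %d)\n",
              x$k, paste(x$sizes, collapse = "/"), x$inertia, x$seed))
  invisible(x)
}

#' Cluster composition of a gene subset
#'
#' How a gene subset (e.g. the shared changed genes) distributes over the
#' architecture clusters.
#'
#' @param clustering a `cluster_result` or a named label vector.
#' @param gene_subset character vector of gene ids (subset of the labeled
#'   genes).
#' @return data.frame `cluster`, `cluster_size`, `count`, `fraction`
#'   (fractions sum to 1 over clusters).
#' @export
cluster_composition <- function(clustering, gene_subset) {
  labels <- if (inherits(clustering, "cluster_result")) clustering$labels
            else clustering
  if (length(gene_subset) == 0L) stop("empty gene subset")
  missing <- setdiff(gene_subset, names(labels))
  if (length(missing) > 0L)
    stop("genes not in clustering: ", paste(head(missing), collapse = ", "))
  ks <- sort(unique(labels))
  counts <- vapply(ks, function(k)
    sum(labels[gene_subset] == k), integer(1))
  data.frame(cluster = ks,
             cluster_size = as.integer(table(factor(labels, levels = ks))),
             count = counts,
             fraction = counts / length(gene_subset))
}

#' Stability scan over a range of k
#'
#' Clusters at each k and reports the inertia curve plus, for adjacent k,
#' the label-flow contingency table showing which clusters merge or
#' split.
#'
#' @param matrix a [signal_matrix()].
#' @param k_range integer vector of k values (default 3:5).
#' @param seed RNG seed shared across k.
#' @param ... passed to [cluster_profiles()].
#' @return list with `inertia` (data.frame k, inertia), `clusterings`
#'   (named list of `cluster_result`), and `flows` (contingency tables
#'   between adjacent k).
#' @export
stability_scan <- function(matrix, k_range = 3:5, seed = 1357L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 1L), all(k_range <= nrow(matrix)))
  clusterings <- lapply(k_range, function(k)
    cluster_profiles(matrix, k = k, seed = seed, ...))
  names(clusterings) <- paste0("k", k_range)
  flows <- list()
  if (length(k_range) > 1L) {
    for (j in seq_len(length(k_range) - 1L)) {
      a <- clusterings[[j]]$labels
      b <- clusterings[[j + 1L]]$labels
      flows[[sprintf("k%d_to_k%d", k_range[j], k_range[j + 1L])]] <-
        table(from = a, to = b[names(a)])
    }
  }
  list(inertia = data.frame(k = k_range,
                            inertia = vapply(clusterings, `[[`,
                                             numeric(1), "inertia")),
       clusterings = clusterings, flows = flows)
}
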