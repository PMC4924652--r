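## End-to-end orchestration: one configuration in, a machine-readable
## report out. Stage results are cached on disk keyed by a hash of the
## stage inputs and parameters, so unchanged reruns are no-ops and
## deleting one stage's cache reruns only that stage and its dependents.

#' Build a run configuration
#'
#' @param samples data.frame with columns `sample_id`, `patient`,
#'   `condition` (`"normal"`/`"tumor"`), `path` (fragment BED). Every
#'   patient must have exactly one normal and one tumor sample.
#' @param annotation named list of paths: `tss`, `capture`, `model`,
#'   `peaks`, `genesets`, and optionally `genome` (enables the
#'   dinucleotide-periodicity stage).
#' @param out_dir output directory.
#' @param params named list overriding the default analysis parameters
#'   (flank, window, step, quantile, threshold, k, cluster_flank,
#'   cluster_seed, shuffle_iter, shuffle_seed, footprint_flank,
#'   core_halfwidth, dinuc_length).
#' @return list of class `run_config`.
#' @export
run_config <- function(samples, annotation, out_dir, params = list()) {
  if (is.character(samples) && length(samples) == 1L) {
    cfg <- jsonlite::read_json(samples, simplifyVector = TRUE)
    return(run_config(as.data.frame(cfg$samples), as.list(cfg$annotation),
                      cfg$out_dir, as.list(cfg$params %||% list())))
  }
  check_columns(samples, c("sample_id", "patient", "condition", "path"))
  for (p in unique(samples$patient)) {
    conds <- sort(samples$condition[samples$patient == p])
    if (!identical(conds, c("normal", "tumor")))
      stop("patient ", p, " must have exactly one normal and one tumor sample")
  }
  needed <- c("tss", "capture", "model", "peaks", "genesets")
  miss <- setdiff(needed, names(annotation))
  if (length(miss) > 0L)
    stop("annotation paths missing: ", paste(miss, collapse = ", "))
  for (f in c(samples$path, unlist(annotation[needed])))
    if (!file.exists(f)) stop("input file not found: ", f)
  defaults <- list(flank = 1000L, window = 100L, step = 10L,
                   quantile = 0.2, threshold = 5, min_len = 1L,
                   k = 4L, cluster_flank = 500L, cluster_seed = 1357L,
                   shuffle_iter = 100L, shuffle_seed = 1L,
                   footprint_flank = 500L, core_halfwidth = 100L,
                   dinuc_length = 150L)
  params <- modifyList(defaults, params)
  structure(list(samples = samples, annotation = annotation,
                 out_dir = out_dir, params = params),
            class = "run_config")
}

## content hash of parameters + input files for stage caching
stage_hash <- function(params, files = character(0)) {
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA), tmp)
  h <- unname(c(md5sum(tmp), md5sum(files[file.exists(files)])))
  unlink(tmp)
  tmp2 <- tempfile()
  writeLines(paste(h, collapse = ""), tmp2)
  out <- unname(md5sum(tmp2))
  unlink(tmp2)
  out
}

with_cache <- function(cache_dir, stage, hash, expr) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cache_dir, sprintf("%s_%s.rds", stage, hash))
  ## stale entries for the same stage are removed so the cache stays tidy
  old <- list.files(cache_dir, pattern = paste0("^", stage, "_"),
                    full.names = TRUE)
  if (file.exists(path)) return(readRDS(path))
  unlink(setdiff(old, path))
  value <- force(expr)
  saveRDS(value, path)
  value
}

#' Run the full analysis
#'
#' Executes fragment ingestion, occupancy matrices, differential
#' analysis, architecture clustering, model agreement, TF-footprint
#' analysis and (when a genome is supplied) dinucleotide periodicity, in
#' order, and writes `report.json` plus stage TSV/BED artifacts under
#' the configured output directory.
#'
#' @param config a [run_config()] (or path to its JSON form).
#' @return the report (named list), invisibly also written as JSON.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  pr <- config$params
  out_dir <- config$out_dir
  cache <- file.path(out_dir, "cache")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- config$annotation
  tss <- read_tss_bed(ann$tss)
  capture <- read_bed_regions(ann$capture)
  peaks <- read_narrowpeak(ann$peaks)
  collections <- read_gmt(ann$genesets)
  model_track <- read_bedgraph(ann$model)
  samples <- config$samples
  patients <- unique(samples$patient)

  ## --- stage: per-sample matrices -------------------------------------
  sample_stage <- function(row) {
    h <- stage_hash(list(pr[c("flank", "window", "step")],
                         row$sample_id), c(row$path, ann$tss, ann$capture))
    with_cache(cache, paste0("matrix_", row$sample_id), h, {
      frags <- read_fragments(row$path, format = "bed")
      ot <- on_target_fraction(frags, capture)
      mat <- tss_matrix(frags, tss, flank = pr$flank, grid = "dyad",
                        window = pr$window, step = pr$step,
                        normalize = TRUE, total = ot$n_on_target)
      nuc <- partition_by_size(frags, "nucleosomal")
      sub <- partition_by_size(frags, "subnucleosomal")
      attr(nuc, "total_fragments") <- nrow(frags)
      attr(sub, "total_fragments") <- nrow(frags)
      list(matrix = mat, on_target = ot$fraction,
           n_fragments = nrow(frags),
           size_hist = length_histogram(frags, 5L),
           nucleosomal = nuc, subnucleosomal = sub)
    })
  }
  per_sample <- lapply(seq_len(nrow(samples)), function(i)
    sample_stage(samples[i, ]))
  names(per_sample) <- samples$sample_id

  sample_of <- function(patient, condition)
    samples$sample_id[samples$patient == patient &
                        samples$condition == condition]

  ## --- stage: differential --------------------------------------------
  diff_hash <- stage_hash(pr[c("quantile", "threshold", "min_len")],
                          unlist(lapply(samples$path, identity)))
  differential <- with_cache(cache, "differential", diff_hash, {
    calls <- list(); regions <- list(); diffs <- list()
    for (p in patients) {
      nm <- per_sample[[sample_of(p, "normal")]]$matrix
      tm <- per_sample[[sample_of(p, "tumor")]]$matrix
      dm <- difference_map(nm, tm)
      calls[[p]] <- correlation_change_call(nm, tm, quantile = pr$quantile)
      regions[[p]] <- call_difference_regions(
        dm, tss, threshold = pr$threshold, min_len = pr$min_len,
        patient_id = p)
      diffs[[p]] <- dm
    }
    shared <- intersect_changed(calls)
    merged <- merge_regions(do.call(rbind, lapply(regions, function(r)
      r[, c("chrom", "start", "end", "max_abs_difference", "patient_id")])))
    enrich <- geneset_enrichment(shared$shared, calls[[1L]]$gene_id,
                                 collections)
    list(calls = calls, regions = regions, shared = shared,
         merged = merged, enrichment = enrich, diffs = diffs)
  })

  ## --- stage: architecture --------------------------------------------
  arch_hash <- stage_hash(pr[c("k", "cluster_flank", "cluster_seed")],
                          samples$path[1L])
  architecture <- with_cache(cache, "architecture", arch_hash, {
    ref <- per_sample[[sample_of(patients[1L], "normal")]]$matrix
    sel <- abs(attr(ref, "positions")) <= pr$cluster_flank
    sub <- signal_matrix(unclass(ref)[, sel, drop = FALSE],
                         attr(ref, "positions")[sel],
                         units = attr(ref, "units"),
                         grid_step = attr(ref, "grid_step"))
    cl <- cluster_profiles(sub, k = pr$k, seed = pr$cluster_seed)
    comp <- cluster_composition(cl, differential$shared$shared)
    list(clustering = cl, composition = comp)
  })

  ## --- stage: model agreement -----------------------------------------
  agree <- lapply(patients, function(p) {
    nm <- per_sample[[sample_of(p, "normal")]]$matrix
    tm <- per_sample[[sample_of(p, "tumor")]]$matrix
    model_agreement(nm, tm, model_track,
                    gene_subset = differential$shared$shared, tss = tss)
  })
  names(agree) <- patients

  ## --- stage: tfbs ------------------------------------------------------
  tf_hash <- stage_hash(pr[c("shuffle_iter", "shuffle_seed",
                             "footprint_flank", "core_halfwidth")],
                        c(ann$peaks, samples$path))
  tfbs <- with_cache(cache, "tfbs", tf_hash, {
    shuffled <- shuffle_peaks(peaks, capture, n_iter = pr$shuffle_iter,
                              seed = pr$shuffle_seed)
    enr <- enrichment_ratio(differential$merged, peaks, shuffled)
    factor_col <- sub("_g[0-9]+$", "", peaks$name)
    changes <- list()
    for (p in patients) {
      sn <- per_sample[[sample_of(p, "normal")]]
      st <- per_sample[[sample_of(p, "tumor")]]
      for (f in unique(factor_col)) {
        pk <- peaks[factor_col == f, , drop = FALSE]
        fp_n <- aggregate_footprint(sn$subnucleosomal, pk,
                                    flank = pr$footprint_flank)
        fp_t <- aggregate_footprint(st$subnucleosomal, pk,
                                    flank = pr$footprint_flank)
        changes[[paste(p, f, sep = ".")]] <-
          c(list(patient = p, factor = f),
            binding_change(fp_n, fp_t,
                           core_halfwidth = pr$core_halfwidth))
      }
    }
    list(enrichment = enr, binding_changes = changes)
  })

  ## --- stage: dinucleotide periodicity (optional) ----------------------
  dinuc <- NULL
  if (!is.null(ann$genome)) {
    genome <- read_genome(ann$genome)
    frags <- per_sample[[sample_of(patients[1L], "normal")]]
    prof <- dinuc_profile(
      rbind(frags$nucleosomal, frags$subnucleosomal),
      genome, length = pr$dinuc_length, relax = 5L)
    per <- estimate_period(prof)
    dinuc <- list(n_fragments = attr(prof, "n_fragments"),
                  period = per$period, detected = per$detected)
  }

  report <- list(
    parameters = pr,
    samples = lapply(per_sample, function(s)
      list(n_fragments = s$n_fragments, on_target = s$on_target)),
    differential = list(
      n_changed_per_patient = lapply(differential$calls, function(cc)
        sum(cc$changed)),
      n_shared_changed = length(differential$shared$shared),
      pairwise = differential$shared$pairwise,
      n_merged_regions = nrow(differential$merged),
      top_genesets = head(differential$enrichment, 5L)),
    architecture = list(
      k = architecture$clustering$k,
      sizes = architecture$clustering$sizes,
      composition = architecture$composition),
    model_agreement = lapply(agree, `[[`, "summary"),
    tfbs = list(
      enrichment_ratio = tfbs$enrichment$ratio,
      observed_count = tfbs$enrichment$observed_count,
      shuffled_mean = tfbs$enrichment$shuffled_mean,
      binding_changes = lapply(tfbs$binding_changes, function(x)
        x[c("patient", "factor", "percent_change")])),
    dinucleotide = dinuc,
    provenance = list(package_version =
                        as.character(utils::packageVersion("mtssr")),
                      seeds = pr[c("cluster_seed", "shuffle_seed")]))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  ## stage artifacts
  write_bed_regions(cbind(differential$merged[, c("chrom", "start", "end")],
                          name = differential$merged$patients),
                    file.path(out_dir, "difference_regions.bed"))
  for (p in patients)
    write.table(differential$calls[[p]],
                file.path(out_dir, sprintf("change_calls_%s.tsv", p)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(architecture$clustering$labels),
                         cluster = architecture$clustering$labels),
              file.path(out_dir, "cluster_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(structure(list(report = report, per_sample = per_sample,
                           differential = differential,
                           architecture = architecture,
                           model_agreement = agree, tfbs = tfbs),
                      class = "mtss_run"))
}

#' Score a run against the planted truth of a synthetic study
#'
#' @param run the object returned by [run_all()].
#' @param truth path to the study's `truth.json`, or the parsed list.
#' @return scorecard list: per-patient change-call sensitivity and
#'   specificity with 95% binomial confidence intervals, adjusted Rand
#'   index of the clustering against planted templates, the
#'   model-agreement tumor-closer fraction on truly changed genes, and
#'   binding-change errors against the planted multipliers.
#' @export
validate_against_truth <- function(run, truth) {
  stopifnot(inherits(run, "mtss_run"))
  if (is.character(truth)) truth <- jsonlite::read_json(truth,
                                                        simplifyVector = TRUE)
  genes <- as.data.frame(truth$genes)
  changed_true <- genes$gene_id[genes$changed]
  calls <- run$differential$calls
  if (!setequal(calls[[1L]]$gene_id, genes$gene_id))
    stop("truth and report gene universes differ")
  prop_ci <- function(x, n) {
    if (n == 0L) return(c(NA_real_, NA_real_))
    as.numeric(binom.test(x, n)$conf.int)
  }
  change_scores <- lapply(calls, function(cc) {
    called <- cc$gene_id[cc$changed]
    tp <- length(intersect(called, changed_true))
    fp <- length(setdiff(called, changed_true))
    tn <- length(setdiff(cc$gene_id, union(called, changed_true)))
    fn <- length(setdiff(changed_true, called))
    sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
    list(sensitivity = sens, sensitivity_ci = prop_ci(tp, tp + fn),
         specificity = spec, specificity_ci = prop_ci(tn, tn + fp),
         n_called = length(called))
  })
  labels <- run$architecture$clustering$labels
  ari <- adjusted_rand_index(labels,
                             genes$template[match(names(labels),
                                                  genes$gene_id)])
  factors <- as.data.frame(truth$factors)
  binding <- lapply(run$tfbs$binding_changes, function(x) {
    planted <- 100 * (factors$tumor_mult[factors$factor == x$factor] /
                        factors$normal_mult[factors$factor == x$factor] - 1)
    list(patient = x$patient, factor = x$factor,
         measured = x$percent_change, planted = planted,
         error = x$percent_change - planted)
  })
  agree <- lapply(run$model_agreement, function(a)
    a$summary$fraction_tumor_closer)
  list(change_calls = change_scores,
       cluster_ari = ari,
       model_agreement_tumor_closer = agree,
       binding_changes = binding)
}
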