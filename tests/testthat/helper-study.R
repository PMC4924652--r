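## A small synthetic study shared (and memoised) across test files:
## 40 genes, 400 nucleosomal fragments per gene, full redistribution
## effect on 20% of genes. Deliberately below the stated-world defaults
## to keep the unit-test run fast; the acceptance tests use the full
## configuration.

.study_cache <- new.env(parent = emptyenv())

small_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  cfg <- sim_config(n_genes = 40L, frag_count_per_gene = 400L, seed = 42L)
  ann <- generate_annotation(cfg)
  model <- generate_model_track(ann, cfg)
  peaks <- generate_tf_peaks(ann, cfg)
  normal <- simulate_fragments("normal", ann, cfg, peaks)
  tumor <- simulate_fragments("tumor", ann, cfg, peaks)
  st <- list(cfg = cfg, ann = ann, model = model, peaks = peaks,
             normal = normal, tumor = tumor,
             mat_normal = tss_matrix(normal, ann$tss),
             mat_tumor = tss_matrix(tumor, ann$tss))
  .study_cache$study <- st
  st
}

## subset a signal matrix to |position| <= flank, keeping attributes
clip_matrix <- function(mat, flank) {
  sel <- abs(positions(mat)) <= flank
  signal_matrix(unclass(mat)[, sel, drop = FALSE], positions(mat)[sel],
                units = attr(mat, "units"),
                grid_step = attr(mat, "grid_step"))
}
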