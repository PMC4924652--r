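test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(changed_gene_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(nuc_size_mode = 90, sub_size_mode = 95),
               "nuc_size_mode")
})

test_that("annotation spacing, capture arithmetic and sizing errors", {
  ## single gene: exactly one 2000 bp capture region
  cfg1 <- sim_config(n_genes = 1L, chrom_count = 1L)
  ann1 <- generate_annotation(cfg1)
  expect_equal(nrow(ann1$capture), 1L)
  expect_equal(ann1$capture$end - ann1$capture$start, 2000L)
  ## n genes: total capture length = n * 2 * flank when nothing clips
  cfg <- sim_config(n_genes = 50L, seed = 7L)
  ann <- generate_annotation(cfg)
  expect_equal(sum(ann$capture$end - ann$capture$start), 50L * 2000L)
  ## capture regions never overlap
  expect_equal(nrow(merge_regions(ann$capture)), nrow(ann$capture))
  ## too-short chromosome is a sizing error
  expect_error(generate_annotation(sim_config(n_genes = 50L,
                                              chrom_len = 10000L)),
               "too short")
})

test_that("identical config and seed give byte-identical study files", {
  cfg <- sim_config(n_genes = 12L, frag_count_per_gene = 80L,
                    sub_background_per_gene = 5L, seed = 7L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10L)
  for (f in files)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("model track is normalized and shared templates correlate to 1", {
  st <- small_study()
  m <- unclass(st$model$matrix)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(apply(m, 1L, max) == 1))
  ## two unchanged genes with the same template+variant have identical
  ## TSS-aligned model windows
  d <- st$ann$design
  same <- d$gene_id[!d$changed & d$template == 1L]
  expect_gte(length(same), 2L)
  expect_equal(cor(m[same[1L], ], m[same[2L], ]), 1)
})

test_that("planted sequence stays in the DNA alphabet; amplitude modulates AT", {
  cfg <- sim_config(n_genes = 4L, seed = 3L)
  ann <- generate_annotation(cfg)
  dyads <- data.frame(chrom = "chr1", pos = c(1500L, 2200L))
  g <- plant_periodic_sequence(ann$genome, dyads, amplitude = 1, seed = 5L)
  freq <- Biostrings::alphabetFrequency(g[["chr1"]])
  expect_equal(sum(freq[c("A", "C", "G", "T")]), length(g[["chr1"]]))
  ## amplitude 0 leaves the base composition at background rates
  g0 <- plant_periodic_sequence(ann$genome, dyads, amplitude = 0, seed = 5L)
  win <- Biostrings::subseq(g0[["chr1"]], 1500L - 73L, 1500L + 74L)
  at <- sum(Biostrings::alphabetFrequency(win)[c("A", "T")])
  expect_gt(at / 148, 0.3)   # binomial(148, .5) stays well inside (0.3, 0.7)
  expect_lt(at / 148, 0.7)
  ## amplitude 1 concentrates A/T at the dyad-phase positions
  win1 <- as.character(Biostrings::subseq(g[["chr1"]], 1500L + 1L - 70L,
                                          1500L + 1L + 70L))
  bases <- strsplit(win1, "")[[1L]]
  phase0 <- bases[seq(1L, 141L, by = 10L)]   # distance multiple of 10
  expect_true(all(phase0 %in% c("A", "T")))
})

test_that("fragment lengths honor the truncation contracts", {
  st <- small_study()
  nuc_draws <- st$normal$length[seq_len(attr(st$normal, "n_nucleosomal"))]
  expect_gte(mean(nuc_draws >= 120 & nuc_draws <= 200), 0.99)
  sub <- partition_by_size(st$normal, "subnucleosomal")
  expect_true(all(sub$length >= 50L & sub$length <= 124L))
  ## conservation: totals decompose into the logged components
  expect_equal(nrow(st$normal),
               attr(st$normal, "n_nucleosomal") +
                 attr(st$normal, "n_footprint") +
                 attr(st$normal, "n_background"))
})

test_that("zero redistribution effect removes the normal/tumor difference", {
  cfg <- sim_config(n_genes = 30L, frag_count_per_gene = 500L,
                    redistribution_effect = 0, tumor_loss_weight = 1,
                    seed = 13L)
  ann <- generate_annotation(cfg)
  fn <- simulate_fragments("normal", ann, cfg)
  ft <- simulate_fragments("tumor", ann, cfg)
  mn <- tss_matrix(fn, ann$tss)
  mt <- tss_matrix(ft, ann$tss)
  cc <- correlation_change_call(mn, mt)
  truth <- ann$design$gene_id[ann$design$changed]
  called <- cc$gene_id[cc$changed]
  ## called set is noise: overlap with the planted labels is not enriched
  ## beyond the hypergeometric null (99.9% upper bound)
  ov <- length(intersect(called, truth))
  expect_lte(ov, qhyper(0.999, length(truth), nrow(ann$design) -
                          length(truth), length(called)))
  ## and per-gene correlations are uniformly high
  expect_gt(min(cc$r), 0.5)
})

test_that("TF peaks stay in capture space with planted multipliers", {
  st <- small_study()
  pk <- st$peaks
  cap <- st$ann$capture
  inside <- vapply(seq_len(nrow(pk)), function(i) {
    any(cap$chrom == pk$chrom[i] & cap$start <= pk$start[i] &
          pk$end[i] <= cap$end)
  }, logical(1))
  expect_true(all(inside))
  expect_true(all(pk$end - pk$start >= 150L & pk$end - pk$start <= 400L))
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
  expect_setequal(unique(pk$tumor_mult), c(0.87, 1.31))
})

test_that("truth file round-trips the planted design", {
  dir <- file.path(tempdir(), "truthcheck")
  unlink(dir, recursive = TRUE)
  cfg <- sim_config(n_genes = 12L, frag_count_per_gene = 60L, seed = 2L)
  st <- simulate_study(cfg, dir, n_patients = 1L)
  truth <- jsonlite::read_json(st$paths$truth, simplifyVector = TRUE)
  expect_equal(as.data.frame(truth$genes)$gene_id, st$annotation$design$gene_id)
  expect_equal(sum(as.data.frame(truth$genes)$changed),
               round(0.2 * 12))
  expect_equal(truth$fragment_counts$patient1$normal$total,
               nrow(st$fragments$patient1$normal))
  unlink(dir, recursive = TRUE)
})
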