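make_mat <- function(values, genes, pos = seq_len(ncol(values)) * 10L) {
  rownames(values) <- genes
  signal_matrix(values, pos, grid_step = 10L)
}

test_that("difference map is normal minus tumor and antisymmetric", {
  a <- make_mat(rbind(c(3, 3), c(1, 0)), c("g1", "g2"))
  b <- make_mat(rbind(c(1, 1), c(1, 0)), c("g1", "g2"))
  d <- difference_map(a, b)
  expect_equal(unname(d["g1", ]), c(2, 2))
  expect_equal(unname(attr(d, "sort_key")), c(2, 0))
  ## map(a, a) = 0 and map(a, b) = -map(b, a)
  expect_true(all(difference_map(a, a) == 0))
  expect_equal(unclass(difference_map(a, b)),
               -unclass(difference_map(b, a)), ignore_attr = TRUE)
  expect_error(difference_map(a, make_mat(matrix(1, 1, 2), "g1")), "share")
})

test_that("change calling flags the lowest correlation quantile exactly", {
  set.seed(1)
  n <- 50L
  base <- matrix(rnorm(n * 20, 10, 2), n)
  normal <- make_mat(abs(base), sprintf("g%02d", 1:n))
  tumor_vals <- abs(base + matrix(rnorm(n * 20, 0, 0.1), n))
  ## plant 10 anti-correlated genes
  tumor_vals[1:10, ] <- abs(max(base) - base[1:10, ])
  tumor <- make_mat(tumor_vals, sprintf("g%02d", 1:n))
  cc <- correlation_change_call(normal, tumor, quantile = 0.20)
  expect_equal(sum(cc$changed), floor(0.2 * n))
  expect_setequal(cc$gene_id[cc$changed], sprintf("g%02d", 1:10))
  expect_true(all(cc$r >= -1 & cc$r <= 1))
  ## tumor == normal: r = 1 everywhere, exactly floor(q*n) called by tie-break
  cc2 <- correlation_change_call(normal, normal)
  expect_equal(cc2$r, rep(1, n), tolerance = 1e-12)
  expect_equal(sum(cc2$changed), floor(0.2 * n))
  ## zero-variance genes are excluded and logged
  flat <- normal
  flat[3, ] <- 5
  cc3 <- correlation_change_call(flat, tumor)
  expect_equal(attr(cc3, "excluded"), "g03")
  expect_equal(nrow(cc3), n - 1L)
})

test_that("changed-set intersection and its null expectation", {
  genes <- sprintf("g%03d", 1:100)
  cc <- function(changed) data.frame(gene_id = genes, r = 0.5,
                                     changed = genes %in% changed)
  a <- cc(genes[1:20]); b <- cc(genes[11:30])
  out <- intersect_changed(list(a, b))
  expect_equal(out$shared, sort(genes[11:20]))
  expect_equal(out$pairwise$overlap, 10L)
  expect_equal(out$pairwise$expected, 20 * 20 / 100)
  ## identical sets intersect to themselves; three-way containment
  out2 <- intersect_changed(list(a, a, b))
  expect_true(all(out2$shared %in% out$shared))
  expect_equal(intersect_changed(list(a, a))$shared, sort(genes[1:20]))
  expect_error(intersect_changed(list(a, cc(genes)[1:50, ])), "universe")
  ## random 20% sets over 1000 genes: mean overlap matches n * p^2
  big <- sprintf("G%04d", 1:1000)
  set.seed(99)
  ov <- replicate(200, {
    s1 <- sample(big, 200); s2 <- sample(big, 200)
    length(intersect(s1, s2))
  })
  expect_lt(abs(mean(ov) - 1000 * 0.2^2), 3 * sd(ov) / sqrt(length(ov)))
})

test_that("difference regions are maximal threshold runs", {
  ## worked example on a per-bp track starting at 0
  regs <- call_difference_regions(c(0, 0, 6, 7, 0, 6), threshold = 5,
                                  chrom = "chr1", origin = 0L, step = 1L)
  expect_equal(regs$start, c(2L, 5L))
  expect_equal(regs$end, c(4L, 6L))
  expect_equal(regs$max_abs_difference, c(7, 6))
  ## all-zero track and translation invariance
  expect_equal(nrow(call_difference_regions(rep(0, 10), threshold = 5)), 0L)
  shifted <- call_difference_regions(c(0, 0, 6, 7, 0, 6), threshold = 5,
                                     origin = 100L)
  expect_equal(shifted$start, regs$start + 100L)
  ## random track equals the brute-force linear scan (two-sided)
  set.seed(5)
  x <- rnorm(400, 0, 4)
  got <- call_difference_regions(x, threshold = 5)
  want <- oracle_regions(x, 5)
  expect_equal(got$start, want[, 1] - 1L)
  expect_equal(got$end, want[, 2])
})

test_that("difference regions from a map land on the right genome strand", {
  vals <- matrix(0, 2, 5)
  vals[1, 2] <- 10   # offset -10 for the plus gene
  vals[2, 4] <- 10   # offset +10 for the minus gene
  d <- structure(vals, positions = seq(-20L, 20L, 10L), grid_step = 10L,
                 class = c("difference_map", "matrix", "array"),
                 sort_key = rowMeans(vals))
  rownames(d) <- c("plus", "minus")
  tss <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                    tss = c(1000L, 5000L), strand = c("+", "-"))
  regs <- call_difference_regions(d, tss, threshold = 5)
  expect_equal(regs$start[regs$gene_id == "plus"], 990L)
  ## minus-strand offset +10 is genomic tss - 10
  expect_equal(regs$start[regs$gene_id == "minus"], 4990L)
  expect_error(call_difference_regions(d, tss[1, ], threshold = 5), "absent")
})

test_that("merging regions equals per-bp union marking", {
  r <- data.frame(chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L),
                  patient_id = c("p1", "p2"))
  m <- merge_regions(r)
  expect_equal(m[, c("start", "end")],
               data.frame(start = 10L, end = 30L))
  expect_equal(m$patients, "p1,p2")
  ## book-ended intervals merge; disjoint inputs pass through
  r2 <- data.frame(chrom = "chr1", start = c(10L, 20L, 50L),
                   end = c(20L, 30L, 60L), patient_id = "p1")
  m2 <- merge_regions(r2)
  expect_equal(m2$start, c(10L, 50L))
  ## randomized check against the boolean-array oracle
  set.seed(8)
  start <- sample.int(5000L, 60L)
  r3 <- data.frame(chrom = "chr1", start = start,
                   end = start + sample(10:300, 60L, TRUE),
                   patient_id = sample(c("p1", "p2"), 60L, TRUE))
  got <- merge_regions(r3)
  want <- oracle_merge(r3)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("gene-set enrichment matches exact hypergeometric enumeration", {
  universe <- sprintf("u%02d", 1:20)
  collections <- list(hit = universe[1:5], other = universe[6:13])
  query <- c(universe[1:4], universe[20])
  res <- geneset_enrichment(query, universe, collections)
  hit <- res[res$set == "hit", ]
  expect_equal(hit$overlap, 4L)
  expect_equal(hit$p, 76 / 15504)
  ## against full enumeration of C(20,5) draws
  expect_equal(hit$p, oracle_hyper_upper(4L, 5L, 20L, 5L))
  ## saturation: query = set = universe -> p = 1
  sat <- geneset_enrichment(universe, universe, list(all = universe))
  expect_equal(sat$p, 1)
  expect_equal(sat$overlap, 20L)
  expect_error(geneset_enrichment(query, character(0), collections), "empty")
  expect_error(geneset_enrichment("zz", universe, collections), "subset")
  ## BH is monotone in p
  expect_true(all(diff(res$q) >= 0))
})

test_that("planted changed set is recovered and its gene set ranks first", {
  st <- small_study()
  cc <- correlation_change_call(st$mat_normal, st$mat_tumor)
  truth <- st$ann$design$gene_id[st$ann$design$changed]
  called <- cc$gene_id[cc$changed]
  expect_gt(length(intersect(called, truth)) / length(truth), 0.9)
  sets <- c(list(changed = truth),
            setNames(lapply(1:4, function(k)
              st$ann$design$gene_id[st$ann$design$template == k]),
              sprintf("template_%d", 1:4)))
  enr <- geneset_enrichment(called, cc$gene_id, sets)
  expect_equal(enr$set[1L], "changed")
})
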